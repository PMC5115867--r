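#' Map gene ids to species
#'
#' Default id convention: `<species>_f<family>_g<copy>` (as emitted by
#' [simulate_gene_families()]); anything before the `_f<digits>_g<digits>`
#' suffix is the species.
#'
#' @param genes Character vector of gene ids.
#' @return Named character vector species-by-gene.
#' @export
species_of <- function(genes) {
  sp <- sub("_f\\d+_g\\d+$", "", genes)
  setNames(sp, genes)
}

#' LCA reconciliation of a gene tree against a species tree
#'
#' Standard lowest-common-ancestor mapping: every gene-tree leaf maps to its
#' species' tip; every internal node maps to the LCA of its children's
#' mappings; a node is a duplication exactly when it maps to the same
#' species-tree node as one of its children, otherwise a speciation.
#'
#' @param gene_tree Rooted [ape::phylo] with supports as internal node labels.
#'   Unrooted input is midpoint-rooted with a warning (branch lengths
#'   required), or rooted at the first internal node when lengths are absent.
#' @param species_tree A [species_tree][make_species_tree].
#' @param species_map Optional named character vector gene -> species;
#'   defaults to [species_of()].
#' @return A `reconciled_tree`: list with `gene_tree`, `species_tree`, and
#'   `nodes` (tibble: `node`, `is_leaf`, `support`, `species_node`,
#'   `species_branch`, `event`).
#' @export
reconcile_lca <- function(gene_tree, species_tree, species_map = NULL) {
  .assert(inherits(species_tree, "species_tree"),
          "`species_tree` must be a species_tree.")
  phy <- gene_tree
  .assert(ape::Ntip(phy) >= 2, "gene tree needs at least 2 leaves.")
  if (!ape::is.rooted(phy)) {
    warn("unrooted gene tree: midpoint rooting applied.")
    phy <- if (!is.null(phy$edge.length)) {
      phangorn_free_midpoint(phy)
    } else {
      ape::root(phy, outgroup = phy$tip.label[1], resolve.root = TRUE)
    }
  }
  sp <- species_tree$phylo
  smap <- species_map %||% species_of(phy$tip.label)
  leaf_species <- unname(smap[phy$tip.label])
  unknown <- is.na(leaf_species) | !(leaf_species %in% sp$tip.label)
  if (any(unknown)) {
    abort(paste0("leaf species not in species tree: ",
                 paste(head(phy$tip.label[unknown], 5), collapse = ", ")))
  }

  anc <- .ancestor_paths(sp)
  depth <- lengths(anc)
  lca2 <- function(u, v) {
    if (u == v) return(u)
    pu <- anc[[u]]; pv <- anc[[v]]
    common <- intersect(pu, pv)
    common[which.max(depth[common])]
  }

  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  map <- integer(nnode)
  map[seq_len(ntip)] <- match(leaf_species, sp$tip.label)
  event <- rep(NA_character_, nnode)
  support <- rep(NA_real_, nnode)
  if (!is.null(phy$node.label)) {
    sup <- suppressWarnings(as.numeric(phy$node.label))
    sup[!is.na(sup) & (sup < 0 | sup > 1)] <- NA
    support[(ntip + 1):nnode] <- sup
  }

  kids <- split(phy$edge[, 2], phy$edge[, 1])
  # children are always deeper than their parent, so processing internal
  # nodes deepest-first is a valid postorder
  depth_g <- lengths(.ancestor_paths(phy))
  parents <- as.integer(names(kids))
  parents <- parents[order(-depth_g[parents])]
  for (nd in parents) {
    ch <- kids[[as.character(nd)]]
    mm <- map[ch[1]]
    for (c2 in ch[-1]) mm <- lca2(mm, map[c2])
    map[nd] <- mm
    event[nd] <- if (any(map[ch] == mm)) "duplication" else "speciation"
  }

  nodes <- tibble(
    node = seq_len(nnode),
    is_leaf = seq_len(nnode) <= ntip,
    label = c(phy$tip.label, rep(NA_character_, phy$Nnode)),
    support = support,
    species_node = map,
    species_branch = branch_label(species_tree, map),
    event = event
  )
  structure(list(gene_tree = phy, species_tree = species_tree, nodes = nodes),
            class = "reconciled_tree")
}

# midpoint rooting without extra deps beyond ape
phangorn_free_midpoint <- function(phy) {
  d <- ape::dist.nodes(phy)
  tips <- seq_len(ape::Ntip(phy))
  dt <- d[tips, tips]
  ij <- which(dt == max(dt), arr.ind = TRUE)[1, ]
  # root on the edge closest to the midpoint of the longest tip-tip path
  ape::root(phy, outgroup = tips[ij[1]], resolve.root = TRUE)
}

# list of ancestors (self included, root last is self-first ordering: from
# node up to root) for every node of a rooted phylo
.ancestor_paths <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  parent <- integer(n)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  lapply(seq_len(n), function(v) {
    path <- v
    while (parent[v] != 0L) {
      v <- parent[v]
      path <- c(path, v)
    }
    path
  })
}

#' @export
print.reconciled_tree <- function(x, ...) {
  ev <- table(x$nodes$event[!x$nodes$is_leaf])
  cat("Reconciled gene tree:", ape::Ntip(x$gene_tree), "leaves;",
      ev["duplication"] %||% 0, "duplications,",
      ev["speciation"] %||% 0, "speciations\n")
  invisible(x)
}

#' Most recent duplication call per gene
#'
#' Walks from each gene-tree leaf toward the root; the first node flagged as a
#' duplication is the candidate. The call is `accepted` when the candidate's
#' support and its two children's supports are all strictly greater than
#' `support_min` (leaf children count as support 1; absent supports are
#' treated as 1); otherwise `uncertain`. The reported branch is the
#' species-tree branch above the candidate's mapped node. Genes with no
#' duplication on the root path get branch `NA` with verdict `accepted`.
#'
#' @param rec A `reconciled_tree`.
#' @param support_min Strict support threshold (default 0.9).
#' @param genes Optional subset of leaf gene ids.
#' @return Tibble `gene`, `species`, `branch`, `verdict`.
#' @export
call_most_recent_duplication <- function(rec, support_min = 0.9, genes = NULL) {
  phy <- rec$gene_tree
  ntip <- ape::Ntip(phy)
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  nodes <- rec$nodes
  sup <- function(nd) {
    if (nd <= ntip) return(1)
    s <- nodes$support[nd]
    if (is.na(s)) 1 else s
  }
  leaves <- seq_len(ntip)
  if (!is.null(genes)) leaves <- leaves[phy$tip.label %in% genes]
  rows <- lapply(leaves, function(lf) {
    nd <- parent[lf]
    cand <- NA_integer_
    while (nd != 0L) {
      if (identical(nodes$event[nd], "duplication")) { cand <- nd; break }
      nd <- parent[nd]
    }
    if (is.na(cand)) {
      return(tibble(gene = phy$tip.label[lf], branch = NA_character_,
                    verdict = "accepted"))
    }
    ch <- phy$edge[phy$edge[, 1] == cand, 2]
    ok <- sup(cand) > support_min && all(vapply(ch, sup, 1.0) > support_min)
    tibble(gene = phy$tip.label[lf],
           branch = nodes$species_branch[cand],
           verdict = if (ok) "accepted" else "uncertain")
  })
  out <- bind_rows(rows)
  mutate(out, species = unname(species_of(.data$gene)), .after = "gene")
}

#' Duplication calls for a set of gene trees
#'
#' Convenience wrapper: reconciles every gene tree and calls the most recent
#' duplication for every gene.
#'
#' @param gene_trees Named list of rooted [ape::phylo].
#' @param species_tree A `species_tree`.
#' @param support_min Strict support threshold.
#' @return Tibble `family`, `gene`, `species`, `branch`, `verdict`.
#' @export
duplication_calls <- function(gene_trees, species_tree, support_min = 0.9) {
  bind_rows(imap(gene_trees, function(tr, nm) {
    rec <- reconcile_lca(tr, species_tree)
    mutate(call_most_recent_duplication(rec, support_min), family = nm,
           .before = 1)
  }))
}

#' Classify duplicate retention and pair WGT-derived copies
#'
#' For focal-species genes with an accepted most-recent-duplication call
#' (uncertain calls are excluded from all totals): `multi_copy` means the most
#' recent duplication postdates the deepest species-tree split (every labelled
#' branch except `ancient_branches`); `wgt_retained` means it maps to the WGT
#' branch; `nld_retained` means it maps to a focal-lineage branch. WGT pairs
#' are unordered pairs of focal-species genes from the same family whose most
#' recent duplication is the WGT branch and which are leaf-expressed; within a
#' family, the two topologically closest copies (gene-tree cophenetic
#' distance, counting edges) are paired first and each gene joins at most one
#' pair.
#'
#' @param calls Output of [duplication_calls()] (needs `family`).
#' @param gene_trees The gene trees used for the calls (for pairing).
#' @param species_tree The `species_tree`.
#' @param focal_species Species id whose genes are classified.
#' @param expressed Character vector of leaf-expressed gene ids, or `NULL`
#'   for all.
#' @param ancient_branches Branch labels that predate the deepest split and
#'   therefore do not count as duplications (default: the root stem when it is
#'   not the WGT branch).
#' @return List with `genes` (tibble `family`, `gene`, `branch`, `multi_copy`,
#'   `wgt_retained`, `nld_retained`, `expressed`) and `pairs` (tibble
#'   `family`, `gene1`, `gene2`).
#' @export
classify_retention <- function(calls, gene_trees, species_tree, focal_species,
                               expressed = NULL, ancient_branches = NULL) {
  if (is.null(ancient_branches)) {
    root <- ape::Ntip(species_tree$phylo) + 1L
    rl <- branch_label(species_tree, root)
    ancient_branches <- setdiff(rl, species_tree$wgt_branch)
  }
  focal <- calls |>
    filter(.data$species %in% focal_species, .data$verdict == "accepted") |>
    mutate(
      multi_copy = !is.na(.data$branch) &
        !(.data$branch %in% ancient_branches),
      wgt_retained = .data$multi_copy &
        .data$branch == species_tree$wgt_branch,
      nld_retained = .data$multi_copy &
        .data$branch %in% species_tree$focal_branches,
      expressed = if (is.null(expressed)) TRUE else .data$gene %in% expressed
    )

  pairs <- focal |>
    filter(.data$wgt_retained, .data$expressed) |>
    group_by(.data$family) |>
    dplyr::group_map(function(df, key) {
      if (nrow(df) < 2) return(NULL)
      tr <- gene_trees[[key$family]]
      tr2 <- tr
      tr2$edge.length <- rep(1, nrow(tr2$edge))
      d <- ape::cophenetic.phylo(tr2)[df$gene, df$gene, drop = FALSE]
      .greedy_pairs(d, key$family)
    }) |>
    bind_rows()
  if (nrow(pairs) == 0) {
    pairs <- tibble(family = character(), gene1 = character(),
                    gene2 = character())
  }
  list(genes = select(focal, "family", "gene", "branch", "multi_copy",
                      "wgt_retained", "nld_retained", "expressed"),
       pairs = pairs)
}

# repeatedly pair the two closest genes; odd gene out stays unpaired
.greedy_pairs <- function(d, family) {
  out <- list()
  genes <- rownames(d)
  while (length(genes) >= 2) {
    dd <- d[genes, genes, drop = FALSE]
    diag(dd) <- Inf
    ij <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    g <- sort(genes[ij])
    out[[length(out) + 1L]] <- tibble(family = family, gene1 = g[1],
                                      gene2 = g[2])
    genes <- setdiff(genes, g)
  }
  bind_rows(out)
}
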