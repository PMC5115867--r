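#' Simulate gene families by branchwise birth--death on a species tree
#'
#' Gene families are evolved along the species tree with per-branch event
#' counts: on every branch each entering gene lineage is first lost with
#' probability `loss_prob`; on the WGT branch each surviving lineage then
#' triplicates, with each of the two extra copies retained independently with
#' probability `wgt_retention_prob`; finally every surviving lineage acquires
#' a Poisson(`dup_rate_per_branch`) number of small-scale duplications. The
#' stem branch above the root is treated like any other branch, so families
#' can carry duplications predating the first speciation.
#'
#' Each emitted gene tree contains only nodes with surviving descendants on
#' both sides, so a reconciliation of the tree against the species tree can
#' recover the visible events. The per-gene truth is the branch label of the
#' nearest surviving duplication node above the gene (`NA` for single-copy
#' history), i.e. exactly what an ideal most-recent-duplication caller should
#' return.
#'
#' @param tree A [species_tree][make_species_tree].
#' @param n_families Number of families to simulate (>= 1).
#' @param dup_rate_per_branch Expected small-scale duplications per lineage
#'   per branch (>= 0).
#' @param wgt_retention_prob Retention probability of each extra WGT copy.
#' @param loss_prob Per-branch per-lineage loss probability.
#' @param support_model Branch-support model for the emitted gene trees:
#'   `list(type = "fixed", value = 1)` or
#'   `list(type = "beta", shape1 = , shape2 = )`.
#' @param seed Integer seed; identical seeds give bit-identical output.
#'
#' @return A list with `gene_trees` (named list of rooted [ape::phylo] with
#'   supports as internal node labels; families with < 2 surviving genes are
#'   omitted), `families` (tibble: `family`, `gene`, `species`) and `truth`
#'   (list of `genes` -- tibble `family`, `gene`, `species`, `truth_branch` --
#'   and `events` -- tibble `family`, `branch`, `type`).
#' @export
simulate_gene_families <- function(tree, n_families,
                                   dup_rate_per_branch = 0.05,
                                   wgt_retention_prob = 0.2,
                                   loss_prob = 0.05,
                                   support_model = list(type = "fixed", value = 1),
                                   seed = 1L) {
  .assert(inherits(tree, "species_tree"), "`tree` must be a species_tree.")
  .assert(n_families >= 1, "`n_families` must be >= 1.")
  .assert(dup_rate_per_branch >= 0, "`dup_rate_per_branch` must be >= 0.")
  .assert(wgt_retention_prob >= 0 && wgt_retention_prob <= 1,
          "`wgt_retention_prob` must be in [0, 1].")
  .assert(loss_prob >= 0 && loss_prob <= 1, "`loss_prob` must be in [0, 1].")

  with_seed(seed, {
    fams <- lapply(seq_len(n_families), function(f) {
      .simulate_one_family(tree, f, dup_rate_per_branch, wgt_retention_prob,
                           loss_prob)
    })
    names(fams) <- sprintf("f%04d", seq_len(n_families))

    genes <- bind_rows(lapply(names(fams), function(nm) {
      g <- fams[[nm]]$genes
      if (nrow(g)) mutate(g, family = nm, .before = 1) else NULL
    }))
    events <- bind_rows(lapply(names(fams), function(nm) {
      e <- fams[[nm]]$events
      if (nrow(e)) mutate(e, family = nm, .before = 1) else NULL
    }))
    trees <- lapply(fams, function(x) x$node)
    keep_tree <- vapply(fams, function(x) nrow(x$genes) >= 2, TRUE)
    gene_trees <- lapply(which(keep_tree), function(i) {
      .gene_tree_phylo(trees[[i]], support_model)
    })
    names(gene_trees) <- names(fams)[keep_tree]

    list(
      gene_trees = gene_trees,
      families = select(genes, "family", "gene", "species"),
      truth = list(
        genes = genes,
        events = if (nrow(events)) events else
          tibble(family = character(), branch = character(), type = character())
      )
    )
  })
}

# One family: recursive descent over species-tree nodes. A lineage entering
# the branch above `node` experiences loss -> WGT triplication -> Poisson
# duplications, then speciates (or terminates) at `node`. Returns NULL when
# the lineage leaves no descendants.
.simulate_one_family <- function(tree, fam, dup_rate, wgt_p, loss_p) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  counter <- new.env(parent = emptyenv())
  counter$g <- 0L
  events <- list()
  genes <- list()
  fam_id <- sprintf("f%04d", fam)

  log_event <- function(branch, type) {
    events[[length(events) + 1L]] <<- list(branch = branch, type = type)
  }

  # continue one lineage from species node `node` downward (the lineage has
  # already survived the branch above `node`)
  at_node <- function(node, last_dup) {
    if (node <= ntip) {
      counter$g <- counter$g + 1L
      gid <- paste0(phy$tip.label[node], "_", fam_id, "_g", counter$g)
      genes[[length(genes) + 1L]] <<- list(
        gene = gid, species = phy$tip.label[node], truth_branch = last_dup)
      return(list(kind = "leaf", label = gid))
    }
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    subs <- lapply(kids, function(k) down_branch(k, last_dup))
    subs <- subs[!vapply(subs, is.null, TRUE)]
    if (length(subs) == 0L) return(NULL)
    if (length(subs) == 1L) return(subs[[1]])
    list(kind = "spec", children = subs)
  }

  # evolve one entering lineage along the branch above `node`
  down_branch <- function(node, last_dup) {
    blab <- branch_label(tree, node)
    if (runif(1) < loss_p) {
      log_event(blab, "loss")
      return(NULL)
    }
    lineages <- 1L
    wgt_here <- tree$branches$wgt[match(node, tree$branches$node)]
    n_extra <- 0L
    if (isTRUE(wgt_here)) {
      n_extra <- sum(runif(2) < wgt_p)
      if (n_extra > 0L) log_event(blab, "triplication")
    }
    # each lineage present on the branch draws its own duplication count
    n_dups <- rpois(1L + n_extra, dup_rate)
    if (any(n_dups > 0)) {
      for (i in seq_len(sum(n_dups))) log_event(blab, "duplication")
    }

    # a single lineage with k caterpillar duplications on this branch;
    # duplication nodes are kept only when both sides survive
    one_lineage <- function(k, ld) {
      ld_here <- if (k > 0) blab else ld
      parts <- lapply(seq_len(k + 1L), function(i) at_node(node, ld_here))
      parts <- parts[!vapply(parts, is.null, TRUE)]
      if (length(parts) == 0L) return(NULL)
      out <- parts[[1]]
      for (p in parts[-1]) {
        out <- list(kind = "dup", branch = blab, children = list(out, p))
      }
      out
    }

    ld_after_wgt <- if (n_extra > 0L) blab else last_dup
    subs <- lapply(seq_len(1L + n_extra), function(i) {
      one_lineage(n_dups[[i]], ld_after_wgt)
    })
    subs <- subs[!vapply(subs, is.null, TRUE)]
    if (length(subs) == 0L) return(NULL)
    out <- subs[[1]]
    for (p in subs[-1]) {
      out <- list(kind = "dup", branch = blab, children = list(out, p))
    }
    out
  }

  node <- down_branch(root, NA_character_)
  # the caterpillar join above can keep a duplication label even when only
  # one side of an early duplication survived; re-derive per-gene truth from
  # the final pruned tree so truth == nearest surviving duplication node
  truth <- .truth_from_tree(node)
  gtbl <- if (length(genes)) {
    tibble(
      gene = map_chr(genes, "gene"),
      species = map_chr(genes, "species"),
      truth_branch = unname(truth[map_chr(genes, "gene")])
    )
  } else {
    tibble(gene = character(), species = character(), truth_branch = character())
  }
  etbl <- if (length(events)) {
    tibble(branch = map_chr(events, "branch"), type = map_chr(events, "type"))
  } else {
    tibble(branch = character(), type = character())
  }
  list(node = node, genes = gtbl, events = etbl)
}

# nearest ancestral duplication-node branch for every leaf of a built tree
.truth_from_tree <- function(node) {
  out <- character()
  walk <- function(nd, last_dup) {
    if (is.null(nd)) return(invisible())
    if (nd$kind == "leaf") {
      out[[nd$label]] <<- last_dup
      return(invisible())
    }
    ld <- if (nd$kind == "dup") nd$branch else last_dup
    for (ch in nd$children) walk(ch, ld)
  }
  walk(node, NA_character_)
  out
}

.draw_support <- function(n, model) {
  if (n == 0L) return(numeric())
  type <- model$type %||% "fixed"
  if (type == "fixed") {
    rep(model$value %||% 1, n)
  } else if (type == "beta") {
    rbeta(n, model$shape1 %||% 40, model$shape2 %||% 2)
  } else {
    abort("unknown support model type: ", type)
  }
}

# nested-list gene tree -> rooted phylo with supports as internal node labels
.gene_tree_phylo <- function(node, support_model) {
  nwk <- .to_newick(node, support_model)
  phy <- ape::read.tree(text = paste0(nwk, ";"))
  phy
}

.to_newick <- function(nd, support_model) {
  if (nd$kind == "leaf") return(nd$label)
  kids <- vapply(nd$children, .to_newick, "", support_model = support_model)
  sup <- .draw_support(1L, support_model)
  sprintf("(%s)%s", paste(kids, collapse = ","),
          format(round(sup, 4), scientific = FALSE, trim = TRUE))
}
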