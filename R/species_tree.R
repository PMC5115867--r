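#' Build a species tree with labelled branches
#'
#' Constructs a rooted species tree whose branches carry stable labels, with
#' exactly one branch marked as the whole-genome-triplication (WGT) stem and a
#' set of branches marked as the focal lineage (the clade in which
#' lineage-specific duplications, NLDs, are scored).
#'
#' Two presets are available. `"nicotiana"` is a fixed six-species tree of the
#' *Petunioides* clade (N. obtusifolia sister to the rest; N. attenuata and
#' N. obtusifolia maximally divergent); its root stem carries the WGT label,
#' standing for the Solanaceae stem, and every branch inside the clade is a
#' focal-lineage branch. `"eudicot"` embeds the same six species in a
#' nine-species eudicot/monocot frame (monocot outgroup, a basal eudicot, and
#' *S. lycopersicum* inside Solanaceae) so that duplications older than the
#' WGT are distinguishable from WGT-derived ones; the branch above the
#' Solanaceae crown carries the WGT label and the Nicotiana stem plus all
#' branches within the Nicotiana clade are focal.
#'
#' With `preset = "random"` a random rooted topology with `n` leaves is drawn;
#' the WGT label is placed on the stem of a randomly chosen internal clade
#' (the root stem when `n == 2`) and the larger child subtree of that clade
#' becomes the focal lineage.
#'
#' @param preset `"nicotiana"`, `"eudicot"`, or `"random"`.
#' @param n Number of leaves for `preset = "random"` (>= 2).
#' @param seed Integer seed (used by the random preset only).
#'
#' @return An object of class `species_tree`: a list with elements `phylo`
#'   (rooted [ape::phylo]), `branches` (tibble with one row per branch keyed
#'   by the node below it: `node`, `label`, `wgt`, `focal`; the root row
#'   describes the stem above the root), `wgt_branch`, `focal_branches`, and
#'   `focal_species`.
#' @export
make_species_tree <- function(preset = c("nicotiana", "eudicot", "random"),
                              n = NULL, seed = 1L) {
  preset <- match.arg(preset)
  nic <- "(N.obtusifolia,(N.miersii,((N.linearis,N.attenuata),(N.acuminata,N.pauciflora))))"
  if (preset == "nicotiana") {
    phy <- ape::read.tree(text = paste0(nic, ";"))
    st <- .species_tree_from_phylo(phy, wgt_node = ape::Ntip(phy) + 1L,
                                   focal_mrca = ape::Ntip(phy) + 1L,
                                   wgt_on_root_stem = TRUE)
  } else if (preset == "eudicot") {
    phy <- ape::read.tree(text = paste0(
      "(O.sativa,(V.vinifera,(S.lycopersicum,", nic, ")));"))
    sol_crown <- ape::getMRCA(phy, c("S.lycopersicum", "N.attenuata"))
    nic_crown <- ape::getMRCA(phy, c("N.obtusifolia", "N.attenuata"))
    st <- .species_tree_from_phylo(phy, wgt_node = sol_crown,
                                   focal_mrca = nic_crown)
  } else {
    .assert(!is.null(n) && n >= 2, "`n` must be >= 2 for a random species tree.")
    phy <- with_seed(seed, ape::rtree(n, rooted = TRUE, br = NULL))
    phy$tip.label <- sprintf("sp%02d", seq_len(n))
    if (n == 2) {
      st <- .species_tree_from_phylo(phy, wgt_node = n + 1L,
                                     focal_mrca = n + 1L,
                                     wgt_on_root_stem = TRUE)
    } else {
      internal <- setdiff(seq.int(n + 1L, n + phy$Nnode), n + 1L)
      wgt_node <- with_seed(seed + 1L, sample(internal, 1L))
      kids <- phy$edge[phy$edge[, 1] == wgt_node, 2]
      sizes <- vapply(kids, function(k) length(.descendant_tips(phy, k)), 1L)
      st <- .species_tree_from_phylo(phy, wgt_node = wgt_node,
                                     focal_mrca = kids[which.max(sizes)])
    }
  }
  st
}

.descendant_tips <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  if (node <= ntip) return(node)
  out <- integer()
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

.descendant_nodes <- function(phy, node) {
  out <- integer()
  stack <- node
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > ape::Ntip(phy)])
  }
  out
}

# wgt_node / focal_mrca are node ids; the branch labelled WGT is the branch
# ABOVE wgt_node (the root-stem row when wgt_node is the root)
.species_tree_from_phylo <- function(phy, wgt_node, focal_mrca,
                                     wgt_on_root_stem = FALSE) {
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  .assert(ape::is.rooted(phy), "species tree must be rooted")
  .assert(!anyDuplicated(phy$tip.label), "species tree leaf names must be unique")
  nodes <- seq_len(ntip + phy$Nnode)
  label <- character(length(nodes))
  label[seq_len(ntip)] <- paste0("B_", phy$tip.label)
  internal <- nodes[nodes > ntip]
  label[internal] <- paste0("CLADE_", seq_along(internal))
  label[root] <- "ROOT_STEM"
  if (wgt_on_root_stem || wgt_node == root) {
    label[root] <- "SOL_WGT_STEM"
  } else {
    label[wgt_node] <- "SOL_WGT_STEM"
  }
  focal_nodes <- unique(c(focal_mrca, .descendant_nodes(phy, focal_mrca)))
  if (focal_mrca == root) focal_nodes <- setdiff(focal_nodes, root)
  focal <- nodes %in% focal_nodes
  # relabel focal internal branches for readability
  fi <- intersect(which(focal), internal)
  label[fi] <- paste0("NIC_", seq_along(fi))
  if (focal_mrca != root && focal_mrca > ntip && wgt_node != focal_mrca) {
    label[focal_mrca] <- "NIC_STEM"
  }
  wgt_label <- "SOL_WGT_STEM"
  branches <- tibble(
    node = nodes,
    label = label,
    wgt = label == wgt_label,
    focal = focal & label != wgt_label
  )
  .assert(sum(branches$wgt) == 1L, "exactly one branch must carry the WGT label")
  phy$node.label <- label[internal]
  structure(
    list(
      phylo = phy,
      branches = branches,
      wgt_branch = wgt_label,
      focal_branches = branches$label[branches$focal],
      focal_species = phy$tip.label[.descendant_tips(phy, focal_mrca)]
    ),
    class = "species_tree"
  )
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree with", ape::Ntip(x$phylo), "leaves\n")
  cat("  WGT branch:", x$wgt_branch, "\n")
  cat("  focal-lineage branches:", length(x$focal_branches), "\n")
  cat("  newick:", species_tree_newick(x), "\n")
  invisible(x)
}

#' Serialize a species tree to newick
#'
#' Internal branch labels are written as internal node labels (the label of a
#' node encodes the branch above it); terminal branch labels are implicit
#' (`B_<tip>`).
#'
#' @param tree A `species_tree`.
#' @return A newick string.
#' @export
species_tree_newick <- function(tree) {
  ape::write.tree(tree$phylo)
}

#' Branch label above a species-tree node
#' @param tree A `species_tree`.
#' @param node Node id(s) in the underlying `phylo`.
#' @return Character vector of branch labels.
#' @export
branch_label <- function(tree, node) {
  tree$branches$label[match(node, tree$branches$node)]
}
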