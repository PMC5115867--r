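# small fixtures shared across test files; everything is generated in code

toy_counts <- function(mat, lengths = NULL) {
  lengths <- lengths %||% rep(1000L, nrow(mat))
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  dplyr::bind_cols(
    tibble::tibble(gene = rownames(mat), length = lengths),
    tibble::as_tibble(mat)
  )
}

toy_expr <- function(mat, transforms = c("tmm_fpkm", "log2")) {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%02d", seq_len(ncol(mat)))
  out <- dplyr::bind_cols(tibble::tibble(gene = rownames(mat)),
                          tibble::as_tibble(mat))
  attr(out, "transforms") <- transforms
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# planted two-block expression: genes x samples, blocks driven by latent
# factors with given loading, remainder pure noise
planted_blocks <- function(n_per_block = 50, n_noise = 50, n_samples = 30,
                           loading = 0.9, seed = 1) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  block <- function(f, n) {
    t(sapply(seq_len(n), function(i) {
      loading * f + sqrt(1 - loading^2) * rnorm(n_samples)
    }))
  }
  m <- rbind(block(f1, n_per_block), block(f2, n_per_block),
             matrix(rnorm(n_noise * n_samples), n_noise))
  rownames(m) <- c(sprintf("a%03d", seq_len(n_per_block)),
                   sprintf("b%03d", seq_len(n_per_block)),
                   sprintf("n%03d", seq_len(n_noise)))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  toy_expr(m)
}

# brute-force TOM from an adjacency matrix, straight from the formula
tom_oracle <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  out <- matrix(0, n, n, dimnames = dimnames(a))
  k <- rowSums(a)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- sum(a[i, ] * a[, j]) - a[i, i] * a[i, j] - a[i, j] * a[j, j]
      out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  out
}

# naive quadratic LCA reconciliation oracle: species sets per gene-tree clade
reconcile_oracle <- function(gene_tree, species_tree) {
  phy <- gene_tree
  sp <- species_tree$phylo
  ntip <- ape::Ntip(phy)
  clade_species <- function(nd) {
    tips <- if (nd <= ntip) nd else {
      kk <- integer(); st <- nd
      while (length(st)) {
        v <- st[[1]]; st <- st[-1]
        ch <- phy$edge[phy$edge[, 1] == v, 2]
        kk <- c(kk, ch[ch <= ntip]); st <- c(st, ch[ch > ntip])
      }
      kk
    }
    unique(unname(species_of(phy$tip.label[tips])))
  }
  sp_tips <- function(nd) {
    if (nd <= ape::Ntip(sp)) return(sp$tip.label[nd])
    kk <- character(); st <- nd
    while (length(st)) {
      v <- st[[1]]; st <- st[-1]
      ch <- sp$edge[sp$edge[, 1] == v, 2]
      kk <- c(kk, sp$tip.label[ch[ch <= ape::Ntip(sp)]])
      st <- c(st, ch[ch > ape::Ntip(sp)])
    }
    kk
  }
  # LCA in species tree = smallest clade containing all species (quadratic)
  lca_sp <- function(species) {
    all_nodes <- seq_len(ape::Ntip(sp) + sp$Nnode)
    sizes <- vapply(all_nodes, function(v) length(sp_tips(v)), 1L)
    cands <- all_nodes[vapply(all_nodes, function(v)
      all(species %in% sp_tips(v)), TRUE)]
    cands[which.min(sizes[cands])]
  }
  internal <- (ntip + 1):(ntip + phy$Nnode)
  tibble::tibble(
    node = internal,
    species_node = vapply(internal, function(nd) lca_sp(clade_species(nd)), 1L),
    event = vapply(internal, function(nd) {
      ch <- phy$edge[phy$edge[, 1] == nd, 2]
      me <- lca_sp(clade_species(nd))
      if (any(vapply(ch, function(c2) lca_sp(clade_species(c2)), 1L) == me))
        "duplication" else "speciation"
    }, "")
  )
}
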