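#' Detect co-expression modules by average-linkage clustering of 1 - TOM
#'
#' Genes are clustered by average-linkage hierarchical clustering on the
#' dissimilarity `1 - TOM`; the tree is cut at `cut_height`, branches with at
#' least `min_module_size` members become modules (labelled `M1`, `M2`, ... in
#' decreasing size; ties broken by smallest member id), and all remaining
#' genes get module 0 (unassigned).
#'
#' The default cut height of 0.95 sits between the average-linkage merge
#' heights of genuinely co-expressed branches (below ~0.9 for unsigned power-6
#' adjacency at a few dozen samples) and the near-1 dissimilarity at which
#' unrelated genes chain together; module boundaries at this resolution are
#' deliberately generous and are refined downstream by the kME > 0.75 core
#' filter of [module_statistics()].
#'
#' @param network An `eds_network` from [build_network()].
#' @param min_module_size Minimum genes per module (default 30).
#' @param cut_height Static cut height on 1 - TOM (default 0.95).
#' @return An `eds_modules` tibble `gene`, `module` (integer, 0 = unassigned),
#'   `module_name`, with the `hclust` tree in attribute `dendrogram`.
#' @export
detect_modules <- function(network, min_module_size = 30, cut_height = 0.95) {
  diss <- 1 - network$tom
  hc <- hclust(as.dist(diss), method = "average")
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  # order by decreasing size, ties by first member id
  firsts <- vapply(big, function(b) min(network$genes[cl == b]), "")
  big <- big[order(-sizes[big], firsts)]
  module <- integer(length(cl))
  for (i in seq_along(big)) module[cl == big[i]] <- i
  out <- tibble(
    gene = network$genes,
    module = module,
    module_name = ifelse(module == 0, "unassigned", paste0("M", module))
  )
  class(out) <- c("eds_modules", class(out))
  attr(out, "dendrogram") <- hc
  attr(out, "params") <- list(min_module_size = min_module_size,
                              cut_height = cut_height)
  out
}

#' Module eigengenes, membership (kME), intramodular connectivity (kIM),
#' core genes and hubs
#'
#' The module eigengene is the first principal component of the standardized
#' module expression (unit norm over samples), sign-oriented to correlate
#' positively with the module mean profile. kME is the Pearson correlation of
#' a gene's profile with its own module's eigengene (signed); the core set is
#' kME strictly greater than `kme_core`. kIM is the gene's within-module
#' adjacency row sum. Hubs are, per module, the top `ceiling(hub_fraction x
#' module size)` genes by connectivity computed on `hub_network` when given
#' (e.g. a network built from elicited samples only), else on `network`.
#'
#' @param expr Expression table used to build the network.
#' @param network The `eds_network`.
#' @param modules An `eds_modules` tibble.
#' @param kme_core Core-membership threshold (strict, default 0.75).
#' @param hub_fraction Fraction of module genes called hubs (default 0.05).
#' @param hub_network Optional `eds_network` for hub connectivity.
#' @return The modules tibble with `kme`, `kim`, `core`, `hub` columns and an
#'   `eigengenes` attribute (samples x modules matrix).
#' @export
module_statistics <- function(expr, network, modules, kme_core = 0.75,
                              hub_fraction = 0.05, hub_network = NULL) {
  .assert(any(modules$module > 0), "no modules to score.")
  m <- .expr_matrix(expr)[modules$gene, , drop = FALSE]
  a <- network$adjacency
  mods <- sort(unique(modules$module[modules$module > 0]))
  eig <- sapply(mods, function(k) .eigengene(m[modules$gene[modules$module == k], , drop = FALSE]))
  if (is.null(dim(eig))) eig <- matrix(eig, ncol = 1)
  colnames(eig) <- paste0("M", mods)

  kme <- rep(NA_real_, nrow(modules))
  kim <- rep(NA_real_, nrow(modules))
  hub <- rep(FALSE, nrow(modules))
  hub_a <- if (is.null(hub_network)) a else hub_network$adjacency
  for (k in mods) {
    idx <- which(modules$module == k)
    genes <- modules$gene[idx]
    kme[idx] <- if (length(genes) == 1) 1 else
      as.numeric(cor(t(m[genes, , drop = FALSE]), eig[, paste0("M", k)]))
    kim[idx] <- rowSums(a[genes, genes, drop = FALSE])
    conn <- rowSums(hub_a[genes, genes, drop = FALSE])
    n_hub <- min(length(genes), ceiling(hub_fraction * length(genes)))
    top <- order(-conn, genes, method = "radix")[seq_len(n_hub)]
    hub[idx[top]] <- TRUE
  }
  out <- mutate(modules, kme = kme, kim = kim,
                core = !is.na(kme) & kme > kme_core, hub = hub)
  class(out) <- c("eds_modules", class(tibble()))
  attr(out, "eigengenes") <- eig
  attr(out, "dendrogram") <- attr(modules, "dendrogram")
  out
}

# first PC of the standardized module expression, unit norm over samples,
# sign-oriented toward the module mean profile
.eigengene <- function(mat) {
  if (nrow(mat) == 1) {
    v <- as.numeric(scale(as.numeric(mat)))
    return(v / sqrt(sum(v^2)))
  }
  z <- t(scale(t(mat)))
  z[!is.finite(z)] <- 0
  sv <- svd(z, nu = 0, nv = 1)
  e <- sv$v[, 1]
  if (cor(e, colMeans(z)) < 0) e <- -e
  e / sqrt(sum(e^2))
}

#' Module--trait coupling
#'
#' Correlates every gene's profile with a per-sample trait, summarises member
#' correlations per module (mean and standard error), and tests whether the
#' top-ranked module's member correlations exceed those of all other assigned
#' genes by a one-sided Wilcoxon--Mann--Whitney rank test.
#'
#' @param expr Expression table.
#' @param modules An `eds_modules` tibble.
#' @param trait Numeric trait per sample (column order or named by sample).
#' @return Tibble `module_name`, `n`, `mean_cor`, `se_cor`, ordered by
#'   decreasing mean correlation, with attributes `gene_correlations`,
#'   `focal_module` and `p_value`.
#' @export
module_trait_correlation <- function(expr, modules, trait) {
  m <- .expr_matrix(expr)[modules$gene, , drop = FALSE]
  if (!is.null(names(trait))) trait <- trait[colnames(m)]
  .assert(length(trait) == ncol(m) && !anyNA(trait),
          "`trait` must be defined for every sample.")
  .assert(sd(trait) > 0, "`trait` is constant.")
  gcor <- as.numeric(cor(t(m), trait))
  per_gene <- tibble(gene = modules$gene, module = modules$module,
                     module_name = modules$module_name, cor = gcor)
  assigned <- filter(per_gene, .data$module > 0)
  smry <- assigned |>
    group_by(.data$module, .data$module_name) |>
    summarise(n = dplyr::n(), mean_cor = mean(.data$cor),
              se_cor = sd(.data$cor) / sqrt(dplyr::n()), .groups = "drop") |>
    arrange(desc(.data$mean_cor))
  focal <- smry$module[1]
  # compare the top module against members of all other modules; when it is
  # the only module, unassigned genes serve as the comparison set
  other <- if (nrow(smry) > 1) {
    assigned$cor[assigned$module != focal]
  } else {
    per_gene$cor[per_gene$module == 0]
  }
  pv <- if (length(other) >= 3) {
    wilcox.test(assigned$cor[assigned$module == focal], other,
                alternative = "greater", exact = FALSE)$p.value
  } else {
    NA_real_
  }
  out <- select(smry, -"module")
  attr(out, "gene_correlations") <- per_gene
  attr(out, "focal_module") <- smry$module_name[1]
  attr(out, "p_value") <- pv
  class(out) <- c("eds_trait_cor", class(out))
  out
}

#' Contrast intramodular connectivity between sample groups
#'
#' Computes a module's intramodular connectivity separately on networks built
#' from two sample subsets (e.g. elicited vs control samples) and compares the
#' per-gene values with a Kruskal--Wallis rank sum test.
#'
#' @param expr Expression table.
#' @param module_genes Character vector of module gene ids.
#' @param groups Sample grouping (column order or named by sample).
#' @param power Soft power for the subset networks.
#' @return Tibble `group`, `n_samples`, `median_kim` with attribute `p_value`.
#' @export
kim_contrast <- function(expr, module_genes, groups, power = 6) {
  m <- .expr_matrix(expr)
  groups <- .per_sample(groups, colnames(m), "groups")
  mg <- intersect(module_genes, rownames(m))
  .assert(length(mg) >= 3, "need at least 3 module genes present.")
  kim <- lapply(unique(groups), function(g) {
    sub <- m[mg, groups == g, drop = FALSE]
    a <- abs(cor(t(sub)))^power
    diag(a) <- 0
    rowSums(a)
  })
  names(kim) <- unique(groups)
  pv <- kruskal.test(kim)$p.value
  out <- tibble(
    group = names(kim),
    n_samples = as.integer(table(groups)[names(kim)]),
    median_kim = vapply(kim, median, 1.0)
  )
  attr(out, "p_value") <- pv
  attr(out, "kim") <- kim
  out
}
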