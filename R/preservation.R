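#' Permutation Z-statistics of module preservation across datasets
#'
#' For each module defined in a reference dataset, three observed statistics
#' are computed in a test dataset: the density (mean within-module test
#' adjacency) and two connectivity statistics (the correlation between
#' reference and test intramodular connectivity, and the correlation between
#' reference and test within-module adjacency entries). Each statistic is
#' standardized against its distribution over `n_perm` random gene sets of the
#' same size drawn from the genes common to both datasets:
#' \eqn{Z = (obs - mean_{perm}) / sd_{perm}}. `z_density` is the density Z,
#' `z_connectivity` the median of the two connectivity Zs, and
#' `z_summary` their mean. Values above 10 indicate a strongly preserved
#' module; values below 2 indicate no evidence of preservation. The
#' permutation p-value is the upper-tail empirical probability (with +1
#' correction) of the composite statistic; p-values at the floor are reported
#' as `1 / (n_perm + 1)` with `p_at_floor = TRUE`.
#'
#' Module genes missing from the test dataset are dropped; a warning is
#' issued when less than `min_overlap` of a module survives, and modules with
#' fewer than 3 surviving genes are skipped.
#'
#' @param ref_expr,test_expr Expression tables (reference defines modules).
#' @param modules An `eds_modules` tibble, or a named list of gene-id vectors.
#' @param power Soft power for both adjacency computations.
#' @param n_perm Number of permutations (>= 50 for a reportable p).
#' @param seed Integer seed for the permutations.
#' @param min_overlap Minimum fraction of module genes present in both
#'   datasets before a warning is raised.
#' @return Tibble `module`, `n_genes`, `density`, `z_density`,
#'   `z_connectivity`, `z_summary`, `p_value`, `p_at_floor`, `n_perm`.
#' @export
module_preservation <- function(ref_expr, test_expr, modules, power = 6,
                                n_perm = 200, seed = 1L, min_overlap = 0.8) {
  mods <- .module_list(modules)
  ref <- .expr_matrix(ref_expr)
  test <- .expr_matrix(test_expr)
  common <- intersect(rownames(ref), rownames(test))
  .assert(length(common) >= 10, "too few genes shared between datasets.")
  if (n_perm < 50) warn("fewer than 50 permutations: p-values are unreliable.")

  stats_for <- function(genes) {
    ra <- abs(cor(t(ref[genes, , drop = FALSE])))^power
    ta <- abs(cor(t(test[genes, , drop = FALSE])))^power
    diag(ra) <- 0; diag(ta) <- 0
    ut <- upper.tri(ta)
    c(density = mean(ta[ut]),
      cor_kim = suppressWarnings(cor(rowSums(ra), rowSums(ta))),
      cor_adj = suppressWarnings(cor(ra[ut], ta[ut])))
  }

  with_seed(seed, {
    rows <- lapply(names(mods), function(nm) {
      genes <- intersect(mods[[nm]], common)
      if (length(genes) / length(mods[[nm]]) < min_overlap) {
        warn(paste0("module ", nm, ": only ",
                    round(100 * length(genes) / length(mods[[nm]])),
                    "% of genes present in both datasets."))
      }
      if (length(genes) < 3) {
        warn(paste0("module ", nm, " skipped: fewer than 3 genes after intersection."))
        return(NULL)
      }
      obs <- stats_for(genes)
      perm <- t(vapply(seq_len(n_perm), function(i) {
        stats_for(sample(common, length(genes)))
      }, c(density = 0, cor_kim = 0, cor_adj = 0)))
      mu <- colMeans(perm, na.rm = TRUE)
      sdev <- apply(perm, 2, sd, na.rm = TRUE)
      z <- (obs - mu) / sdev
      z[!is.finite(z)] <- 0
      z_density <- unname(z["density"])
      z_connectivity <- median(c(z["cor_kim"], z["cor_adj"]), na.rm = TRUE)
      z_summary <- mean(c(z_density, z_connectivity))
      # composite permutation p: standardize each permuted stat the same way
      perm_z <- sweep(sweep(perm, 2, mu), 2, sdev, "/")
      perm_z[!is.finite(perm_z)] <- 0
      comp <- (perm_z[, "density"] +
                 apply(perm_z[, c("cor_kim", "cor_adj"), drop = FALSE], 1, median)) / 2
      n_ge <- sum(comp >= z_summary, na.rm = TRUE)
      tibble(
        module = nm, n_genes = length(genes),
        density = unname(obs["density"]),
        z_density = z_density, z_connectivity = z_connectivity,
        z_summary = z_summary,
        p_value = (1 + n_ge) / (n_perm + 1),
        p_at_floor = n_ge == 0,
        n_perm = n_perm
      )
    })
    bind_rows(rows)
  })
}

.module_list <- function(modules) {
  if (inherits(modules, "eds_modules") ||
      (is.data.frame(modules) && all(c("gene", "module") %in% names(modules)))) {
    mm <- modules[modules$module > 0, ]
    split(mm$gene, mm$module_name %||% paste0("M", mm$module))
  } else if (is.list(modules)) {
    .assert(!is.null(names(modules)), "module list must be named.")
    modules
  } else {
    abort("`modules` must be an eds_modules tibble or a named list of genes.")
  }
}
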