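#' Exact negative-binomial differential expression test
#'
#' Two-group exact test in the NB family: counts are first rescaled to the
#' geometric-mean effective library size (library size times TMM factor),
#' summed within each group and rounded; conditional on the total, the probability of the
#' observed split is evaluated under NB group sums with common dispersion
#' \eqn{\phi} (variance \eqn{\mu + \phi\mu^2}), and the two-sided p-value is
#' twice the smaller tail, capped at 1. With \eqn{\phi = 0} the conditional
#' law is exactly binomial. Fold changes use normalized group means with a 0.5
#' pseudocount; BH adjustment is applied across all tested genes; a gene is
#' flagged differentially expressed when its linear fold change is strictly
#' greater than `fc_threshold` and its adjusted p is below `alpha`.
#'
#' @param counts A count table (see [expression-tables]).
#' @param group Two-level label per sample (column order or named by sample).
#' @param dispersion Common NB dispersion \eqn{\phi >= 0}, or `"estimate"` for
#'   a method-of-moments common value across genes.
#' @param fc_threshold Linear fold-change threshold (strict).
#' @param alpha FDR threshold.
#' @param norm_factors Per-sample scaling factors multiplying the library
#'   sizes (a tibble from [tmm_factors()], a named numeric vector, or `NULL`
#'   to compute TMM factors internally, guarding against compositional bias).
#' @return A tibble `gene`, `log2fc`, `pvalue`, `fdr`, `de`, with the
#'   dispersion used stored in attribute `dispersion`.
#' @export
nb_exact_de <- function(counts, group, dispersion = "estimate",
                        fc_threshold = 1.5, alpha = 0.05,
                        norm_factors = NULL) {
  m <- .count_matrix(counts)
  lv_in <- if (is.factor(group)) levels(group) else NULL
  group <- .per_sample(group, colnames(m), "group")
  # orientation: factor levels when given, else alphabetical; log2fc is
  # second level over first, so relabelling the groups flips its sign
  lv <- lv_in %||% sort(unique(group))
  .assert(length(setdiff(group, lv)) == 0 && length(lv) == 2,
          "`group` must have exactly two levels.")
  n1 <- sum(group == lv[1]); n2 <- sum(group == lv[2])
  .assert(n1 >= 1 && n2 >= 1, "both groups need at least one sample.")

  lib <- colSums(m)
  .assert(all(lib > 0), "library sizes must be positive.")
  f <- if (is.null(norm_factors)) {
    edgeR::calcNormFactors(m, method = "TMM")
  } else if (is.data.frame(norm_factors)) {
    setNames(norm_factors$factor, norm_factors$sample)[colnames(m)]
  } else {
    .per_sample_numeric(norm_factors, colnames(m))
  }
  lib <- lib * f
  geo <- exp(mean(log(lib)))
  pseudo <- sweep(m, 2, geo / lib, "*")

  if (identical(dispersion, "estimate")) {
    dispersion <- .mom_common_dispersion(pseudo, group)
  }
  .assert(is.numeric(dispersion) && dispersion >= 0,
          "`dispersion` must be a nonnegative number or \"estimate\".")

  s1 <- round(rowSums(pseudo[, group == lv[1], drop = FALSE]))
  s2 <- round(rowSums(pseudo[, group == lv[2], drop = FALSE]))
  pval <- vapply(seq_len(nrow(m)), function(i) {
    .exact_nb_p(s1[i], s2[i], n1, n2, dispersion)
  }, 1.0)

  m1 <- rowMeans(pseudo[, group == lv[1], drop = FALSE])
  m2 <- rowMeans(pseudo[, group == lv[2], drop = FALSE])
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  fdr <- p.adjust(pval, "BH")
  out <- tibble(
    gene = rownames(m),
    log2fc = unname(log2fc),
    pvalue = unname(pval),
    fdr = unname(fdr),
    de = 2^abs(log2fc) > fc_threshold & fdr < alpha
  )
  attr(out, "dispersion") <- dispersion
  attr(out, "groups") <- lv
  out
}

# conditional exact two-sided p for group sums s1, s2 from n1, n2 equalized
# libraries under common dispersion phi; doubling the smaller tail, capped
.exact_nb_p <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  k <- 0:s
  if (phi == 0) {
    logp <- dbinom(k, s, n1 / (n1 + n2), log = TRUE)
  } else {
    mhat <- s / (n1 + n2)
    logp <- dnbinom(k, size = n1 / phi, mu = n1 * mhat, log = TRUE) +
      dnbinom(s - k, size = n2 / phi, mu = n2 * mhat, log = TRUE)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  lower <- sum(p[k <= s1])
  upper <- sum(p[k >= s1])
  min(1, 2 * min(lower, upper))
}

# method-of-moments common dispersion on library-equalized counts:
# per-gene phi = (pooled within-group variance - mean) / mean^2, summarised
# by the median across genes and floored at 0
.mom_common_dispersion <- function(pseudo, group) {
  lv <- unique(group)
  resvar <- function(x, g) {
    xs <- split(x, g)
    dfs <- vapply(xs, function(v) length(v) - 1, 1.0)
    if (sum(dfs) <= 0) return(NA_real_)
    sum(vapply(xs, function(v) sum((v - mean(v))^2), 1.0)) / sum(dfs)
  }
  mu <- rowMeans(pseudo)
  v <- apply(pseudo, 1, resvar, g = group)
  ok <- mu > 0 & !is.na(v)
  if (!any(ok)) return(0)
  phi <- (v[ok] - mu[ok]) / mu[ok]^2
  max(0, median(phi))
}

#' Summary counts for a differential-expression table
#' @param de Output of [nb_exact_de()].
#' @return One-row tibble with gene and call counts.
#' @export
de_summary <- function(de) {
  tibble(
    n_genes = nrow(de),
    n_de = sum(de$de),
    n_up = sum(de$de & de$log2fc > 0),
    n_down = sum(de$de & de$log2fc < 0),
    dispersion = attr(de, "dispersion") %||% NA_real_
  )
}
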