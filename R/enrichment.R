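#' Category enrichment odds ratio with exact binomial test
#'
#' Given `k_set` of `n_set` genes in a category within a gene set and
#' `k_genome` of `n_genome` genome-wide, computes p1 = k_set/n_set, p2 =
#' k_genome/n_genome, the odds ratio
#' \deqn{odds = (p1 / (1 - p1)) / (p2 / (1 - p2)),}
#' and an exact binomial test of `k_set` successes in `n_set` trials at
#' success probability p2. The two-sided test is the default (it reproduces
#' published retention-table p-values); `alternative = "greater"` gives the
#' upper-tail enrichment test.
#'
#' @param k_set,n_set Category count and total within the gene set.
#' @param k_genome,n_genome Category count and total genome-wide.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return One-row tibble: `k_set`, `n_set`, `k_genome`, `n_genome`, `p1`,
#'   `p2`, `odds`, `odds_2dec` (truncated to two decimals, the convention of
#'   printed retention tables), `p_value`.
#' @export
category_odds_ratio <- function(k_set, n_set, k_genome, n_genome,
                                alternative = "two.sided") {
  .assert(n_set > 0 && n_genome > 0, "totals must be positive.")
  .assert(k_set >= 0 && k_set <= n_set && k_genome >= 0 && k_genome <= n_genome,
          "counts must lie in [0, total].")
  p1 <- k_set / n_set
  p2 <- k_genome / n_genome
  if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1) {
    abort("degenerate proportion (0 or 1): odds ratio undefined.")
  }
  odds <- (p1 / (1 - p1)) / (p2 / (1 - p2))
  tibble(
    k_set = k_set, n_set = n_set, k_genome = k_genome, n_genome = n_genome,
    p1 = p1, p2 = p2, odds = odds, odds_2dec = trunc(odds * 100) / 100,
    p_value = binom.test(k_set, n_set, p2, alternative = alternative)$p.value
  )
}

#' Exact binomial tail probability
#'
#' Upper-tail by default: \eqn{P(X \ge k)} for \eqn{X \sim Binomial(n, p0)},
#' summed exactly.
#'
#' @param k Observed successes (0 <= k <= n).
#' @param n Trials.
#' @param p0 Null success probability (0 < p0 < 1).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return The exact p-value.
#' @export
binomial_enrichment <- function(k, n, p0, alternative = "greater") {
  .assert(k >= 0 && k <= n, "`k` must lie in [0, n].")
  .assert(p0 > 0 && p0 < 1, "`p0` must lie strictly in (0, 1).")
  switch(alternative,
    greater = sum(dbinom(k:n, n, p0)),
    less = sum(dbinom(0:k, n, p0)),
    two.sided = binom.test(k, n, p0)$p.value,
    abort("unknown alternative")
  )
}

#' Chi-square test of preferential pair retention
#'
#' For `n_pairs` duplicate pairs (2 x n_pairs genes) of which `m_in_module`
#' genes are in the module and `observed_both` pairs have both members in the
#' module: under independent recruitment each gene enters the module with
#' probability q = m / (2 n_pairs), so the (0, 1, 2)-members-in-module pair
#' counts are Binomial(2, q) multiples of n_pairs. The observed 1-member count
#' is m - 2 x observed_both. Pearson's chi-square with 2 degrees of freedom
#' compares observed to expected; when any expected category count is below 1
#' an exact multinomial p-value is substituted (enumeration for small
#' n_pairs, otherwise a warning is kept with the chi-square p).
#'
#' @param n_pairs Number of duplicate pairs.
#' @param m_in_module Pair-member genes found in the module.
#' @param observed_both Pairs with both members in the module.
#' @return One-row tibble: `n_pairs`, `n_genes`, `m_in_module`,
#'   `observed_both`, `expected_both`, `chi_sq`, `df`, `p_value`, `method`.
#' @export
pair_retention_chi2 <- function(n_pairs, m_in_module, observed_both) {
  .assert(m_in_module <= 2 * n_pairs, "`m_in_module` cannot exceed 2 x n_pairs.")
  .assert(observed_both <= min(n_pairs, floor(m_in_module / 2)),
          "`observed_both` inconsistent with the totals.")
  q <- m_in_module / (2 * n_pairs)
  p_cat <- dbinom(0:2, 2, q)
  expected <- n_pairs * p_cat
  obs1 <- m_in_module - 2 * observed_both
  observed <- c(n_pairs - observed_both - obs1, obs1, observed_both)
  .assert(all(observed >= 0), "inconsistent category counts.")
  chi_sq <- sum((observed - expected)^2 / expected)
  method <- "chi-square"
  p <- pchisq(chi_sq, df = 2, lower.tail = FALSE)
  if (any(expected < 1)) {
    if (n_pairs <= 200) {
      method <- "exact multinomial"
      p <- .multinomial_exact_p(observed, p_cat)
    } else {
      warn("expected category count below 1; chi-square p is approximate.")
    }
  }
  tibble(
    n_pairs = n_pairs, n_genes = 2 * n_pairs, m_in_module = m_in_module,
    observed_both = observed_both, expected_both = expected[3],
    chi_sq = chi_sq, df = 2L, p_value = p, method = method
  )
}

# exact multinomial tail: total probability of outcomes no more probable
# than the observed one
.multinomial_exact_p <- function(observed, p_cat) {
  n <- sum(observed)
  p_obs <- stats::dmultinom(observed, prob = p_cat)
  p <- 0
  for (a in 0:n) {
    for (b in 0:(n - a)) {
      pr <- stats::dmultinom(c(a, b, n - a - b), prob = p_cat)
      if (pr <= p_obs + 1e-12) p <- p + pr
    }
  }
  min(1, p)
}

#' Upstream TE-insertion enrichment in a gene set
#'
#' Flags every gene carrying at least one insertion of the given TE family
#' with upstream distance less than or equal to `window_bp` (inclusive), then
#' tests enrichment of flagged genes in `gene_set` against the whole universe
#' via [category_odds_ratio()].
#'
#' @param gene_set Character vector of gene ids (subset of `universe`).
#' @param universe Character vector of all gene ids considered.
#' @param insertions Tibble `gene`, `family`, `distance` (bp upstream of the
#'   transcription start, >= 0).
#' @param family TE family to score.
#' @param window_bp Window size in bp (inclusive, default 1000).
#' @param alternative Test sidedness (default upper tail).
#' @return One-row tibble as [category_odds_ratio()], with a `flagged_set` /
#'   `flagged_genome` naming convention via `k_set` / `k_genome`. When no gene
#'   is flagged the odds ratio is undefined and `p_value` is 1 with zero
#'   counts.
#' @export
upstream_te_enrichment <- function(gene_set, universe, insertions, family,
                                   window_bp = 1000,
                                   alternative = "greater") {
  .assert(length(universe) > 0, "`universe` must not be empty.")
  .assert(all(gene_set %in% universe), "`gene_set` must be a subset of `universe`.")
  .assert(all(insertions$distance >= 0), "insertion distances must be >= 0.")
  hit <- insertions |>
    filter(.data$family == !!family, .data$distance <= window_bp) |>
    pull("gene") |>
    unique()
  k_set <- sum(gene_set %in% hit)
  k_genome <- sum(universe %in% hit)
  if (k_genome == 0 || k_set == length(gene_set) ||
      k_genome == length(universe)) {
    return(tibble(
      k_set = k_set, n_set = length(gene_set),
      k_genome = k_genome, n_genome = length(universe),
      p1 = k_set / length(gene_set), p2 = k_genome / length(universe),
      odds = NA_real_, odds_2dec = NA_real_,
      p_value = if (k_genome == 0) 1 else NA_real_
    ))
  }
  category_odds_ratio(k_set, length(gene_set), k_genome, length(universe),
                      alternative = alternative)
}

#' Retention-enrichment report (published-table layout)
#'
#' Recomputes, for each gene set x category row, the within-set and
#' genome-wide proportions, the odds ratio (full precision and truncated to
#' two decimals as in printed tables) and the exact binomial p-value.
#'
#' @param counts Tibble with columns `set`, `category`, `k_set`, `n_set`,
#'   `k_genome`, `n_genome`.
#' @param alternative Binomial test sidedness (two-sided reproduces the
#'   published tables).
#' @return `counts` with `p1`, `p2`, `odds`, `odds_2dec`, `p_value` appended.
#' @export
retention_report <- function(counts, alternative = "two.sided") {
  need <- c("set", "category", "k_set", "n_set", "k_genome", "n_genome")
  .assert(all(need %in% names(counts)),
          paste0("`counts` needs columns: ", paste(need, collapse = ", ")))
  res <- pmap(counts[c("k_set", "n_set", "k_genome", "n_genome")],
              category_odds_ratio, alternative = alternative)
  bind_cols(counts[c("set", "category")],
            bind_rows(res))
}
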