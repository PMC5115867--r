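#' Ka, Ks and omega for a pairwise codon alignment (NG86 counting)
#'
#' Nei--Gojobori-style counting: synonymous site counts average the per-codon
#' degeneracies of the two sequences (changes creating stop codons are counted
#' as nonsynonymous so that N + S = 3 x codons compared); substitution counts
#' for codons differing at several positions average over all minimal mutation
#' pathways that avoid stop codons (all pathways, with stop steps counted
#' nonsynonymous, in the rare case every pathway is blocked). The
#' Jukes--Cantor correction \eqn{d = -3/4 \log(1 - 4p/3)} converts proportions
#' pN, pS into Ka, Ks. Pairs with Ks < `ks_min` are flagged `excluded`
#' (omega unreliable at negligible synonymous divergence); proportions at or
#' above 3/4 are flagged `saturated` and give `NA` distances.
#'
#' Gapped codons (and codons with ambiguous bases or stops) are dropped and
#' counted in `codons_dropped`. Outputs are symmetric in the two sequences.
#'
#' @param seq1,seq2 Nucleotide strings of equal length (multiple of 3).
#' @param ks_min Exclusion threshold on Ks (default 0.02).
#' @return One-row tibble: `n_codons`, `codons_dropped`, `N`, `S`, `Nd`, `Sd`,
#'   `pN`, `pS`, `Ka`, `Ks`, `omega`, `excluded`, `saturated`.
#' @export
ng86_kaks <- function(seq1, seq2, ks_min = 0.02) {
  s1 <- toupper(as.character(seq1))
  s2 <- toupper(as.character(seq2))
  .assert(nchar(s1) == nchar(s2), "sequences must be the same length.")
  .assert(nchar(s1) %% 3 == 0, "alignment length must be a multiple of 3.")
  code <- .codon_code()
  c1 <- substring(s1, seq(1, nchar(s1), 3), seq(3, nchar(s1), 3))
  c2 <- substring(s2, seq(1, nchar(s2), 3), seq(3, nchar(s2), 3))
  valid <- function(x) {
    idx <- match(x, code$codons)
    res <- !is.na(idx)
    res[res] <- unlist(code$aa[idx[res]]) != "*"
    res
  }
  ok <- valid(c1) & valid(c2)
  dropped <- sum(!ok)
  c1 <- c1[ok]; c2 <- c2[ok]
  .assert(length(c1) > 0, "no comparable codons left.")

  sites <- (.codon_sites(c1) + .codon_sites(c2)) / 2
  S <- sum(sites)
  N <- 3 * length(c1) - S
  subs <- purrr::map2(c1, c2, .codon_differences)
  Sd <- sum(map_dbl(subs, "syn"))
  Nd <- sum(map_dbl(subs, "nonsyn"))

  pN <- Nd / N
  pS <- Sd / S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ka <- jc(pN)
  Ks <- jc(pS)
  saturated <- pN >= 0.75 || pS >= 0.75
  excluded <- !saturated && Ks < ks_min
  omega <- if (saturated || excluded || Ks == 0) NA_real_ else Ka / Ks
  tibble(
    n_codons = length(c1), codons_dropped = dropped,
    N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
    Ka = Ka, Ks = Ks, omega = omega,
    excluded = excluded, saturated = saturated
  )
}

# synonymous site count per codon: for each position, the fraction of the 3
# alternative nucleotides that preserve the amino acid (stop-creating changes
# count as nonsynonymous)
.codon_sites <- local({
  cache <- NULL
  function(codons) {
    if (is.null(cache)) {
      code <- .codon_code()
      nts <- c("A", "C", "G", "T")
      syn <- setNames(numeric(length(code$sense)), code$sense)
      for (cod in code$sense) {
        s <- 0
        chars <- strsplit(cod, "")[[1]]
        for (pos in 1:3) {
          for (alt in setdiff(nts, chars[pos])) {
            mut <- chars
            mut[pos] <- alt
            if (code$aa[[paste(mut, collapse = "")]] == code$aa[[cod]]) {
              s <- s + 1 / 3
            }
          }
        }
        syn[cod] <- s
      }
      cache <<- syn
    }
    cache[codons]
  }
})

# average synonymous / nonsynonymous substitution counts between two codons
# over minimal mutation pathways avoiding stops
.codon_differences <- function(cod1, cod2) {
  if (cod1 == cod2) return(list(syn = 0, nonsyn = 0))
  code <- .codon_code()
  pos <- which(strsplit(cod1, "")[[1]] != strsplit(cod2, "")[[1]])
  perms <- .permutations(pos)
  step_counts <- function(order_pos, allow_stop) {
    cur <- strsplit(cod1, "")[[1]]
    tgt <- strsplit(cod2, "")[[1]]
    syn <- 0; nonsyn <- 0
    for (p in order_pos) {
      nxt <- cur
      nxt[p] <- tgt[p]
      aa_from <- code$aa[[paste(cur, collapse = "")]]
      aa_to <- code$aa[[paste(nxt, collapse = "")]]
      if (aa_to == "*" && !allow_stop) return(NULL)
      if (aa_from == aa_to) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  paths <- purrr::compact(lapply(perms, step_counts, allow_stop = FALSE))
  if (length(paths) == 0) {
    paths <- lapply(perms, step_counts, allow_stop = TRUE)
  }
  avg <- Reduce(`+`, paths) / length(paths)
  list(syn = unname(avg["syn"]), nonsyn = unname(avg["nonsyn"]))
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in .permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Batch Ka/Ks over a list of codon pairs
#' @param pairs Named list of length-2 character vectors (as from
#'   [simulate_codon_pairs()] or [read_codon_pairs()]).
#' @param ks_min Exclusion threshold on Ks.
#' @return Tibble with one row per pair (`pair` column first) including the
#'   one-sided `p_omega_lt_1` of [omega_test()].
#' @export
kaks_pairs <- function(pairs, ks_min = 0.02) {
  bind_rows(imap(pairs, function(p, nm) {
    row <- ng86_kaks(p[[1]], p[[2]], ks_min = ks_min)
    row$p_omega_lt_1 <- omega_test(row)
    mutate(row, pair = nm, .before = 1)
  }))
}

#' One-sided test of omega < 1
#'
#' Fisher's exact test on the 2x2 table with rows (nonsynonymous, synonymous)
#' and columns (substituted, unsubstituted sites); counts are rounded to the
#' nearest integer for the table only. The alternative is that the
#' nonsynonymous substitution proportion is below the synonymous one
#' (purifying selection, omega < 1). Excluded or saturated results give `NA`;
#' a zero-margin table gives p = 1.
#'
#' @param result A row from [ng86_kaks()], or a list with `N`, `S`, `Nd`,
#'   `Sd` (and optional `excluded`/`saturated` flags).
#' @return One-sided p-value.
#' @export
omega_test <- function(result) {
  if (isTRUE(result$excluded) || isTRUE(result$saturated)) return(NA_real_)
  tab <- matrix(round(c(result$Nd, result$N - result$Nd,
                        result$Sd, result$S - result$Sd)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("nonsyn", "syn"),
                                c("substituted", "unsubstituted")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  fisher.test(tab, alternative = "less")$p.value
}

#' Rank-test comparison of two value distributions
#'
#' Convenience wrapper for the distribution contrasts used downstream (e.g.
#' module omega values vs genome-wide): a Wilcoxon--Mann--Whitney or
#' Kruskal--Wallis rank test.
#'
#' @param x,y Numeric vectors (NAs dropped).
#' @param method `"wilcoxon"` or `"kruskal"`.
#' @param alternative Passed to [wilcox.test()] (ignored for Kruskal--Wallis).
#' @return One-row tibble `method`, `statistic`, `p_value`, `median_x`,
#'   `median_y`.
#' @export
rank_compare <- function(x, y, method = c("wilcoxon", "kruskal"),
                         alternative = "two.sided") {
  method <- match.arg(method)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (method == "wilcoxon") {
    ht <- wilcox.test(x, y, alternative = alternative, exact = FALSE)
  } else {
    ht <- kruskal.test(list(x, y))
  }
  tibble(method = method, statistic = unname(ht$statistic),
         p_value = ht$p.value, median_x = median(x), median_y = median(y))
}
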