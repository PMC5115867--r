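#' Simulate pairwise codon alignments with known omega and Ks
#'
#' Each pair starts from a random ancestor of `n_codons` sense codons; one
#' copy then accumulates point substitutions under a codon-level
#' accept/reject process: attempted changes arrive uniformly over positions at
#' rate `target_ks` per site, synonymous changes are always accepted,
#' nonsynonymous changes are accepted with probability `omega`, and changes
#' creating a stop codon are rejected. Under this process the expected
#' synonymous divergence per synonymous site is `target_ks` and the
#' nonsynonymous/synonymous rate ratio is `omega`; multiple hits are allowed
#' (the substitutions are applied sequentially), so distance correction in the
#' estimator is exercised.
#'
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param target_ks Expected synonymous substitutions per synonymous site
#'   (>= 0).
#' @param n_codons Codons per alignment (>= 50).
#' @param n_pairs Number of pairs.
#' @param seed Integer seed.
#'
#' @return A list with `pairs` (list of length-2 character vectors, the two
#'   gapless stop-free sequences) and `truth` (tibble: `pair`, `omega`, `ks`).
#' @export
simulate_codon_pairs <- function(omega, target_ks, n_codons = 300,
                                 n_pairs = 1, seed = 1L) {
  .assert(omega >= 0, "`omega` must be >= 0.")
  .assert(target_ks >= 0, "`target_ks` must be >= 0.")
  .assert(n_codons >= 50, "`n_codons` must be >= 50.")
  code <- .codon_code()
  sense <- code$sense
  with_seed(seed, {
    pairs <- lapply(seq_len(n_pairs), function(i) {
      anc <- sample(sense, n_codons, replace = TRUE)
      der <- .evolve_codons(anc, omega, target_ks, code)
      c(paste(anc, collapse = ""), paste(der, collapse = ""))
    })
    names(pairs) <- sprintf("pair%04d", seq_len(n_pairs))
    list(
      pairs = pairs,
      truth = tibble(pair = names(pairs), omega = omega, ks = target_ks)
    )
  })
}

.evolve_codons <- function(codons, omega, rate, code) {
  n_pos <- 3L * length(codons)
  n_events <- rpois(1, rate * n_pos)
  if (n_events == 0) return(codons)
  nts <- c("A", "C", "G", "T")
  for (e in seq_len(n_events)) {
    pos <- sample.int(n_pos, 1)
    ci <- (pos - 1L) %/% 3L + 1L
    off <- (pos - 1L) %% 3L + 1L
    cod <- strsplit(codons[ci], "")[[1]]
    alt <- sample(setdiff(nts, cod[off]), 1)
    new <- cod
    new[off] <- alt
    new_codon <- paste(new, collapse = "")
    aa_old <- code$aa[[codons[ci]]]
    aa_new <- code$aa[[new_codon]]
    if (aa_new == "*") next            # stops never emitted
    if (aa_new == aa_old || runif(1) < omega) codons[ci] <- new_codon
  }
  codons
}

# cached genetic-code tables (standard code, from Biostrings)
.codon_code <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      codons <- names(gc)
      aa <- as.list(gc)
      cache <<- list(
        aa = aa,
        codons = codons,
        sense = codons[unlist(aa) != "*"]
      )
    }
    cache
  }
})
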