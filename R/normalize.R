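#' @rdname expression-tables
#' @name expression-tables
#' @title Tabular expression containers
#'
#' @description Count tables are tibbles with a `gene` column, a `length`
#' column (bp) and one integer column per sample. Expression tables are
#' tibbles with a `gene` column and one numeric column per sample, carrying a
#' `transforms` attribute (`"tmm_fpkm"`, `"log2"`, `"batch_adjusted"`) that
#' records the provenance of the values.
NULL

.count_matrix <- function(counts) {
  .assert(all(c("gene", "length") %in% names(counts)),
          "count table needs `gene` and `length` columns.")
  m <- as.matrix(counts[, setdiff(names(counts), c("gene", "length"))])
  .assert(is.numeric(m) && all(m >= 0) && all(m == round(m)),
          "counts must be nonnegative integers.")
  .assert(all(counts$length > 0), "gene lengths must be positive.")
  rownames(m) <- counts$gene
  storage.mode(m) <- "double"
  m
}

.expr_matrix <- function(expr) {
  .assert("gene" %in% names(expr), "expression table needs a `gene` column.")
  m <- as.matrix(expr[, setdiff(names(expr), c("gene", "length"))])
  rownames(m) <- expr$gene
  m
}

.expr_table <- function(m, transforms) {
  out <- bind_cols(tibble(gene = rownames(m)), as_tibble(m))
  attr(out, "transforms") <- transforms
  out
}

#' Transform flags of an expression table
#' @param expr An expression table.
#' @return Character vector of transform flags.
#' @export
transforms <- function(expr) attr(expr, "transforms") %||% character()

#' Trimmed mean of M-values scaling factors
#'
#' Computes TMM scaling factors (one per sample) against a reference sample,
#' trimming the most extreme log-ratios (M) and log-abundances (A) and
#' weighting by inverse asymptotic variance. The factors are rescaled so their
#' geometric mean is 1. The computation is delegated to
#' [edgeR::calcNormFactors()], the field-standard implementation of this
#' estimator.
#'
#' @param counts A count table (see [expression-tables]).
#' @param reference Reference sample name, or `NULL` to pick the sample whose
#'   upper quartile is closest to the mean upper quartile.
#' @param trim_m Fraction of M-values trimmed on each side (default 0.3).
#' @param trim_a Fraction of A-values trimmed on each side (default 0.05).
#' @return Tibble with `sample`, `lib_size`, `factor`.
#' @export
tmm_factors <- function(counts, reference = NULL, trim_m = 0.3, trim_a = 0.05) {
  m <- .count_matrix(counts)
  .assert(ncol(m) >= 2, "TMM needs at least two samples.")
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(paste0("sample(s) with all-zero counts: ",
                 paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  ref_col <- if (is.null(reference)) NULL else {
    .assert(reference %in% colnames(m), "unknown reference sample.")
    match(reference, colnames(m))
  }
  f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref_col,
                              logratioTrim = trim_m, sumTrim = trim_a)
  tibble(sample = colnames(m), lib_size = unname(lib), factor = unname(f))
}

#' FPKM matrix on TMM-effective library sizes
#'
#' FPKM = count / (length in kb x effective library size in millions), with
#' effective library size = library size x TMM factor.
#'
#' @param counts A count table.
#' @param factors Output of [tmm_factors()] (or any tibble with `sample`,
#'   `factor`).
#' @return An expression table flagged `tmm_fpkm`.
#' @export
fpkm_matrix <- function(counts, factors) {
  m <- .count_matrix(counts)
  f <- factors$factor[match(colnames(m), factors$sample)]
  .assert(!anyNA(f), "`factors` must cover every sample.")
  eff <- colSums(m) * f
  fpkm <- sweep(m, 2, eff / 1e6, "/") / (counts$length / 1e3)
  .expr_table(fpkm, "tmm_fpkm")
}

#' Expressed-gene filter
#'
#' A gene is retained when its value is strictly greater than `min_value` in
#' at least `min_samples` samples (default: FPKM > 5 in >= 3 samples).
#'
#' @param expr An expression table flagged `tmm_fpkm`.
#' @param min_value Threshold (strict).
#' @param min_samples Minimum number of samples exceeding it.
#' @return The filtered expression table.
#' @export
filter_expressed <- function(expr, min_value = 5, min_samples = 3) {
  .assert("tmm_fpkm" %in% transforms(expr),
          "`expr` must carry the tmm_fpkm flag.")
  m <- .expr_matrix(expr)
  keep <- rowSums(m > min_value) >= min_samples
  out <- expr[keep, , drop = FALSE]
  attr(out, "transforms") <- transforms(expr)
  out
}

#' Log2 transform with pseudocount
#' @param expr An expression table.
#' @param pseudo Pseudocount added before log2 (default 1).
#' @return The expression table with the `log2` flag added.
#' @export
log2_expr <- function(expr, pseudo = 1) {
  m <- log2(.expr_matrix(expr) + pseudo)
  .expr_table(m, union(transforms(expr), "log2"))
}

#' Cross-species empirical-Bayes batch adjustment
#'
#' Removes per-gene location/scale differences between species (batches) while
#' preserving treatment effects, via the parametric empirical-Bayes adjustment
#' of [sva::ComBat()] (normal prior on locations, inverse-gamma on scales).
#' Input must be log-scaled.
#'
#' @param expr A log2 expression table.
#' @param batch Batch (species) label per sample, in column order or named by
#'   sample.
#' @param covariates Optional covariate (treatment) label per sample whose
#'   effect must be preserved.
#' @return The adjusted expression table, flagged `batch_adjusted`.
#' @export
batch_adjust <- function(expr, batch, covariates = NULL) {
  .assert("log2" %in% transforms(expr), "`expr` must be log2-scaled.")
  m <- .expr_matrix(expr)
  batch <- .per_sample(batch, colnames(m), "batch")
  tab <- table(batch)
  if (any(tab < 2)) {
    abort(paste0("batch(es) with a single sample: ",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  if (length(tab) == 1L) return(expr)
  mod <- NULL
  if (!is.null(covariates)) {
    covariates <- .per_sample(covariates, colnames(m), "covariates")
    mod <- model.matrix(~ factor(covariates))
  }
  # ComBat drops genes with zero within-batch variance; guard them
  ok <- apply(m, 1, function(x) all(tapply(x, batch, var) > 0))
  adj <- m
  if (any(ok)) {
    fit <- suppressMessages(
      sva::ComBat(dat = m[ok, , drop = FALSE], batch = batch, mod = mod,
                  par.prior = TRUE)
    )
    adj[ok, ] <- fit
  }
  if (!all(ok)) {
    warn(paste0(sum(!ok), " gene(s) with zero within-batch variance left unadjusted."))
  }
  .expr_table(adj, union(transforms(expr), "batch_adjusted"))
}

.per_sample_numeric <- function(x, samples) {
  if (!is.null(names(x))) {
    .assert(all(samples %in% names(x)), "factors must cover every sample.")
    x <- x[samples]
  }
  .assert(length(x) == length(samples), "one factor per sample required.")
  as.numeric(x)
}

.per_sample <- function(x, samples, what) {
  if (!is.null(names(x))) {
    .assert(all(samples %in% names(x)),
            paste0("`", what, "` must be named by sample or given in column order."))
    x <- x[samples]
  }
  .assert(length(x) == length(samples),
          paste0("`", what, "` must have one value per sample."))
  as.character(x)
}
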