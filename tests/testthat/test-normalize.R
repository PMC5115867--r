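test_that("TMM factors are 1 for duplicated or rescaled columns", {
  set.seed(1)
  base <- rpois(50, 60) + 1
  m <- cbind(s1 = base, s2 = base, s3 = base)
  f <- tmm_factors(toy_counts(m))
  expect_equal(f$factor, rep(1, 3), tolerance = 1e-12)

  m2 <- cbind(s1 = base, s2 = 2L * base)
  f2 <- tmm_factors(toy_counts(m2))
  expect_equal(f2$factor, rep(1, 2), tolerance = 1e-12)

  expect_equal(prod(f$factor)^(1 / 3), 1, tolerance = 1e-12)
  expect_error(tmm_factors(toy_counts(cbind(s1 = base, s2 = 0L * base))), "s2")
})

test_that("TMM matches a hand-rolled weighted trimmed-mean oracle", {
  # oracle: the weighted trimmed mean of M-values against a reference column,
  # computed directly from the definition (double trimming on M and A,
  # inverse-variance weights), on a table without zero counts
  set.seed(42)
  m <- matrix(rpois(400, 100) + 1, 100, 4,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
  m[1:5, 1] <- m[1:5, 1] * 20   # a few inflated genes break the symmetry
  f <- tmm_factors(toy_counts(m), reference = "s2")

  tmm_oracle <- function(obs, ref) {
    no <- sum(obs); nr <- sum(ref)
    keep <- obs > 0 & ref > 0
    M <- log2((obs / no) / (ref / nr))[keep]
    A <- (log2(obs / no) + log2(ref / nr))[keep] / 2
    v <- ((no - obs) / (no * obs) + (nr - ref) / (nr * ref))[keep]
    nk <- length(M)
    loM <- floor(nk * 0.3) + 1; hiM <- nk + 1 - loM
    loA <- floor(nk * 0.05) + 1; hiA <- nk + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[sel] / v[sel]) / sum(1 / v[sel]))
  }
  raw <- vapply(1:4, function(j) tmm_oracle(m[, j], m[, 2]), 1.0)
  raw <- raw / exp(mean(log(raw)))
  expect_equal(f$factor, unname(raw), tolerance = 1e-8)
})

test_that("FPKM arithmetic and scale invariance", {
  m <- matrix(c(1, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  cnt <- toy_counts(m, lengths = c(1000L, 500L))
  f <- tibble::tibble(sample = "s1", lib_size = 11, factor = 1e6 / 11)
  fp <- fpkm_matrix(cnt, f)
  expect_equal(fp$s1, c(1, 20))  # 1 read / 1 kb / 1 M effective reads

  set.seed(2)
  m2 <- matrix(rpois(60, 50) + 1, 20, 3,
               dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:3)))
  cnt2 <- toy_counts(m2)
  fac2 <- tibble::tibble(sample = paste0("s", 1:3), factor = 1)
  fp2 <- fpkm_matrix(cnt2, fac2)
  m3 <- m2; m3[, 2] <- m3[, 2] * 2L
  fp3 <- fpkm_matrix(toy_counts(m3), fac2)
  expect_equal(fp2$s2, fp3$s2, tolerance = 1e-12)

  # hand-computed 3 x 2 toy
  m4 <- matrix(c(10, 0, 5, 20, 10, 0), 3, 2,
               dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  cnt4 <- toy_counts(m4, lengths = c(2000L, 500L, 1000L))
  fac4 <- tibble::tibble(sample = c("s1", "s2"), factor = c(1, 1))
  fp4 <- fpkm_matrix(cnt4, fac4)
  lib <- colSums(m4)
  expect_equal(fp4$s1, m4[, 1] / (c(2, 0.5, 1) * lib[1] / 1e6),
               ignore_attr = TRUE)
  expect_equal(fp4$s2, m4[, 2] / (c(2, 0.5, 1) * lib[2] / 1e6),
               ignore_attr = TRUE)
})

test_that("expression filter applies a strict threshold", {
  m <- rbind(
    zero = c(0, 0, 0, 0),
    boundary = c(5, 5, 5, 5),
    justover = c(5.1, 5.1, 5.1, 0),
    twoonly = c(9, 9, 0, 0)
  )
  colnames(m) <- paste0("s", 1:4)
  fe <- filter_expressed(toy_expr(m, "tmm_fpkm"))
  expect_identical(fe$gene, "justover")
})

test_that("batch adjustment removes location shifts and respects guards", {
  set.seed(3)
  n <- 60
  batch <- rep(c("A", "B"), each = 4)
  # identical per-sample noise for every gene: the per-gene batch effects are
  # then all equal, the EB prior is degenerate at the true shift and the
  # adjustment equalizes batch means exactly
  e <- rnorm(8)
  mu <- rnorm(n, 8)
  m <- outer(mu, rep(1, 8)) + matrix(e, n, 8, byrow = TRUE)
  dimnames(m) <- list(sprintf("g%02d", 1:n), paste0("s", 1:8))
  m[, batch == "B"] <- m[, batch == "B"] + 2
  expr <- toy_expr(m, c("tmm_fpkm", "log2"))
  adj <- batch_adjust(expr, batch)
  am <- as.matrix(adj[, -1])
  gap <- rowMeans(am[, batch == "A"]) - rowMeans(am[, batch == "B"])
  expect_lt(max(abs(gap)), 1e-6)
  expect_true("batch_adjusted" %in% transforms(adj))

  # noisy per-gene batch effects: EB shrinkage leaves per-gene residuals but
  # removes the bulk of the shift
  base <- matrix(rnorm(n * 8, 8), n, 8,
                 dimnames = list(sprintf("g%02d", 1:n), paste0("s", 1:8)))
  m2 <- base
  m2[, batch == "B"] <- m2[, batch == "B"] + rnorm(n, 2)
  adj2 <- batch_adjust(toy_expr(m2, c("tmm_fpkm", "log2")), batch)
  am2 <- as.matrix(adj2[, -1])
  gap2 <- rowMeans(am2[, batch == "A"]) - rowMeans(am2[, batch == "B"])
  expect_lt(mean(abs(gap2)), 0.6)
  expect_lt(abs(mean(gap2)), 0.2)

  # single batch: identity
  one <- batch_adjust(expr, rep("A", 8))
  expect_equal(as.matrix(one[, -1]), m, tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(batch_adjust(expr, c("A", rep("B", 7))), "single sample")
  expect_error(batch_adjust(toy_expr(m, "tmm_fpkm"), batch), "log2")
})

test_that("batch scale differences shrink toward equality", {
  set.seed(4)
  n <- 300
  batch <- rep(c("A", "B"), each = 10)
  m <- matrix(rnorm(n * 20, 8), n, 20,
              dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:20)))
  m[, batch == "B"] <- 8 + (m[, batch == "B"] - 8) * 2
  adj <- batch_adjust(toy_expr(m, c("tmm_fpkm", "log2")), batch)
  am <- as.matrix(adj[, -1])
  va <- apply(am[, batch == "A"], 1, var)
  vb <- apply(am[, batch == "B"], 1, var)
  expect_lt(abs(median(vb) / median(va) - 1), 0.10)
})
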