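#' Weighted co-expression network with topological overlap
#'
#' Builds the adjacency matrix \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} (unsigned,
#' default) or \eqn{((1 + cor)/2)^\beta} (signed) and the unsigned topological
#' overlap matrix
#' \deqn{TOM_{ij} = (L_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 - a_{ij}),}
#' where \eqn{L_{ij} = \sum_u a_{iu} a_{uj}} and \eqn{k_i = \sum_u a_{iu}}
#' (diagonal excluded). `TOM[i,i]` is fixed at 1 by convention.
#'
#' @param expr An expression table (genes in rows).
#' @param power Soft-thresholding power \eqn{\beta > 0}.
#' @param signed Use the signed adjacency transform.
#' @return An `eds_network`: list with `genes`, `adjacency`, `tom`, `config`.
#' @export
build_network <- function(expr, power, signed = FALSE) {
  m <- .expr_matrix(expr)
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    abort(paste0("zero-variance gene(s): ",
                 paste(head(rownames(m)[v == 0], 5), collapse = ", ")))
  }
  cc <- cor(t(m))
  a <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
  diag(a) <- 0
  tom <- .tom(a)
  structure(
    list(genes = rownames(m), adjacency = a, tom = tom,
         config = list(power = power, signed = signed, correlation = "pearson")),
    class = "eds_network"
  )
}

.tom <- function(a) {
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' @export
print.eds_network <- function(x, ...) {
  cat("Co-expression network:", length(x$genes), "genes, beta =",
      x$config$power, if (x$config$signed) "(signed)" else "(unsigned)", "\n")
  invisible(x)
}

#' Rank genes by soft connectivity and select the top k
#'
#' Soft connectivity is the adjacency row sum \eqn{k_i = \sum_{j \ne i}
#' |cor(x_i, x_j)|^\beta}. Ties are broken by gene identifier (lexicographic),
#' so the selection is deterministic.
#'
#' @param expr An expression table.
#' @param k Number of genes to keep (>= 1); all genes if `k >= n`.
#' @param power Soft power used for the connectivity.
#' @return Tibble `gene`, `connectivity`, `rank`, `selected`.
#' @export
select_top_connected <- function(expr, k = 5000, power = 6) {
  .assert(k >= 1, "`k` must be >= 1.")
  m <- .expr_matrix(expr)
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    warn(paste0(sum(v == 0), " zero-variance gene(s) ranked last."))
  }
  a <- abs(cor(t(m[v > 0, , drop = FALSE])))^power
  diag(a) <- 0
  conn <- setNames(rep(0, nrow(m)), rownames(m))
  conn[rownames(a)] <- rowSums(a)
  ord <- order(-conn, names(conn), method = "radix")
  out <- tibble(
    gene = names(conn)[ord],
    connectivity = unname(conn[ord]),
    rank = seq_along(conn)
  )
  mutate(out, selected = .data$rank <= k)
}

#' Choose the soft-thresholding power by scale-free fit
#'
#' For each candidate power the connectivity distribution is binned
#' (`n_breaks` equal-width bins of k), and \eqn{\log_{10} p(k)} is regressed
#' on \eqn{\log_{10} \bar k}; the signed fit index is \eqn{R^2} times the sign
#' of the negative slope. The chosen power is the smallest candidate whose
#' signed \eqn{R^2} reaches `r2_target`; if none does, the candidate
#' maximizing it is returned with `reached_target = FALSE`.
#'
#' @param expr An expression table.
#' @param candidates Candidate powers.
#' @param r2_target Required signed scale-free fit R^2.
#' @param signed Signed adjacency transform.
#' @param n_breaks Connectivity bins for the fit.
#' @return List with `power`, `reached_target` and `fit` (tibble `power`,
#'   `r_squared`, `slope`, `mean_k`).
#' @export
pick_soft_power <- function(expr, candidates = 1:20, r2_target = 0.8,
                            signed = FALSE, n_breaks = 10) {
  m <- .expr_matrix(expr)
  .assert(ncol(m) >= 3, "at least 3 samples are required.")
  if (ncol(m) < 8) warn("fewer than 8 samples: scale-free fit is unstable.")
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    warn(paste0(sum(v == 0), " zero-variance gene(s) dropped before fitting."))
    m <- m[v > 0, , drop = FALSE]
  }
  cc <- cor(t(m))
  fit <- purrr::map_dfr(candidates, function(b) {
    a <- if (signed) ((1 + cc) / 2)^b else abs(cc)^b
    diag(a) <- 0
    k <- rowSums(a)
    r2 <- .scale_free_r2(k, n_breaks)
    tibble(power = b,
           r_squared = as.numeric(r2),
           slope = attr(r2, "slope") %||% NA_real_,
           mean_k = mean(k))
  })
  ok <- which(fit$r_squared >= r2_target)
  if (length(ok)) {
    list(power = fit$power[ok[1]], reached_target = TRUE, fit = fit)
  } else {
    warn("no candidate reached the scale-free fit target; using the best one.")
    list(power = fit$power[which.max(fit$r_squared)],
         reached_target = FALSE, fit = fit)
  }
}

# signed scale-free topology fit index: R^2 of log10 p(k) ~ log10 mean(k)
# over occupied bins, negated when the slope is positive
.scale_free_r2 <- function(k, n_breaks) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(structure(0, slope = NA_real_))
  cuts <- cut(k, n_breaks)
  dk <- tapply(k, cuts, mean)
  pk <- tabulate(cuts, nbins = n_breaks) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3) return(structure(0, slope = NA_real_))
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  sl <- unname(stats::coef(fit)[2])
  structure(-sign(sl) * r2, slope = sl)
}

#' Export the network edge list
#'
#' Undirected edges with TOM weight strictly greater than the cutoff, each
#' unordered pair emitted once with `gene1 < gene2` (lexicographic).
#'
#' @param network An `eds_network`.
#' @param weight_cutoff Strict lower bound on TOM weight (default 0.15).
#' @return Tibble `gene1`, `gene2`, `weight`.
#' @export
export_edges <- function(network, weight_cutoff = 0.15) {
  tom <- network$tom
  idx <- which(upper.tri(tom) & tom > weight_cutoff, arr.ind = TRUE)
  g1 <- rownames(tom)[idx[, 1]]
  g2 <- colnames(tom)[idx[, 2]]
  swap <- g1 > g2
  out <- tibble(
    gene1 = ifelse(swap, g2, g1),
    gene2 = ifelse(swap, g1, g2),
    weight = tom[idx]
  )
  arrange(out, .data$gene1, .data$gene2)
}
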