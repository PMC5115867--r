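#' Filter all-vs-all similarity hits into an undirected graph
#'
#' Keeps a hit when (strictly) E-value < `e_max`, alignment length >
#' `len_min` amino acids, query coverage > `cov_min` and identity > `id_min`.
#' Self-hits are removed; reciprocal hits are merged into one undirected edge
#' keeping the best (smallest) E-value. Edge weights for clustering are
#' `-log10(E)` capped at 200.
#'
#' @param hits Tibble with columns `query`, `subject`, `evalue`, `length`,
#'   `coverage`, `identity` (fractions in \[0, 1\]).
#' @param e_max,len_min,cov_min,id_min Strict thresholds.
#' @return Tibble `gene1`, `gene2`, `evalue`, `weight` with `gene1 < gene2`.
#' @export
filter_hits <- function(hits, e_max = 1e-20, len_min = 60, cov_min = 0.60,
                        id_min = 0.50) {
  need <- c("query", "subject", "evalue", "length", "coverage", "identity")
  .assert(all(need %in% names(hits)),
          paste0("`hits` needs columns: ", paste(need, collapse = ", ")))
  bad <- which(!complete.cases(hits[need]) | hits$evalue < 0 |
                 hits$coverage < 0 | hits$coverage > 1 |
                 hits$identity < 0 | hits$identity > 1)
  if (length(bad)) {
    abort(paste0("malformed hit row(s): ", paste(head(bad, 5), collapse = ", ")))
  }
  kept <- hits |>
    filter(.data$query != .data$subject,
           .data$evalue < e_max,
           .data$length > len_min,
           .data$coverage > cov_min,
           .data$identity > id_min)
  if (nrow(kept) == 0) {
    return(tibble(gene1 = character(), gene2 = character(),
                  evalue = numeric(), weight = numeric()))
  }
  kept |>
    mutate(gene1 = pmin(.data$query, .data$subject),
           gene2 = pmax(.data$query, .data$subject)) |>
    group_by(.data$gene1, .data$gene2) |>
    summarise(evalue = min(.data$evalue), .groups = "drop") |>
    mutate(weight = pmin(200, -log10(pmax(.data$evalue, 1e-300)))) |>
    arrange(.data$gene1, .data$gene2)
}

#' Markov clustering (MCL) of a weighted similarity graph
#'
#' Classic MCL update rules on the column-stochastic transition matrix of the
#' weighted graph (with self-loops added, weight equal to the node's maximum
#' incident weight): expansion is matrix squaring; inflation raises entries to
#' the power `inflation` and renormalizes columns. Iteration stops when the
#' largest entrywise change falls below `tol`; clusters are the connected
#' components of the support of the limit matrix. Deterministic for a fixed
#' input order.
#'
#' @param graph Edge tibble (`gene1`, `gene2`, `weight`) as from
#'   [filter_hits()], or a symmetric nonnegative matrix with dimnames.
#' @param inflation Inflation exponent (> 1, default 2).
#' @param max_iter Maximum iterations.
#' @param tol Convergence tolerance on the max entrywise change.
#' @return Tibble `gene`, `group` (`HG1`, `HG2`, ... ordered by decreasing
#'   size then smallest member), with attribute `converged`.
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 100, tol = 1e-6) {
  .assert(inflation > 1, "`inflation` must be > 1.")
  a <- if (is.matrix(graph)) {
    .assert(!is.null(rownames(graph)), "matrix input needs dimnames.")
    graph
  } else {
    nodes <- sort(unique(c(graph$gene1, graph$gene2)))
    m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    if (nrow(graph)) {
      i <- match(graph$gene1, nodes); j <- match(graph$gene2, nodes)
      w <- graph$weight %||% rep(1, nrow(graph))
      m[cbind(i, j)] <- w
      m[cbind(j, i)] <- w
    }
    m
  }
  .assert(all(a >= 0), "edge weights must be nonnegative.")
  n <- nrow(a)
  if (n == 0) return(tibble(gene = character(), group = character()))
  loops <- apply(a, 1, max)
  diag(a) <- ifelse(loops > 0, loops, 1)
  m <- sweep(a, 2, colSums(a), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m2 <- m %*% m                      # expansion
    m2 <- m2^inflation                 # inflation
    m2 <- sweep(m2, 2, colSums(m2), "/")
    m2[m2 < 1e-12] <- 0
    m2 <- sweep(m2, 2, colSums(m2), "/")
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warn("MCL did not converge; returning current clustering.")
  comp <- .components(m > 1e-8 | t(m) > 1e-8)
  nodes <- rownames(a)
  sizes <- table(comp)
  firsts <- vapply(names(sizes), function(k) min(nodes[comp == k]), "")
  ord <- names(sizes)[order(-sizes, firsts)]
  grp <- paste0("HG", match(as.character(comp), ord))
  out <- tibble(gene = nodes, group = grp) |> arrange(.data$group, .data$gene)
  attr(out, "converged") <- converged
  out
}

# connected components of a logical adjacency matrix (BFS)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
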