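test_that("two planted blocks are recovered as two modules", {
  expr <- planted_blocks(50, 50, 30, loading = 0.95, seed = 11)
  net <- build_network(expr, power = 6)
  # clean planted blocks separate well below the default height
  mods <- detect_modules(net, min_module_size = 30, cut_height = 0.9)
  found <- unique(mods$module[mods$module > 0])
  expect_equal(length(found), 2)
  truth_a <- grep("^a", mods$gene, value = TRUE)
  truth_b <- grep("^b", mods$gene, value = TRUE)
  jac <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  best_a <- max(sapply(found, function(k) jac(mods$gene[mods$module == k], truth_a)))
  best_b <- max(sapply(found, function(k) jac(mods$gene[mods$module == k], truth_b)))
  expect_gte(best_a, 0.95)
  expect_gte(best_b, 0.95)
})

test_that("structureless data leaves genes unassigned", {
  set.seed(12)
  m <- matrix(rnorm(200 * 30), 200, 30,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:30)))
  net <- build_network(toy_expr(m), power = 6)
  mods <- detect_modules(net, min_module_size = 30)
  expect_gte(mean(mods$module == 0), 0.9)
  # fewer genes than the minimum size: everything unassigned
  net_small <- build_network(toy_expr(m[1:10, ]), power = 6)
  mods_small <- detect_modules(net_small, min_module_size = 30)
  expect_true(all(mods_small$module == 0))
})

test_that("kIM equals the brute-force within-module adjacency row sum", {
  expr <- planted_blocks(30, 20, 25, loading = 0.9, seed = 13)
  net <- build_network(expr, power = 6)
  mods <- detect_modules(net, min_module_size = 20)
  st <- module_statistics(expr, net, mods)
  for (k in unique(st$module[st$module > 0])) {
    genes <- st$gene[st$module == k]
    manual <- rowSums(net$adjacency[genes, genes])
    expect_equal(st$kim[match(genes, st$gene)], unname(manual),
                 tolerance = 1e-12)
  }
  expect_true(all(st$kme[st$module > 0] >= -1 & st$kme[st$module > 0] <= 1))
  expect_true(all(st$kim[st$module > 0] >= 0))
})

test_that("hub fraction 1 marks every module gene; eigengene is unit norm", {
  expr <- planted_blocks(30, 10, 25, loading = 0.9, seed = 14)
  net <- build_network(expr, power = 6)
  mods <- detect_modules(net, min_module_size = 20)
  st <- module_statistics(expr, net, mods, hub_fraction = 1)
  expect_true(all(st$hub[st$module > 0]))
  eig <- attr(st, "eigengenes")
  expect_equal(sqrt(colSums(eig^2)), rep(1, ncol(eig)), ignore_attr = TRUE)
  # default 5%: ceiling rule
  st2 <- module_statistics(expr, net, mods, hub_fraction = 0.05)
  for (k in unique(st2$module[st2$module > 0])) {
    n_k <- sum(st2$module == k)
    expect_equal(sum(st2$hub[st2$module == k]), ceiling(0.05 * n_k))
  }
})

test_that("trait coupling finds the planted trait-coupled module", {
  set.seed(15)
  n_samples <- 30
  f1 <- rnorm(n_samples)
  trait <- 0.8 * f1 + sqrt(1 - 0.64) * rnorm(n_samples)
  block <- function(f, n, load = 0.85) {
    t(sapply(seq_len(n), function(i) load * f + sqrt(1 - load^2) * rnorm(n_samples)))
  }
  f2 <- rnorm(n_samples)
  m <- rbind(block(f1, 40), block(f2, 40),
             matrix(rnorm(40 * n_samples), 40))
  rownames(m) <- sprintf("g%03d", 1:120)
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  expr <- toy_expr(m)
  net <- build_network(expr, power = 6)
  mods <- detect_modules(net, min_module_size = 30)
  tc <- module_trait_correlation(expr, mods, setNames(trait, colnames(m)))
  # the coupled block ranks first and the rank test is decisive
  top_genes <- attr(tc, "gene_correlations")
  focal <- attr(tc, "focal_module")
  focal_genes <- top_genes$gene[top_genes$module_name == focal]
  expect_gte(mean(focal_genes %in% sprintf("g%03d", 1:40)), 0.9)
  expect_lt(attr(tc, "p_value"), 0.001)

  # a trait equal to one gene's profile correlates perfectly with it
  tc2 <- module_trait_correlation(expr, mods, setNames(m["g001", ], colnames(m)))
  gc2 <- attr(tc2, "gene_correlations")
  expect_equal(gc2$cor[gc2$gene == "g001"], 1, tolerance = 1e-12)

  expect_error(module_trait_correlation(expr, mods,
                                        setNames(rep(1, n_samples), colnames(m))),
               "constant")
})

test_that("a trait independent of expression gives null module means", {
  set.seed(16)
  expr <- planted_blocks(40, 40, 30, loading = 0.9, seed = 16)
  trait <- rnorm(30)
  net <- build_network(expr, power = 6)
  mods <- detect_modules(net, min_module_size = 30)
  tc <- module_trait_correlation(expr, mods, setNames(trait, colnames(expr)[-1]))
  # genes within a module are co-expressed, so their trait correlations are
  # themselves correlated: the module-mean SE scales as 1/sqrt(n_samples),
  # not 1/sqrt(n_genes)
  expect_true(all(abs(tc$mean_cor) < 3 / sqrt(30 - 3)))
})

test_that("intramodular connectivity contrast detects planted co-induction", {
  tr <- make_species_tree("nicotiana")
  sim <- simulate_expression(tr, n_genes = 400, seed = 17)
  fac <- tmm_factors(sim$counts)
  adj <- batch_adjust(log2_expr(filter_expressed(fpkm_matrix(sim$counts, fac))),
                      sim$metadata$species, sim$metadata$treatment)
  groups <- setNames(sim$metadata$treatment, sim$metadata$sample)
  kc <- kim_contrast(adj, sim$truth$module_genes, groups, power = 6)
  med <- setNames(kc$median_kim, kc$group)
  expect_gt(med[["FAC"]], med[["WW"]])
  expect_lt(attr(kc, "p_value"), 0.05)
})
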