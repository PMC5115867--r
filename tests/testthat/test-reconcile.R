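test_that("congruent single-copy trees reconcile with zero duplications", {
  te <- make_species_tree("eudicot")
  fam <- simulate_gene_families(te, 5, dup_rate_per_branch = 0,
                                wgt_retention_prob = 0, loss_prob = 0, seed = 2)
  for (tr in fam$gene_trees) {
    rec <- reconcile_lca(tr, te)
    expect_false(any(rec$nodes$event == "duplication", na.rm = TRUE))
  }
})

test_that("a hand-worked duplication topology maps to the root", {
  cherry <- make_species_tree("random", n = 2, seed = 1)
  gt <- read_newick(text = "((sp01_f0001_g1,sp02_f0001_g2),(sp01_f0001_g3,sp02_f0001_g4));")
  rec <- reconcile_lca(gt, cherry)
  internal <- rec$nodes[!rec$nodes$is_leaf, ]
  root_row <- internal[internal$node == 5, ]    # phylo root node id = ntip + 1
  expect_equal(root_row$event, "duplication")
  expect_equal(root_row$species_node, 3)        # species-tree root
  cherries <- internal[internal$node != 5, ]
  expect_true(all(cherries$event == "speciation"))
})

test_that("reconciliation is invariant to leaf-order permutations", {
  te <- make_species_tree("eudicot")
  fam <- simulate_gene_families(te, 10, dup_rate_per_branch = 0.2,
                                wgt_retention_prob = 0.5, loss_prob = 0.05,
                                seed = 13)
  tr <- fam$gene_trees[[which.max(vapply(fam$gene_trees, ape::Ntip, 1L))]]
  rec1 <- reconcile_lca(tr, te)
  tr2 <- ape::rotateConstr(tr, rev(tr$tip.label))
  rec2 <- reconcile_lca(tr2, te)
  ev1 <- table(rec1$nodes$event[!rec1$nodes$is_leaf])
  ev2 <- table(rec2$nodes$event[!rec2$nodes$is_leaf])
  expect_equal(ev1, ev2)
  c1 <- call_most_recent_duplication(rec1)
  c2 <- call_most_recent_duplication(rec2)
  expect_equal(dplyr::arrange(c1, gene), dplyr::arrange(c2, gene))
})

test_that("events agree with the naive quadratic LCA oracle", {
  te <- make_species_tree("eudicot")
  fam <- simulate_gene_families(te, 30, dup_rate_per_branch = 0.15,
                                wgt_retention_prob = 0.4, loss_prob = 0.1,
                                seed = 19)
  for (tr in fam$gene_trees[seq_len(min(15, length(fam$gene_trees)))]) {
    rec <- reconcile_lca(tr, te)
    oracle <- reconcile_oracle(tr, te)
    got <- rec$nodes[!rec$nodes$is_leaf, c("node", "species_node", "event")]
    expect_equal(got$species_node, oracle$species_node)
    expect_equal(got$event, oracle$event)
  }
})

test_that("support gating follows the three-closest-branches rule", {
  cherry <- make_species_tree("random", n = 2, seed = 1)
  # all three relevant supports high: accepted
  gt <- read_newick(text = sprintf(
    "((sp01_f0001_g1,sp02_f0001_g2)%s,(sp01_f0001_g3,sp02_f0001_g4)%s)%s;",
    "0.92", "0.91", "0.95"))
  rec <- reconcile_lca(gt, cherry)
  calls <- call_most_recent_duplication(rec, support_min = 0.9)
  expect_true(all(calls$verdict == "accepted"))
  expect_true(all(calls$branch == "SOL_WGT_STEM"))

  # one child support below the threshold: uncertain
  gt2 <- read_newick(text = sprintf(
    "((sp01_f0001_g1,sp02_f0001_g2)%s,(sp01_f0001_g3,sp02_f0001_g4)%s)%s;",
    "0.85", "0.91", "0.95"))
  calls2 <- call_most_recent_duplication(reconcile_lca(gt2, cherry),
                                         support_min = 0.9)
  expect_true(all(calls2$verdict == "uncertain"))

  # single-copy congruent tree: branch NA, accepted
  gt3 <- read_newick(text = "(sp01_f0001_g1,sp02_f0001_g2)1;")
  calls3 <- call_most_recent_duplication(reconcile_lca(gt3, cherry))
  expect_true(all(is.na(calls3$branch)))
  expect_true(all(calls3$verdict == "accepted"))
})

test_that("lowering the support threshold never loses accepted calls", {
  te <- make_species_tree("eudicot")
  fam <- simulate_gene_families(te, 40, dup_rate_per_branch = 0.1,
                                wgt_retention_prob = 0.3, loss_prob = 0.05,
                                support_model = list(type = "beta",
                                                     shape1 = 8, shape2 = 2),
                                seed = 23)
  n_accept <- vapply(c(0.95, 0.9, 0.7, 0.5, 0), function(s) {
    calls <- duplication_calls(fam$gene_trees, te, support_min = s)
    sum(calls$verdict == "accepted")
  }, 1.0)
  expect_true(all(diff(n_accept) >= 0))
})

test_that("duplication-branch recovery on clean supports is near-perfect", {
  te <- make_species_tree("eudicot")
  fam <- simulate_gene_families(te, 200, dup_rate_per_branch = 0.05,
                                wgt_retention_prob = 0.2, loss_prob = 0.05,
                                support_model = list(type = "fixed", value = 1),
                                seed = 42)
  calls <- duplication_calls(fam$gene_trees, te)
  j <- dplyr::inner_join(calls, fam$truth$genes,
                         by = c("family", "gene", "species"))
  ok <- ifelse(is.na(j$branch) & is.na(j$truth_branch), TRUE,
               !is.na(j$branch) & !is.na(j$truth_branch) &
                 j$branch == j$truth_branch)
  expect_gte(mean(ok), 0.95)
  expect_true(all(calls$verdict == "accepted"))
})

test_that("retention classification flags and pairs are consistent", {
  te <- make_species_tree("eudicot")
  fam <- simulate_gene_families(te, 120, dup_rate_per_branch = 0.05,
                                wgt_retention_prob = 0.4, loss_prob = 0.05,
                                seed = 29)
  calls <- duplication_calls(fam$gene_trees, te)
  ret <- classify_retention(calls, fam$gene_trees, te,
                            focal_species = "N.attenuata")
  g <- ret$genes
  expect_true(all(g$multi_copy[g$wgt_retained]))
  expect_true(all(g$multi_copy[g$nld_retained]))
  expect_false(any(g$wgt_retained & g$nld_retained))
  # pairs: disjoint, same family, WGT-retained members
  p <- ret$pairs
  expect_false(any(duplicated(c(p$gene1, p$gene2))))
  expect_true(all(p$gene1 %in% g$gene[g$wgt_retained]))
  expect_true(all(p$gene2 %in% g$gene[g$wgt_retained]))
  # bookkeeping: pairs x 2 = paired genes
  expect_equal(2 * nrow(p), length(unique(c(p$gene1, p$gene2))))
  # two expressed WGT copies in one family form exactly one pair
  fam2 <- simulate_gene_families(te, 40, dup_rate_per_branch = 0,
                                 wgt_retention_prob = 1, loss_prob = 0,
                                 seed = 31)
  calls2 <- duplication_calls(fam2$gene_trees, te)
  ret2 <- classify_retention(calls2, fam2$gene_trees, te,
                             focal_species = "N.attenuata")
  # forced triplication: 3 focal copies -> one pair per family, third unpaired
  expect_equal(nrow(ret2$pairs), 40)
  expect_true(all(ret2$genes$wgt_retained))
})

test_that("unknown leaf species raise a named error", {
  te <- make_species_tree("eudicot")
  gt <- read_newick(text = "(Martian_f0001_g1,N.attenuata_f0001_g2);")
  expect_error(reconcile_lca(gt, te), "Martian")
})
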