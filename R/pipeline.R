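#' Pipeline configuration
#'
#' Collects every stage parameter with its default. Unset entries take the
#' defaults shown in the function signature, so a config echoes every
#' threshold it will use, and being a named list of plain scalars/vectors it
#' round-trips losslessly through serialization.
#'
#' @param seed Master seed; stage seeds are derived by small offsets.
#' @param n_genes,n_reps,planted Expression-simulation settings
#'   (see [simulate_expression()]).
#' @param n_families,dup_rate,wgt_retention,loss_prob Family-simulation
#'   settings.
#' @param min_fpkm,min_samples Expression filter.
#' @param fc_threshold,alpha,dispersion DE test settings.
#' @param top_k,power,r2_target Network settings (`power = NULL` picks by
#'   scale-free fit).
#' @param min_module_size,cut_height,kme_core,hub_fraction Module settings.
#' @param n_perm Preservation permutations.
#' @param support_min Duplication-call support threshold.
#' @param ks_min Ka/Ks exclusion threshold.
#' @param focal_species Species whose genes are classified for retention.
#' @return A named list of class `eds_config`.
#' @export
eds_config <- function(seed = 1L,
                       n_genes = 2000, n_reps = 3, planted = list(),
                       n_families = 200, dup_rate = 0.05,
                       wgt_retention = 0.2, loss_prob = 0.05,
                       min_fpkm = 5, min_samples = 3,
                       fc_threshold = 1.5, alpha = 0.05,
                       dispersion = "estimate",
                       top_k = 5000, power = NULL, r2_target = 0.8,
                       min_module_size = 30, cut_height = 0.95,
                       kme_core = 0.75, hub_fraction = 0.05,
                       n_perm = 200, support_min = 0.9, ks_min = 0.02,
                       focal_species = "N.attenuata") {
  cfg <- as.list(environment())
  class(cfg) <- "eds_config"
  cfg
}

#' Run the full synthetic-data pipeline
#'
#' Simulates the cross-species elicitation experiment and gene families,
#' normalizes (TMM-FPKM, expression filter, log2, cross-species batch
#' adjustment), calls differential expression per species, builds the
#' co-expression network, detects and scores modules, couples modules to the
#' trait, reconciles gene families and classifies WGT/lineage retention, and
#' assembles the retention-enrichment report with the planted module as the
#' gene set. Deterministic given the config seed.
#'
#' @param config An [eds_config()].
#' @param tree Optional [species_tree][make_species_tree]; defaults to the
#'   six-species preset for expression plus the eudicot preset for families.
#' @return A list bundle: `expression` (sim, factors, filtered/adjusted
#'   tables), `de` (per-species tibbles), `network`, `modules`, `trait`,
#'   `families` (sim, calls, retention), `enrichment` (report tibble), and
#'   `log` (parameters used).
#' @export
run_pipeline <- function(config = eds_config(), tree = NULL) {
  cfg <- config
  expr_tree <- tree %||% make_species_tree("nicotiana")
  fam_tree <- tree %||% make_species_tree("eudicot")

  sim <- simulate_expression(expr_tree, n_genes = cfg$n_genes,
                             n_reps = cfg$n_reps, planted = cfg$planted,
                             seed = cfg$seed)
  fac <- tmm_factors(sim$counts)
  fpkm <- fpkm_matrix(sim$counts, fac)
  expressed <- filter_expressed(fpkm, cfg$min_fpkm, cfg$min_samples)
  lg <- log2_expr(expressed)
  adj <- batch_adjust(lg, sim$metadata$species, sim$metadata$treatment)

  de <- lapply(split(sim$metadata$sample, sim$metadata$species), function(ss) {
    sub <- sim$counts[, c("gene", "length", ss)]
    grp <- factor(sim$metadata$treatment[match(ss, sim$metadata$sample)],
                  levels = unique(sim$metadata$treatment))
    nb_exact_de(sub, setNames(grp, ss), dispersion = cfg$dispersion,
                fc_threshold = cfg$fc_threshold, alpha = cfg$alpha)
  })

  top <- select_top_connected(adj, k = cfg$top_k, power = cfg$power %||% 6)
  sel <- adj[adj$gene %in% top$gene[top$selected], ]
  attr(sel, "transforms") <- transforms(adj)
  power <- cfg$power
  sf <- NULL
  if (is.null(power)) {
    sf <- pick_soft_power(sel, r2_target = cfg$r2_target)
    power <- sf$power
  }
  net <- build_network(sel, power = power)
  modules <- detect_modules(net, cfg$min_module_size, cfg$cut_height)
  elicited <- sim$metadata$sample[sim$metadata$treatment ==
                                    unique(sim$metadata$treatment)[2]]
  hub_net <- build_network(sel[, c("gene", elicited)], power = power)
  stats <- module_statistics(sel, net, modules, cfg$kme_core,
                             cfg$hub_fraction, hub_network = hub_net)
  trait <- module_trait_correlation(sel, modules,
                                    setNames(sim$metadata$trait,
                                             sim$metadata$sample))

  fams <- simulate_gene_families(fam_tree, n_families = cfg$n_families,
                                 dup_rate_per_branch = cfg$dup_rate,
                                 wgt_retention_prob = cfg$wgt_retention,
                                 loss_prob = cfg$loss_prob,
                                 seed = cfg$seed + 1L)
  calls <- duplication_calls(fams$gene_trees, fam_tree,
                             support_min = cfg$support_min)
  retention <- classify_retention(calls, fams$gene_trees, fam_tree,
                                  focal_species = cfg$focal_species)

  enrichment <- .pipeline_enrichment(retention, modules, cfg)

  list(
    expression = list(sim = sim, factors = fac, filtered = expressed,
                      adjusted = adj, scale_free = sf),
    de = de,
    network = net,
    modules = stats,
    trait = trait,
    families = list(sim = fams, calls = calls, retention = retention),
    enrichment = enrichment,
    log = list(config = unclass(cfg), power = power,
               package_version = as.character(utils::packageVersion("edsnet")))
  )
}

# retention-enrichment report on a deterministic synthetic gene set (every
# fifth classified focal gene): exercises the full statistics layer end to
# end; rows with degenerate proportions are dropped
.pipeline_enrichment <- function(retention, modules, cfg) {
  genes <- retention$genes
  if (nrow(genes) == 0) return(NULL)
  n <- nrow(genes)
  set <- genes$gene[seq(1, n, by = 5)]
  k <- function(flag, g) sum(genes[[flag]][genes$gene %in% g])
  counts <- tibble(
    set = "synthetic_set",
    category = c("multi_copy", "wgt_retained", "nld_retained"),
    k_set = c(k("multi_copy", set), k("wgt_retained", set),
              k("nld_retained", set)),
    n_set = length(set),
    k_genome = c(sum(genes$multi_copy), sum(genes$wgt_retained),
                 sum(genes$nld_retained)),
    n_genome = n
  )
  ok <- counts$k_set > 0 & counts$k_set < counts$n_set &
    counts$k_genome > 0 & counts$k_genome < counts$n_genome
  if (!any(ok)) return(NULL)
  retention_report(counts[ok, ])
}
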