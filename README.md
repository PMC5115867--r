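# edsnet

Cross-species co-expression modules and duplicate retention in
herbivory-induced early defense signaling (EDS).

## The problem

When a chewing insect attacks a leaf, plants perceive herbivore-associated
elicitors (e.g. fatty acid–amino acid conjugates, FACs, in caterpillar oral
secretions) and mount a fast transcriptional response — early defense
signaling — that precedes and steers the jasmonate (JA) burst. Because the
response is fast, tissue-specific and treatment-specific, the usual
time-course co-expression designs have little power; comparing elicited
leaves of several closely related species instead uses natural variation in
responsiveness as the contrast. `edsnet` implements that analysis chain for
anyone studying the evolution of an induced-response network:

1. **Expression**: TMM-normalized FPKM, an expressed-gene filter (FPKM > 5 in
   ≥ 3 samples), an exact negative-binomial test for differential expression
   (fold change > 1.5, BH-adjusted p < 0.05), and empirical-Bayes batch
   adjustment to remove cross-species background differences.
2. **Co-expression**: unsigned weighted networks (adjacency `|cor|^β`),
   topological overlap (TOM), average-linkage module detection, module
   eigengenes/kME/kIM, hub calling, module–trait coupling, and permutation
   Z-statistics of cross-dataset module preservation (Z-summary > 10
   preserved, < 2 not preserved).
3. **Phylogenomics**: similarity-hit filtering, Markov clustering into
   homologous groups, LCA reconciliation of gene trees against a species
   tree, support-gated dating of each gene's most recent duplication, and
   classification of whole-genome-triplication (WGT) versus lineage-specific
   retention.
4. **Molecular evolution**: NG86 Ka/Ks with Jukes–Cantor correction, the
   Ks < 0.02 exclusion rule, and a Fisher test of ω < 1.
5. **Enrichment statistics**: the retention odds ratio
   `odds = (p1/(1−p1)) / (p2/(1−p2))` with exact binomial tests, the
   chi-square test of preferential pair retention against the
   independent-recruitment null `E[both] = n_pairs (m / 2n_pairs)^2`, and
   windowed upstream TE-insertion enrichment.
6. **Synthetic data**: generators for every input — a labelled species tree,
   birth–death gene families with a triplication on the Solanaceae-stem
   branch, NB counts with a planted trait-coupled module, and codon pairs
   with known ω and Ks — so the whole chain is testable against known truth.

## Worked example

The retention statistics from a published six-species *Nicotiana* survey,
recomputed from the printed counts (906/1140 module genes in multiple-copy
families vs 9691/14642 genome-wide, etc.):

```r
library(edsnet)
retention_report(tibble::tibble(
  set      = c("complete", "complete", "conserved"),
  category = c("multiple_copy", "wgt_retained", "multiple_copy"),
  k_set    = c(906, 587, 561),
  n_set    = c(1140, 1140, 692),
  k_genome = c(9691, 6181, 9691),
  n_genome = 14642
))
#>         set      category    p1    p2 odds_2dec  p_value
#> 1  complete multiple_copy 0.795 0.662      1.97 5.53e-23
#> 2  complete  wgt_retained 0.515 0.422      1.45 3.30e-10
#> 3 conserved multiple_copy 0.811 0.662      2.18 5.51e-18
```

79.5% of module genes sit in multiple-copy families (odds ratio 1.97 against
the genome-wide 66.2%) and 51.5% trace their most recent duplication to the
Solanaceae WGT (odds 1.45, exact binomial p = 3.3e-10): duplicates, and WGT
duplicates in particular, are over-retained in the defense-signaling module.
The preferential-retention test asks whether *both* members of WGT pairs
co-occur in the module more often than chance:

```r
pair_retention_chi2(n_pairs = 4292, m_in_module = 428, observed_both = 120)
#>   observed_both expected_both chi_sq    p_value
#> 1           120         10.67   1241 3.491e-270
```

120 observed double-retained pairs against 10.7 expected under independent
recruitment — far below any reporting floor, evidence of preferential
retention of duplicate pairs in the network.

End-to-end on synthetic data with known truth:

```r
cfg <- eds_config(seed = 1, n_genes = 2000, n_families = 200)
res <- run_pipeline(cfg)
glance(res$modules)          # detected modules
attr(res$trait, "p_value")   # rank test: top module vs rest
res$families$retention$pairs # WGT-derived duplicate pairs
```

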