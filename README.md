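# switchtraj

Tissue-adaptation trajectories and switch-like gene kinetics from
single-cell RNA-seq.

Regulatory T cells recruited from lymphoid tissues (spleen, draining lymph
nodes) adapt progressively to non-lymphoid tissues such as skin and colon.
`switchtraj` reconstructs this lymphoid-to-non-lymphoid (LT→NLT) transition
from single-cell count matrices and extracts the gene kinetics along it.
It is aimed at computational immunologists who have clustered and annotated
single-cell data (cluster labels and reconstructed TCR chain tables are
inputs, not products) and want a tested, reproducible route from counts to
an adaptation pseudospace and the switch-like genes that structure it.

The pipeline stages:

* **QC** — UMI/gene-count bounds plus TCR-based rules (doublets: more than
  two distinct recombinants on a locus; γδ T cells: γ and δ chains without
  an αβ pair; removal of TCR-less cells), log-normalisation
  (`ln(1 + 10⁴·count/total)`), equal-frequency binned variable-gene
  selection.
* **Markers** — Wilcoxon rank-sum DE with Bonferroni adjustment
  (`|avg logFC| ≥ 0.25`, adjusted p ≤ 0.05, 5% expression filter, two-pass
  union re-testing), one-vs-rest cluster markers, and the NLT/LT signature
  ratio score.
* **Label transfer** — L1-penalised multinomial logistic regression on raw
  counts; argmax labels, full probabilities, composition matrices.
* **Trajectory** — a MAP Gaussian process latent variable model with an
  ARD kernel; the adaptation dimension is the most relevant latent variable
  whose ordering tracks tissue identity, oriented LT-low/NLT-high. Held-out
  cells project into a fitted space. A partitioned variant (shared latent
  space, per-partition relevance) isolates cell-cycle variation from
  tissue adaptation.
* **Switch kinetics** — per-gene maximum-likelihood sigmoid fits
  `S(t) = 2μ₀ / (1 + e^(−k(t−t₀)))` with a likelihood-ratio test against
  the constant model (2 df), BH q-values over the tested universe, t₀-range
  and prevalence/correlation filters, and a subsample-median scheme for
  unbalanced subpopulations.
* **Program ordering** — hypergeometric gene-set enrichment, per-term mean
  activation times, Spearman comparison of program order across
  trajectories, Welch t tests of t₀ between conditions.
* **Cross-species** — marker overlap through one-to-one orthologs,
  fold-change concordance, and detection of paralog substitutions (the
  NLT-marker role carried by different paralog-family members in the two
  species).

A calibrated negative-binomial simulator with planted ground truth
(`simulateTrajectoryDataset()` and friends) generates every input the
pipeline consumes — counts, metadata, TCR tables, condition pairs and
species pairs — so the whole package is testable without downloads.

## A worked example

```r
library(switchtraj)

cfg <- pipelineConfig(seed = 2, n_cells_per_group = 80,
                      n_switch_genes = 30, n_flat_genes = 50,
                      n_marker_genes_per_group = 6, n_background_genes = 30,
                      genes_min = 40, n_variable_genes = 40,
                      gplvm_maxit = 250, min_cells = 20)
res <- runPipeline("all", cfg, "pipeline_out")

# how well did the inferred coordinate order the cells?
cor(adaptationLV(res$embedding), res$traj_sce$true_t, method = "spearman")
#> [1] 0.8911743

# switch-gene recovery along the inferred coordinate
fits <- res$switch_fits
table(reported = fits$reported, planted_switch = grepl("^SW", fits$gene))
#>         planted_switch
#> reported FALSE TRUE
#>    FALSE     0    1
#>    TRUE      12   29
```

The Spearman correlation of 0.89 says the fitted latent variable
reproduces the planted adaptation order closely at this deliberately small
demonstration scale. The contingency table shows 29 of the 30 planted
sigmoid genes that survived the pre-filters being reported (q ≤ 0.05, t₀
within the coordinate range); the 12 reported genes not planted as
sigmoids are exactly the 12 tissue-marker genes, which are restricted to
one tissue and therefore genuinely switch along the LT→NLT coordinate.
Artifacts (QC report, marker tables, embedding, switch fits, program
timing, manifest with seed and checksums) are written under
`pipeline_out/`; re-running with the same seed reproduces them
byte-for-byte. A command-line wrapper lives at `inst/scripts/pipeline.R`.

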