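# hcrtseq

Hypocretin (orexin, Hcrt) neurons are a small hypothalamic population that
regulates sleep and wake. Studying them end to end means (1) deciding which
transcripts are genuinely enriched in a few hundred FACS-sorted fluorescent
neurons profiled by heavily amplified low-input RNA-seq, (2) asking whether
the enriched transcripts share upstream transcription-factor (TF)
regulators, and (3) measuring the behavioral consequence — larval zebrafish
sleep — when a candidate gene is disrupted. `hcrtseq` implements these three
computational stages as a tested R package, plus calibrated synthetic-data
generators so that every stage can be validated against known ground truth
without any external download. It is written for computational biologists
who need the statistics of such a screen to be auditable.

## What it computes

**Enrichment calling.** Counts are normalized to transcripts per million,
TPM\_g = 10^6 (c\_g/l\_g) / Σ\_j (c\_j/l\_j), and between-sample scale factors
come from a weighted trimmed mean of M-values (30% trim on M = log2 ratios,
5% on average abundance A, precision weights). Replicates are pooled; each
gene's sorted-cell count is tested against both control groups with an
exact conditional binomial test of two Poisson rates — counts deflated by an
estimated variance-inflation factor φ to absorb amplification
overdispersion — taking p = max of the two comparisons, Bonferroni-corrected
over genes averaging >15 raw reads in the sorted samples. Significant genes
(adjusted p < 0.01) fall into the published tiers: **strict** (≥100 TPM in
sorted cells, ≥7-fold over the larger control) and **relaxed** (≥10 TPM,
≥3.6-fold).

**TF prediction.** Promoters are scanned on both strands with position
weight matrices scored as Σ log2(f/q); a hit in the reference species is
kept only if every other species carries a threshold-passing hit at the
aligned position (±10 bp). Per gene and TF, a combined score sums each
conserved site's excess over the matrix threshold; TF-set enrichment of a
foreground gene set against the background is a one-sided hypergeometric
test, Benjamini–Hochberg adjusted across TFs.

**Sleep scoring.** Sleep is any run of ≥1 minute of zero activity.
Per-larva, per-phase (14 h light : 10 h dark) aggregates of sleep min/h,
wake→sleep transitions/h and mean bout length are compared between
genotypes with a permutation test on the difference of group means
(exhaustive when feasible), including sleep-deprivation rebound.

## Worked example

```r
library(hcrtseq)

## a sorting experiment with 25 planted neuron-specific genes
sim <- simulate_count_experiment(count_sim_config(
  n_genes = 5000, n_planted = 25, planted_fold = 10,
  planted_min_tpm = 150, overdispersion_factor = 2, seed = 42))
res <- run_enrichment_pipeline(sim$dataset)
head(res, 3)
#>     gene_id tpm_egfp_pos fold_vs_max_control p_adjusted   tier
#> 1 gene04598        298.4              10.052          0 strict
#> 2 gene01998        273.1               9.731          0 strict
#> 3 gene03570        199.0               9.703          0 strict
sum(res$tier == "strict")                                   # 25
sum(sim$truth$gene_id %in% res$gene_id[res$tier == "strict"]) # 25 recovered
attr(res, "phi")                                            # 1.79

## a behavioral cohort with the published genotype sleep parameters
cohort <- simulate_activity_cohort(sleep_sim_config(
  n_larvae_per_genotype = 30, seed = 7))
scores <- score_cohort(cohort$cohort)
compare_genotypes(scores, c("hom", "wt"), phase = "dark", seed = 7)
#> night sleep: hom 13.70 vs wt 15.02 min/h
#> effect -1.32 min/h, permutation p = 0.023
```

The enrichment caller recovers all 25 planted genes with no false strict
calls, estimates the amplification overdispersion (generative φ = 2;
three-replicate estimates center just below the truth, see the methods
vignette), and the night-sleep deficit planted in the mutant genotype is
detected by the permutation contrast.

## Analysis workflow

The `analysis/` scripts run the full study on a synthetic bundle and
narrate what they find, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R   # counts, promoters, activity traces + ground truth
Rscript analysis/02_enrichment.R      # tiered enrichment calls, recovery vs truth
Rscript analysis/03_tf_analysis.R     # conserved-site scan, combined scores, TF enrichment
Rscript analysis/04_sleep.R           # sleep architecture, genotype contrasts, rebound
```

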