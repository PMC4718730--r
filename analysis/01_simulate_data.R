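#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study bundle with recorded ground truth.
#
# Three datasets mirror the study's three data modalities:
#   (a) a replicated FACS/RNA-seq count matrix (3 groups x 3 replicates,
#       read depths 24M/22M/175M per replicate, amplification
#       overdispersion phi = 2) with 50 planted neuron-specific genes
#       (10-fold enriched, >= 150 TPM in the sorted cells);
#   (b) a 3-species promoter set for 480 genes, with the "planted" TF's
#       motif implanted conservedly in 30 of the 48 foreground genes and a
#       5% single-species background rate;
#   (c) a 24-h activity cohort (90 larvae per genotype, 14:10 LD) with the
#       published genotype-specific night-sleep parameters.

suppressPackageStartupMessages(library(hcrtseq))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("== counts ==")
csim <- simulate_count_experiment(count_sim_config(
  n_genes = 10000, n_planted = 50, planted_fold = 10, planted_min_tpm = 150,
  overdispersion_factor = 2, seed = seed
))
write_count_matrix(csim$dataset, file.path(out, "counts.tsv"),
                   params = list(seed = seed, n_planted = 50,
                                 planted_fold = 10, phi = 2))
write_results_tsv(csim$truth, file.path(out, "counts_truth.tsv"),
                  params = list(seed = seed))
message(sprintf("  %d genes x %d samples; %d planted enriched genes",
                length(csim$dataset$gene_ids), length(csim$dataset$samples),
                nrow(csim$truth)))

message("== promoters ==")
set.seed(seed + 17)
make_motif <- function(name) {
  m <- matrix(rgamma(32, 1), 4, 8)
  dom <- sample.int(4, 8, replace = TRUE)
  m[cbind(dom, 1:8)] <- m[cbind(dom, 1:8)] + 6
  pwm(m, tf_name = name)
}
pwms <- c(list(make_motif("planted")),
          lapply(1:4, function(i) make_motif(paste0("decoy", i))))
psim <- simulate_promoter_set(
  n_genes = 480, n_foreground = 48, promoter_length = 200,
  motif = pwms[[1]], planted_fraction_foreground = 30 / 48,
  background_rate = 0.05, n_species = 3, seed = seed + 1
)
write_promoters(psim$promoters, file.path(out, "promoters.fa"))
write_transfac(pwms, file.path(out, "matrices.txt"))
write_results_tsv(psim$truth, file.path(out, "promoters_truth.tsv"),
                  params = list(seed = seed + 1))
message(sprintf("  480 genes x 3 species; %d conserved placements",
                sum(psim$truth$species == "all")))

message("== activity traces ==")
ssim <- simulate_activity_cohort(sleep_sim_config(
  n_larvae_per_genotype = 90, seed = seed + 2
))
write_activity_cohort(ssim$cohort, file.path(out, "traces.csv"))
write_results_tsv(ssim$truth, file.path(out, "traces_truth.tsv"),
                  params = list(seed = seed + 2))
message(sprintf("  %d larvae x %d minutes",
                length(unique(ssim$cohort$larva_id)),
                max(ssim$cohort$minute_index) + 1))

message("done: synthetic bundle under ", out)
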