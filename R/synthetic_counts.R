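#' Configuration of the synthetic count-matrix generator
#'
#' Describes a sorting experiment to simulate: three sample groups
#' (`egfp_pos`, `egfp_neg`, `whole_head`) with `n_replicates_per_group`
#' libraries each, sequenced to per-replicate depths `library_size_per_group`
#' (defaults match the order of magnitude of the study: 24, 22 and 175
#' million reads). True relative abundances are drawn from a log-normal on
#' the TPM scale; a planted subset of genes is elevated in the sorted
#' population by `planted_fold` over both controls, with sorted-cell
#' abundance at least `planted_min_tpm`. Counts are negative-binomial with
#' variance = `overdispersion_factor` x mean (Poisson when the factor is 1),
#' emulating amplification noise on top of sampling noise.
#'
#' @param n_genes number of genes.
#' @param n_replicates_per_group replicates per group (study used 3).
#' @param library_size_per_group named numeric vector of per-replicate read
#'   depths for `egfp_pos`, `egfp_neg`, `whole_head`.
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the raw
#'   baseline abundance draw (rescaled to the TPM simplex afterwards).
#' @param n_planted number of planted neuron-specific genes.
#' @param planted_fold true fold elevation of planted genes in the sorted
#'   cells (> 1).
#' @param planted_min_tpm minimum true sorted-cell TPM of planted genes.
#' @param overdispersion_factor phi >= 1; variance = phi x mean.
#' @param length_meanlog,length_sdlog log-normal parameters of transcript
#'   lengths (bp, floored at 200).
#' @param seed integer seed; every draw of the generator derives from it.
#' @return list of class `count_sim_config`.
#' @export
count_sim_config <- function(n_genes = 10000,
                             n_replicates_per_group = 3,
                             library_size_per_group = c(
                               egfp_pos = 24e6, egfp_neg = 22e6,
                               whole_head = 175e6
                             ),
                             baseline_meanlog = 1.5, baseline_sdlog = 1.5,
                             n_planted = 0,
                             planted_fold = 10,
                             planted_min_tpm = 150,
                             overdispersion_factor = 2,
                             length_meanlog = log(1500), length_sdlog = 0.5,
                             seed = 1L) {
  if (n_genes < 1 || n_replicates_per_group < 1) {
    stop("n_genes and n_replicates_per_group must be positive")
  }
  if (n_planted < 0 || n_planted > n_genes) {
    stop("n_planted must be between 0 and n_genes")
  }
  if (planted_fold <= 1) stop("planted_fold must exceed 1")
  if (planted_min_tpm <= 0) stop("planted_min_tpm must be positive")
  if (overdispersion_factor < 1) stop("overdispersion_factor must be >= 1")
  stopifnot(
    length(library_size_per_group) == 3,
    all(library_size_per_group > 0)
  )
  if (is.null(names(library_size_per_group))) {
    names(library_size_per_group) <- SAMPLE_GROUPS
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_replicates_per_group = as.integer(n_replicates_per_group),
      library_size_per_group = library_size_per_group,
      baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
      n_planted = as.integer(n_planted),
      planted_fold = planted_fold,
      planted_min_tpm = planted_min_tpm,
      overdispersion_factor = overdispersion_factor,
      length_meanlog = length_meanlog, length_sdlog = length_sdlog,
      seed = as.integer(seed)
    ),
    class = "count_sim_config"
  )
}

# NB draw with variance = phi * mean; phi = 1 degenerates to Poisson.
.rcounts <- function(n, mean, phi) {
  if (phi == 1) return(rpois(n, mean))
  size <- mean / (phi - 1)
  out <- numeric(n)
  pos <- mean > 0
  out[pos] <- rnbinom(sum(pos), size = size[pos], mu = mean[pos])
  out
}

#' Simulate a replicated sorting-experiment count matrix with planted genes
#'
#' Draws gene-level counts for three sample groups with known ground truth.
#' Per group g and gene i the expected count is
#' `lib_g * tpm_gi * len_i / sum_j(tpm_gj * len_j)`; replicate counts are
#' negative-binomial with variance = phi x mean. Planted genes have their
#' sorted-cell true abundance set to `planted_fold` times the control
#' abundance, with control abundance at least `planted_min_tpm / planted_fold`
#' so the sorted-cell abundance clears `planted_min_tpm`.
#'
#' @param config a [count_sim_config()].
#' @return list with elements `dataset` (a [count_matrix()] with columns
#'   `<group>_rep<k>`) and `truth` (data.frame of planted gene ids with their
#'   true control/sorted TPM; config echoed as attribute `config`).
#' @export
simulate_count_experiment <- function(config = count_sim_config()) {
  stopifnot(inherits(config, "count_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(n))
  lengths_bp <- pmax(200, round(rlnorm(n, config$length_meanlog,
                                       config$length_sdlog)))

  base <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  base <- base * 1e6 / sum(base)  # baseline on the TPM simplex

  planted <- if (config$n_planted > 0) {
    sort(sample.int(n, config$n_planted))
  } else {
    integer(0)
  }
  tpm_true <- matrix(base, nrow = n, ncol = 3,
                     dimnames = list(gene_ids, SAMPLE_GROUPS))
  if (length(planted)) {
    ctl_floor <- config$planted_min_tpm / config$planted_fold
    ctl_tpm <- ctl_floor * (1 + runif(length(planted)))
    tpm_true[planted, "egfp_neg"] <- ctl_tpm
    tpm_true[planted, "whole_head"] <- ctl_tpm
    tpm_true[planted, "egfp_pos"] <- ctl_tpm * config$planted_fold
  }
  # re-close each group's composition to 1e6
  tpm_true <- sweep(tpm_true, 2, 1e6 / colSums(tpm_true), `*`)

  reps <- config$n_replicates_per_group
  phi <- config$overdispersion_factor
  cols <- list()
  groups <- character(0)
  for (g in SAMPLE_GROUPS) {
    wt <- tpm_true[, g] * lengths_bp
    mu <- config$library_size_per_group[[g]] * wt / sum(wt)
    for (k in seq_len(reps)) {
      cols[[paste0(g, "_rep", k)]] <- .rcounts(n, mu, phi)
      groups <- c(groups, g)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- gene_ids

  dataset <- count_matrix(counts, lengths_bp, groups)
  truth <- data.frame(
    gene_id = gene_ids[planted],
    true_tpm_control = if (length(planted)) tpm_true[planted, "egfp_neg"] else numeric(0),
    true_tpm_egfp_pos = if (length(planted)) tpm_true[planted, "egfp_pos"] else numeric(0),
    stringsAsFactors = FALSE
  )
  attr(truth, "config") <- config
  list(dataset = dataset, truth = truth)
}
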