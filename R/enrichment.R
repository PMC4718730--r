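#' Configuration of the enrichment caller
#'
#' Collects the statistical and filtering parameters of the two-tier
#' enrichment criteria. Defaults are the published thresholds: significance at
#' Bonferroni-corrected p < 0.01; strict tier at >= 100 TPM in the sorted
#' cells and >= 7-fold over the larger control; relaxed tier at >= 10 TPM and
#' >= 3.6-fold; and only genes averaging more than 15 raw reads in the sorted
#' samples are tested at all.
#'
#' @param alpha family-wise significance level after Bonferroni correction.
#' @param strict_tpm,strict_fold strict-tier abundance (TPM) and fold cutoffs.
#' @param relaxed_tpm,relaxed_fold relaxed-tier cutoffs; must not exceed the
#'   strict ones.
#' @param reads_floor genes at or below this mean raw read count in the sorted
#'   replicates are excluded from testing (and from the Bonferroni family).
#' @param overdispersion `"estimate"` (from replicate variability) or
#'   `"fixed"` (use `phi`).
#' @param phi fixed variance-inflation factor when `overdispersion = "fixed"`.
#' @param pooling `"pooled"` tests summed replicate groups; `"per_replicate"`
#'   tests each sorted replicate against each pooled control and keeps the
#'   largest p-value.
#' @param pseudocount TPM pseudocount for fold changes (see [fold_change()]).
#' @return list of class `enrichment_config`.
#' @export
enrichment_config <- function(alpha = 0.01,
                              strict_tpm = 100, strict_fold = 7,
                              relaxed_tpm = 10, relaxed_fold = 3.6,
                              reads_floor = 15,
                              overdispersion = c("estimate", "fixed"),
                              phi = 1,
                              pooling = c("pooled", "per_replicate"),
                              pseudocount = 1) {
  overdispersion <- match.arg(overdispersion)
  pooling <- match.arg(pooling)
  if (relaxed_tpm > strict_tpm || relaxed_fold > strict_fold) {
    stop("relaxed thresholds must not exceed strict thresholds")
  }
  if (phi < 1) stop("phi must be >= 1")
  structure(
    list(
      alpha = alpha, strict_tpm = strict_tpm, strict_fold = strict_fold,
      relaxed_tpm = relaxed_tpm, relaxed_fold = relaxed_fold,
      reads_floor = reads_floor, overdispersion = overdispersion, phi = phi,
      pooling = pooling, pseudocount = pseudocount
    ),
    class = "enrichment_config"
  )
}

#' Estimate the variance-inflation factor from replicate variability
#'
#' Low-input FACS/RNA-seq libraries go through heavy amplification, so the
#' replicate-to-replicate variance of a gene's count exceeds the Poisson
#' expectation (variance = mean). The inflation factor phi is estimated as the
#' median, over well-expressed genes (overall mean count >= `min_mean`), of
#' the per-gene within-group variance/mean ratio averaged across replicate
#' groups, floored at 1 (counts can never be under-dispersed for the purposes
#' of the test).
#'
#' @param x a [count_matrix()] with replicate columns.
#' @param min_mean minimum overall mean count for a gene to enter the median.
#' @return phi >= 1. If no group has two or more replicates, returns 1 with a
#'   warning.
#' @export
estimate_overdispersion <- function(x, min_mean = 10) {
  stopifnot(inherits(x, "count_matrix"))
  groups <- unique(x$groups)
  multi <- groups[vapply(groups, function(g) sum(x$groups == g) >= 2, logical(1))]
  if (!length(multi)) {
    warning("no group has >= 2 replicates; returning phi = 1")
    return(1)
  }
  eligible <- rowMeans(x$counts) >= min_mean
  if (!any(eligible)) {
    warning("no gene passes the mean-count floor; returning phi = 1")
    return(1)
  }
  ratios <- vapply(multi, function(g) {
    sub <- x$counts[eligible, x$groups == g, drop = FALSE]
    mu <- rowMeans(sub)
    v <- apply(sub, 1, var)
    ifelse(mu > 0, v / mu, NA_real_)
  }, numeric(sum(eligible)))
  ratios <- as.matrix(ratios)
  per_gene <- rowMeans(ratios, na.rm = TRUE)
  max(1, median(per_gene, na.rm = TRUE))
}

#' Exact conditional test for a difference between two Poisson counts
#'
#' Tests whether counts `a` and `b`, observed at sequencing depths `lib_a`
#' and `lib_b`, differ beyond Poisson noise. Conditional on the total
#' n = a + b, `a` is Binomial(n, lib_a / (lib_a + lib_b)) under the null of
#' equal underlying concentration; the two-sided p-value doubles the smaller
#' tail (point included) and is capped at 1. Variance inflation (phi > 1) is
#' handled quasi-Poisson style: both counts are deflated by phi (and rounded)
#' before testing, which restores the Poisson mean-variance relation.
#'
#' All arguments are vectorized over genes.
#'
#' @param a,b non-negative counts.
#' @param lib_a,lib_b positive library sizes (any common scale).
#' @param phi variance-inflation factor >= 1.
#' @return p-value(s) in (0, 1]; a pair of zero counts gives p = 1.
#' @export
poisson_pair_test <- function(a, lib_a, b, lib_b, phi = 1) {
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  if (any(lib_a <= 0) || any(lib_b <= 0)) stop("library sizes must be positive")
  if (any(phi < 1)) stop("phi must be >= 1")
  a2 <- round(a / phi)
  b2 <- round(b / phi)
  n <- a2 + b2
  pr <- lib_a / (lib_a + lib_b)
  lower <- pbinom(a2, n, pr)
  upper <- pbinom(a2 - 1, n, pr, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[n == 0] <- 1
  p
}

#' Classify a transcript into the strict/relaxed enrichment tiers
#'
#' Strict: abundance >= `strict_tpm` in the sorted cells, fold over the larger
#' control >= `strict_fold`, Bonferroni-adjusted p below `alpha`, and the raw
#' read floor met. Relaxed: the same with the relaxed cutoffs. Strict
#' membership implies relaxed membership by the config invariant.
#'
#' @param tpm_pos abundance in the sorted population (TPM), vectorized.
#' @param fold fold change over the larger control, vectorized.
#' @param p_adjusted Bonferroni-adjusted p (NA for untested genes).
#' @param mean_raw_reads mean raw read count in the sorted replicates.
#' @param config an [enrichment_config()].
#' @return character vector in `c("strict", "relaxed", "none")`.
#' @export
classify_enrichment <- function(tpm_pos, fold, p_adjusted, mean_raw_reads,
                                config = enrichment_config()) {
  sig <- !is.na(p_adjusted) & p_adjusted < config$alpha &
    mean_raw_reads > config$reads_floor
  strict <- sig & tpm_pos >= config$strict_tpm & fold >= config$strict_fold
  relaxed <- sig & tpm_pos >= config$relaxed_tpm & fold >= config$relaxed_fold
  ifelse(strict, "strict", ifelse(relaxed, "relaxed", "none"))
}

#' Call neuron-enriched transcripts from a replicated count matrix
#'
#' The full enrichment caller: estimates (or takes) the variance-inflation
#' factor, pools replicates, computes TPM on the pooled groups, tests each
#' gene's sorted count against both control groups with [poisson_pair_test()]
#' at TMM-derived effective library sizes, combines the two tests by taking
#' the larger p-value (enrichment must hold against *both* controls),
#' Bonferroni-adjusts over the genes passing the raw-read floor, classifies
#' the tiers, and returns the records with fold change above the relaxed
#' cutoff, sorted by decreasing fold (ties broken by gene id).
#'
#' @param x a [count_matrix()] containing all three groups (`egfp_pos`,
#'   `egfp_neg`, `whole_head`).
#' @param config an [enrichment_config()].
#' @param emit_all emit every gene rather than only those above the relaxed
#'   fold cutoff (useful for calibration studies; default FALSE).
#' @return data.frame with one row per reported transcript: `gene_id`,
#'   `tpm_egfp_pos`, `tpm_egfp_neg`, `tpm_whole_head`, `fold_vs_max_control`,
#'   `mean_raw_reads_egfp_pos`, `p_raw`, `p_adjusted`, `tier`. The estimated
#'   phi and the number of tested genes are attached as attributes `phi` and
#'   `n_tested`.
#' @export
run_enrichment_pipeline <- function(x, config = enrichment_config(),
                                    emit_all = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  missing_groups <- setdiff(SAMPLE_GROUPS, unique(x$groups))
  if (length(missing_groups)) {
    stop("missing sample group(s): ", paste(missing_groups, collapse = ", "))
  }
  phi <- switch(config$overdispersion,
    estimate = estimate_overdispersion(x),
    fixed = config$phi
  )

  mean_reads_pos <- rowMeans(x$counts[, x$groups == "egfp_pos", drop = FALSE])
  pooled <- pool_replicates(x)
  tpm <- compute_tpm(pooled)
  tmm <- tmm_factors(pooled, reference_sample = "egfp_pos")

  controls <- c("egfp_neg", "whole_head")
  a <- pooled$counts[, "egfp_pos"]
  if (config$pooling == "pooled") {
    p_each <- vapply(controls, function(ctl) {
      poisson_pair_test(a, 1, pooled$counts[, ctl], tmm[ctl], phi = phi)
    }, numeric(length(a)))
  } else {
    pos_cols <- which(x$groups == "egfp_pos")
    pos_libs <- colSums(x$counts[, pos_cols, drop = FALSE])
    p_each <- vapply(controls, function(ctl) {
      b <- pooled$counts[, ctl]
      lib_b <- sum(x$counts[, x$groups == ctl, drop = FALSE])
      p_reps <- vapply(seq_along(pos_cols), function(i) {
        poisson_pair_test(
          x$counts[, pos_cols[i]], pos_libs[i], b, lib_b, phi = phi
        )
      }, numeric(nrow(x$counts)))
      apply(as.matrix(p_reps), 1, max)
    }, numeric(length(a)))
  }
  p_raw <- apply(as.matrix(p_each), 1, max)

  tested <- mean_reads_pos > config$reads_floor
  m <- sum(tested)
  p_adj <- rep(NA_real_, length(p_raw))
  p_adj[tested] <- pmin(1, m * p_raw[tested])

  fold <- fold_change(
    tpm[, "egfp_pos"], tpm[, controls, drop = FALSE],
    pseudocount = config$pseudocount
  )
  tier <- classify_enrichment(
    tpm[, "egfp_pos"], fold, p_adj, mean_reads_pos, config
  )

  res <- data.frame(
    gene_id = x$gene_ids,
    tpm_egfp_pos = tpm[, "egfp_pos"],
    tpm_egfp_neg = tpm[, "egfp_neg"],
    tpm_whole_head = tpm[, "whole_head"],
    fold_vs_max_control = fold,
    mean_raw_reads_egfp_pos = mean_reads_pos,
    p_raw = p_raw,
    p_adjusted = p_adj,
    tier = tier,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  if (!emit_all) {
    res <- res[res$fold_vs_max_control > config$relaxed_fold, , drop = FALSE]
  }
  res <- res[order(-res$fold_vs_max_control, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "phi") <- phi
  attr(res, "n_tested") <- m
  res
}
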