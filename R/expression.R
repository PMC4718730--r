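#' The three sample groups of the sorting experiment
#'
#' FACS-sorted fluorescent cells (`egfp_pos`), the non-fluorescent sorted
#' fraction (`egfp_neg`) and unsorted whole-head tissue (`whole_head`); the
#' latter two are the controls the enrichment caller tests against.
#'
#' @export
SAMPLE_GROUPS <- c("egfp_pos", "egfp_neg", "whole_head")

#' Construct a validated count matrix
#'
#' Bundles gene-level read counts with transcript lengths and a sample-to-group
#' assignment. This is the input container for every expression-level
#' operation: TPM computation, TMM scaling, replicate pooling and the
#' enrichment caller.
#'
#' @param counts integer-like matrix, genes x samples, non-negative; rownames
#'   are gene ids, colnames sample labels.
#' @param lengths_bp positive integer vector of transcript lengths, one per
#'   gene (recycled names from `counts` rownames if unnamed).
#' @param groups character vector, one group per sample column; values must be
#'   among [SAMPLE_GROUPS].
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `lengths_bp`, `groups`, `gene_ids`, `samples`.
#' @export
count_matrix <- function(counts, lengths_bp, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids in counts")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (length(lengths_bp) != nrow(counts)) {
    stop("lengths_bp must have one entry per gene")
  }
  if (any(lengths_bp <= 0)) stop("transcript lengths must be positive")
  groups <- as.character(groups)
  if (length(groups) != ncol(counts)) {
    stop("groups must have one entry per sample")
  }
  bad <- setdiff(unique(groups), SAMPLE_GROUPS)
  if (length(bad)) {
    stop("unknown sample group(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      counts = counts,
      lengths_bp = setNames(as.numeric(lengths_bp), rownames(counts)),
      groups = setNames(groups, colnames(counts)),
      gene_ids = rownames(counts),
      samples = colnames(counts)
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(
    "count_matrix:", length(x$gene_ids), "genes x", length(x$samples),
    "samples\n"
  )
  cat("  groups:", paste(sprintf(
    "%s=%d", names(table(x$groups)), as.integer(table(x$groups))
  ), collapse = ", "), "\n")
  invisible(x)
}

#' Transcripts-per-million normalization
#'
#' For each sample, counts are divided by transcript length (reads per base),
#' then rescaled so that the values sum to one million:
#' \deqn{TPM_g = 10^6 \frac{c_g / l_g}{\sum_j c_j / l_j}.}
#' TPM is the scale on which the enrichment caller's abundance thresholds are
#' expressed.
#'
#' @param x a [count_matrix()].
#' @return numeric matrix of the same dimensions; each column sums to 1e6
#'   except all-zero columns, which stay zero (with a warning).
#' @export
compute_tpm <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  rate <- x$counts / x$lengths_bp
  totals <- colSums(rate)
  if (any(totals == 0)) {
    warning(
      "all-zero sample column(s): ",
      paste(colnames(x$counts)[totals == 0], collapse = ", ")
    )
  }
  scale <- ifelse(totals > 0, 1e6 / totals, 0)
  sweep(rate, 2, scale, `*`)
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Between-sample scaling factors from a doubly trimmed, precision-weighted
#' mean of per-gene log2 count ratios against a reference sample. Genes with a
#' zero count in either sample are excluded; the most extreme fractions of the
#' log-ratio (M) and average log-abundance (A) distributions are trimmed; the
#' remaining M values are averaged with inverse asymptotic-variance weights.
#'
#' The factor is on the raw-count scale: it is the number that multiplies the
#' reference sample's counts to match the target sample, so a sample identical
#' to the reference gets factor 1 and a sample with every count doubled gets
#' factor 2. Factors divided by library size give the usual composition-bias
#' correction.
#'
#' @param x a [count_matrix()].
#' @param reference_sample column name (or index) of the reference; must have
#'   a positive total count.
#' @param trim_m two-sided trim fraction on M (default 0.3).
#' @param trim_a two-sided trim fraction on A (default 0.05).
#' @param weighted use inverse asymptotic-variance weights (default TRUE).
#' @return named numeric vector of factors, one per sample; the reference's
#'   factor is exactly 1.
#' @export
tmm_factors <- function(x, reference_sample = 1, trim_m = 0.3, trim_a = 0.05,
                        weighted = TRUE) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  ref_idx <- if (is.character(reference_sample)) {
    match(reference_sample, colnames(counts))
  } else {
    as.integer(reference_sample)
  }
  if (is.na(ref_idx) || ref_idx < 1 || ref_idx > ncol(counts)) {
    stop("reference_sample not found")
  }
  ref <- counts[, ref_idx]
  n_ref <- sum(ref)
  if (n_ref <= 0) stop("reference sample has zero total count")
  ref_name <- colnames(counts)[ref_idx]

  factors <- vapply(colnames(counts), function(s) {
    if (s == ref_name) return(1)
    obs <- counts[, s]
    keep <- obs > 0 & ref > 0
    if (!any(keep)) {
      stop("sample '", s, "' shares no nonzero genes with the reference")
    }
    o <- obs[keep]
    r <- ref[keep]
    m <- log2(o / r)
    a <- 0.5 * log2(o * r)
    lo_m <- quantile(m, trim_m)
    hi_m <- quantile(m, 1 - trim_m)
    lo_a <- quantile(a, trim_a)
    hi_a <- quantile(a, 1 - trim_a)
    use <- m >= lo_m & m <= hi_m & a >= lo_a & a <= hi_a
    if (!any(use)) use <- rep(TRUE, length(m))
    n_obs <- sum(obs)
    w <- if (weighted) {
      1 / ((n_obs - o[use]) / (n_obs * o[use]) + (n_ref - r[use]) / (n_ref * r[use]))
    } else {
      rep(1, sum(use))
    }
    2^(sum(w * m[use]) / sum(w))
  }, numeric(1))
  factors
}

#' Pool replicate samples into one column per group
#'
#' Replicates within each sample group are summed gene-wise, yielding one
#' pooled column per group. Pooling increases the per-gene read cover and
#' averages out amplification noise between replicates; the enrichment caller
#' runs on pooled groups by default.
#'
#' @param x a [count_matrix()].
#' @return a [count_matrix()] with one column per group, named by group.
#' @export
pool_replicates <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  groups <- unique(x$groups)
  pooled <- vapply(groups, function(g) {
    rowSums(x$counts[, x$groups == g, drop = FALSE])
  }, numeric(nrow(x$counts)))
  colnames(pooled) <- groups
  count_matrix(pooled, x$lengths_bp, groups)
}

#' Fold change of the sorted population over the larger control
#'
#' The enrichment criterion requires a transcript to be more abundant in the
#' sorted (EGFP+) cells than in *both* controls, so the denominator is the
#' larger of the two control abundances. A pseudocount guards against zero
#' controls.
#'
#' @param tpm_pos abundance in the sorted population (TPM).
#' @param tpm_controls numeric vector or matrix (genes x controls) of control
#'   abundances; the maximum per gene is used.
#' @param pseudocount added to numerator and denominator (default 1 TPM).
#' @return numeric fold change(s), `(tpm_pos + pc) / (max(controls) + pc)`.
#' @export
fold_change <- function(tpm_pos, tpm_controls, pseudocount = 1) {
  if (any(tpm_pos < 0) || any(tpm_controls < 0)) {
    stop("TPM values must be non-negative")
  }
  ctl <- if (is.matrix(tpm_controls)) {
    apply(tpm_controls, 1, max)
  } else if (length(tpm_pos) == 1L) {
    max(tpm_controls)
  } else {
    tpm_controls
  }
  (tpm_pos + pseudocount) / (ctl + pseudocount)
}
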