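#' Keep reference-species PWM hits conserved across all species
#'
#' A binding-site prediction in the reference species is retained only if
#' every other species' promoter for the same gene carries a
#' threshold-passing hit for the same matrix at an approximately aligned
#' position (start offsets within `window` bp). Equal-length promoter windows
#' stand in for a true multiple alignment; with a single species the filter
#' is the identity.
#'
#' @param hits data.frame from [scan_promoters()] (one PWM).
#' @param species character vector of all species in the promoter set (some
#'   may have no hits at all).
#' @param reference reference species (default the first).
#' @param window positional tolerance in bp (default 10).
#' @return the subset of `hits` rows in the reference species that are
#'   conserved.
#' @export
filter_conserved_hits <- function(hits, species, reference = species[1],
                                  window = 10) {
  stopifnot(is.data.frame(hits))
  species <- unique(as.character(species))
  if (!reference %in% species) stop("reference species not in species list")
  ref_hits <- hits[hits$species == reference, , drop = FALSE]
  if (length(species) == 1L || !nrow(ref_hits)) {
    rownames(ref_hits) <- NULL
    return(ref_hits)
  }
  others <- setdiff(species, reference)
  keep <- vapply(seq_len(nrow(ref_hits)), function(i) {
    g <- ref_hits$gene_id[i]
    o <- ref_hits$offset[i]
    all(vapply(others, function(sp) {
      cand <- hits[hits$species == sp & hits$gene_id == g, , drop = FALSE]
      nrow(cand) > 0 && any(abs(cand$offset - o) <= window)
    }, logical(1)))
  }, logical(1))
  out <- ref_hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combined per-gene binding-site score for one transcription factor
#'
#' Aggregates all conserved predicted sites of one TF in one gene's promoter
#' into a single score, so that a gene whose promoter over-represents the
#' TF's site scores high. The default rule sums each hit's excess over the
#' matrix threshold (every summand is non-negative by the hit definition, so
#' adding a site never lowers the score); `"max"` keeps the largest excess,
#' `"count"` the number of sites.
#'
#' @param hits data.frame of conserved hits for a single gene/TF (columns
#'   `score`; may be empty).
#' @param threshold the matrix threshold the excesses are measured from.
#' @param method `"sum"` (default), `"max"` or `"count"`.
#' @return non-negative scalar; 0 when there are no hits.
#' @export
combined_gene_score <- function(hits, threshold, method = c("sum", "max", "count")) {
  method <- match.arg(method)
  if (!nrow(hits)) return(0)
  excess <- hits$score - threshold
  switch(method,
    sum = sum(excess),
    max = max(excess),
    count = as.numeric(nrow(hits))
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1.
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted p-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Transcription-factor set enrichment in a foreground gene set
#'
#' For each TF, tests whether genes carrying at least one conserved binding
#' site are over-represented among the foreground genes (e.g. the most
#' enriched neuron-specific transcripts) relative to the background, with a
#' one-sided hypergeometric tail; p-values are BH-adjusted across TFs.
#'
#' @param foreground character vector of foreground gene ids (subset of
#'   `background`, non-empty).
#' @param background character vector of all gene ids considered.
#' @param hit_genes named list, one element per TF, each a character vector of
#'   genes with >= 1 conserved hit for that TF.
#' @param scores optional named list (parallel to `hit_genes`) of per-gene
#'   combined scores to carry through.
#' @return data.frame sorted by `p_raw` (ties by `tf_name`): `tf_name`,
#'   `n_fg_hits`, `n_bg_hits`, `p_raw`, `p_bh`, and a list-column
#'   `target_genes` of foreground genes with hits.
#' @export
tf_set_enrichment <- function(foreground, background, hit_genes,
                              scores = NULL) {
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  if (!length(foreground)) stop("foreground gene set is empty")
  if (length(setdiff(foreground, background))) {
    stop("foreground must be a subset of background")
  }
  if (!length(hit_genes)) stop("need at least one TF")
  N <- length(background)
  n_fg <- length(foreground)
  res <- lapply(names(hit_genes), function(tf) {
    carriers <- intersect(unique(hit_genes[[tf]]), background)
    K <- length(carriers)
    fg_hits <- intersect(carriers, foreground)
    k <- length(fg_hits)
    p <- phyper(k - 1, K, N - K, n_fg, lower.tail = FALSE)
    data.frame(tf_name = tf, n_fg_hits = k, n_bg_hits = K,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bh <- bh_adjust(out$p_raw)
  out$target_genes <- lapply(names(hit_genes), function(tf) {
    intersect(unique(hit_genes[[tf]]), foreground)
  })
  out <- out[order(out$p_raw, out$tf_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' End-to-end promoter TF analysis for one PWM set
#'
#' Scans every promoter with every matrix, applies the conservation filter,
#' computes per-gene combined scores, and runs the TF-set enrichment of the
#' foreground against the background.
#'
#' @param promoters named character vector / `DNAStringSet`, names
#'   `gene|species`.
#' @param pwms named list of [pwm()] objects.
#' @param foreground foreground gene ids.
#' @param background background gene ids (default: all genes in the promoter
#'   set).
#' @param window conservation tolerance in bp.
#' @param score_method passed to [combined_gene_score()].
#' @return list with `enrichment` (the [tf_set_enrichment()] table),
#'   `conserved_hits` (per-TF data.frames) and `combined_scores` (per-TF named
#'   vectors over genes with hits).
#' @export
run_tf_analysis <- function(promoters, pwms, foreground,
                            background = NULL, window = 10,
                            score_method = "sum") {
  seqs <- if (is.character(promoters)) promoters else as.character(promoters)
  if (is.null(names(seqs))) names(seqs) <- names(promoters)
  promoters <- seqs
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  genes <- unique(vapply(parts, `[`, character(1), 1))
  species <- unique(vapply(parts, function(p) {
    if (length(p) >= 2) p[2] else "sp1"
  }, character(1)))
  if (is.null(background)) background <- genes

  conserved <- lapply(pwms, function(p) {
    filter_conserved_hits(scan_promoters(promoters, p), species,
                          window = window)
  })
  names(conserved) <- vapply(pwms, `[[`, character(1), "tf_name")
  hit_genes <- lapply(conserved, function(h) unique(h$gene_id))
  combined <- lapply(names(conserved), function(tf) {
    h <- conserved[[tf]]
    thr <- pwms[[match(tf, vapply(pwms, `[[`, character(1), "tf_name"))]]$threshold
    if (!nrow(h)) return(setNames(numeric(0), character(0)))
    vapply(split(h, h$gene_id), combined_gene_score, numeric(1),
           threshold = thr, method = score_method)
  })
  names(combined) <- names(conserved)
  enr <- tf_set_enrichment(foreground, background, hit_genes)
  list(enrichment = enr, conserved_hits = conserved,
       combined_scores = combined)
}
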