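DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix with a per-matrix score threshold
#'
#' Per-position base frequencies (or counts) are regularized with a
#' background-proportional pseudocount and converted to log2-odds against the
#' background. A window of sequence is scored by summing the log-odds of its
#' bases; windows scoring at or above the matrix threshold are reported as
#' binding-site hits. The default threshold is a fixed fraction of the best
#' attainable score, mirroring the per-matrix thresholds of curated matrix
#' databases without reproducing any proprietary content.
#'
#' @param matrix 4 x L numeric matrix of frequencies or counts; rows A, C, G,
#'   T (rownames optional, this order assumed).
#' @param tf_name transcription-factor name.
#' @param pseudocount total pseudocount mass per position, split according to
#'   the background (default 0.01; use ~1 for raw count matrices).
#' @param background nucleotide probabilities, default uniform.
#' @param threshold absolute score threshold; if `NULL`, set to
#'   `threshold_fraction` of the maximal attainable score.
#' @param threshold_fraction fraction of the maximum score (default 0.85).
#' @return object of class `pwm` with elements `tf_name`, `freq` (normalized
#'   frequencies), `score_matrix` (4 x L log2-odds), `threshold`,
#'   `max_score`, `background`, `length`.
#' @export
pwm <- function(matrix, tf_name = "TF", pseudocount = 0.01,
                background = rep(0.25, 4), threshold = NULL,
                threshold_fraction = 0.85) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(matrix) < 4) stop("PWM must have length >= 4")
  if (any(matrix < 0)) stop("PWM entries must be non-negative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-8) {
    stop("background must be 4 probabilities summing to 1")
  }
  rownames(matrix) <- DNA_BASES
  freq <- sweep(matrix + pseudocount * background, 2,
                colSums(matrix) + pseudocount, `/`)
  score_matrix <- log2(freq / background)
  max_score <- sum(apply(score_matrix, 2, max))
  if (is.null(threshold)) threshold <- threshold_fraction * max_score
  if (threshold > max_score) {
    stop("threshold exceeds the maximal attainable score")
  }
  structure(
    list(
      tf_name = tf_name, freq = freq, score_matrix = score_matrix,
      threshold = threshold, max_score = max_score,
      background = background, length = ncol(matrix)
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf(
    "pwm '%s': length %d, threshold %.3f (max %.3f), consensus %s\n",
    x$tf_name, x$length, x$threshold, x$max_score, pwm_consensus(x)
  ))
  invisible(x)
}

#' Consensus sequence of a PWM (highest-frequency base per position)
#' @param x a [pwm()].
#' @return character string of length `x$length`.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$freq, 2, which.max)], collapse = "")
}

#' Read TRANSFAC-style plain-text matrices
#'
#' Parses the minimal TRANSFAC dialect: records delimited by `//`, a name on
#' the `ID` (or `NA`) line, a `PO`/`P0` column-header line, then numbered rows
#' `01 <A> <C> <G> <T> [consensus]`.
#'
#' @param path file path.
#' @param ... passed to [pwm()] (pseudocount, background, threshold_fraction).
#' @return named list of [pwm()] objects.
#' @export
read_transfac <- function(path, ...) {
  lines <- readLines(path)
  out <- list()
  name <- NULL
  rows <- list()
  in_matrix <- FALSE
  flush <- function() {
    if (!length(rows)) return()
    m <- t(vapply(rows, identity, numeric(4)))
    nm <- if (is.null(name)) paste0("TF", length(out) + 1) else name
    out[[nm]] <<- pwm(t(m), tf_name = nm, ...)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "" ) next
    tag <- substr(ln, 1, 2)
    if (tag == "//") {
      flush(); name <- NULL; rows <- list(); in_matrix <- FALSE
    } else if (tag %in% c("ID", "NA")) {
      val <- trimws(substring(ln, 3))
      if (tag == "NA" || is.null(name)) name <- val
    } else if (tag %in% c("PO", "P0")) {
      in_matrix <- TRUE
    } else if (in_matrix && grepl("^[0-9]+\\s", ln)) {
      parts <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts[2:5]))
      if (any(is.na(vals))) stop("malformed matrix row: ", ln)
      rows[[length(rows) + 1]] <- vals
    }
  }
  flush()
  out
}

#' Write PWMs in the TRANSFAC-style plain-text dialect
#' @param pwms list of [pwm()] objects.
#' @param path output file.
#' @export
write_transfac <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(c(
      paste("ID", p$tf_name),
      "PO A C G T"
    ), con)
    for (j in seq_len(p$length)) {
      writeLines(sprintf(
        "%02d %.6g %.6g %.6g %.6g %s", j,
        p$freq[1, j], p$freq[2, j], p$freq[3, j], p$freq[4, j],
        DNA_BASES[which.max(p$freq[, j])]
      ), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# Encode a sequence as integer indices into DNA_BASES (NA for N/other).
.encode_seq <- function(seq) {
  match(strsplit(toupper(as.character(seq)), "")[[1]], DNA_BASES)
}

.revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(as.character(seq), "")[[1]]),
                                       collapse = ""))
}

# Score every window of an encoded sequence against the score matrix.
# Returns a numeric vector of window scores (NA where a window contains N).
.scan_encoded <- function(enc, score_matrix) {
  L <- ncol(score_matrix)
  n_win <- length(enc) - L + 1
  if (n_win < 1) return(numeric(0))
  scores <- numeric(n_win)
  for (j in seq_len(L)) {
    b <- enc[j:(j + n_win - 1)]
    scores <- scores + score_matrix[cbind(b, j)]
  }
  scores
}

#' Scan a promoter sequence for PWM hits on both strands
#'
#' Slides the matrix over every window of the sequence and of its reverse
#' complement; windows containing `N` are skipped. Hits are windows scoring at
#' or above the matrix threshold, reported in ascending start offset with the
#' plus strand before the minus strand at equal offset. Minus-strand offsets
#' refer to the match start on the forward (promoter) coordinates.
#'
#' @param seq nucleotide string over A, C, G, T, N (case-insensitive).
#' @param pwm a [pwm()].
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return data.frame with columns `offset` (0-based), `strand` (`+`/`-`),
#'   `score`; empty when the sequence is shorter than the matrix.
#' @export
scan_sequence <- function(seq, pwm, both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"))
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  seq <- as.character(seq)
  n <- nchar(seq)
  L <- pwm$length
  if (n < L) return(empty)
  enc <- .encode_seq(seq)
  fwd <- .scan_encoded(enc, pwm$score_matrix)
  hits <- list()
  keep <- which(!is.na(fwd) & fwd >= pwm$threshold)
  if (length(keep)) {
    hits[["+"]] <- data.frame(offset = keep - 1L, strand = "+",
                              score = fwd[keep], stringsAsFactors = FALSE)
  }
  if (both_strands) {
    enc_rc <- rev(5L - enc)  # A<->T, C<->G on the index scale; NA stays NA
    rc <- .scan_encoded(enc_rc, pwm$score_matrix)
    keep <- which(!is.na(rc) & rc >= pwm$threshold)
    if (length(keep)) {
      # window starting at i (1-based) on the revcomp covers forward
      # positions [n - i - L + 2, n - i + 1], i.e. 0-based start n - i - L + 1
      hits[["-"]] <- data.frame(offset = n - keep - L + 1L, strand = "-",
                                score = rc[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a set of promoters (one record per gene/species) for one PWM
#'
#' @param promoters named character vector or `Biostrings::DNAStringSet`;
#'   names follow the `gene|species` convention of [simulate_promoter_set()]
#'   (a bare `gene` name implies a single unnamed species `sp1`).
#' @param pwm a [pwm()].
#' @param both_strands passed to [scan_sequence()].
#' @return data.frame of hits with columns `gene_id`, `species`, `offset`,
#'   `strand`, `score`.
#' @export
scan_promoters <- function(promoters, pwm, both_strands = TRUE) {
  seqs <- if (is.character(promoters)) promoters else as.character(promoters)
  if (is.null(names(seqs))) stop("promoters must be named (gene|species)")
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  gene <- vapply(parts, `[`, character(1), 1)
  species <- vapply(parts, function(p) {
    if (length(p) >= 2) p[2] else "sp1"
  }, character(1))
  res <- lapply(seq_along(seqs), function(i) {
    h <- scan_sequence(seqs[[i]], pwm, both_strands)
    if (!nrow(h)) return(NULL)
    cbind(data.frame(gene_id = gene[i], species = species[i],
                     stringsAsFactors = FALSE), h)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(gene_id = character(0), species = character(0),
                      offset = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
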