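#' Simulate a multi-species promoter set with planted motif instances
#'
#' Generates one uniform-random promoter per gene per species. A chosen
#' fraction of a designated foreground set carries a planted instance of the
#' motif at the same recorded offset in *every* species (a conserved site);
#' each remaining gene independently carries, with probability
#' `background_rate`, an instance in a single random species only (a
#' non-conserved site the conservation filter should drop). Planted instances
#' are sampled per species from the PWM's frequency model, redrawn until they
#' clear the matrix threshold (consensus as fallback), so every planted site
#' is detectable by construction.
#'
#' @param n_genes total number of genes.
#' @param n_foreground size of the foreground set (the first
#'   `n_foreground` gene ids); planted genes are drawn from it.
#' @param promoter_length promoter length in bp (>= motif length).
#' @param motif a [pwm()].
#' @param planted_fraction_foreground fraction of foreground genes receiving
#'   a conserved planted instance.
#' @param background_rate probability that a non-planted gene carries a
#'   single-species instance.
#' @param n_species number of species; the first (`sp1`) is the reference.
#' @param seed integer seed.
#' @return list with `promoters` (named character vector, names
#'   `gene|species`) and `truth` (data.frame of placements: `gene_id`,
#'   `species` — `"all"` for conserved placements —, `offset`, `strand`).
#' @export
simulate_promoter_set <- function(n_genes, n_foreground = n_genes,
                                  promoter_length, motif,
                                  planted_fraction_foreground = 0.5,
                                  background_rate = 0.05,
                                  n_species = 3, seed = 1L) {
  stopifnot(inherits(motif, "pwm"))
  if (promoter_length < motif$length) {
    stop("promoter_length must be at least the motif length")
  }
  if (planted_fraction_foreground < 0 || planted_fraction_foreground > 1 ||
      background_rate < 0 || background_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (n_foreground > n_genes) stop("n_foreground must not exceed n_genes")
  set.seed(as.integer(seed))
  genes <- sprintf("g%04d", seq_len(n_genes))
  species <- paste0("sp", seq_len(n_species))
  L <- motif$length

  draw_seq <- function(len) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }
  sample_instance <- function() {
    for (i in 1:50) {
      inst <- vapply(seq_len(L), function(j) {
        sample(DNA_BASES, 1, prob = motif$freq[, j])
      }, character(1))
      sc <- sum(motif$score_matrix[cbind(match(inst, DNA_BASES), seq_len(L))])
      if (sc >= motif$threshold) return(paste(inst, collapse = ""))
    }
    pwm_consensus(motif)
  }
  implant <- function(seq, inst, offset) {
    paste0(substr(seq, 1, offset), inst,
           substr(seq, offset + L + 1, nchar(seq)))
  }

  promoters <- setNames(
    vapply(seq_len(n_genes * n_species), function(i) draw_seq(promoter_length),
           character(1)),
    as.vector(outer(genes, species, paste, sep = "|"))
  )

  n_planted <- round(planted_fraction_foreground * n_foreground)
  planted <- if (n_planted > 0) {
    sort(sample.int(n_foreground, n_planted))
  } else {
    integer(0)
  }
  placements <- list()
  for (gi in planted) {
    offset <- sample.int(promoter_length - L + 1, 1) - 1L
    for (sp in species) {
      key <- paste(genes[gi], sp, sep = "|")
      promoters[[key]] <- implant(promoters[[key]], sample_instance(), offset)
    }
    placements[[length(placements) + 1]] <- data.frame(
      gene_id = genes[gi], species = "all", offset = offset, strand = "+",
      stringsAsFactors = FALSE
    )
  }
  non_planted <- setdiff(seq_len(n_genes), planted)
  if (background_rate > 0) {
    carriers <- non_planted[runif(length(non_planted)) < background_rate]
    for (gi in carriers) {
      sp <- sample(species, 1)
      offset <- sample.int(promoter_length - L + 1, 1) - 1L
      key <- paste(genes[gi], sp, sep = "|")
      promoters[[key]] <- implant(promoters[[key]], sample_instance(), offset)
      placements[[length(placements) + 1]] <- data.frame(
        gene_id = genes[gi], species = sp, offset = offset, strand = "+",
        stringsAsFactors = FALSE
      )
    }
  }
  truth <- if (length(placements)) {
    do.call(rbind, placements)
  } else {
    data.frame(gene_id = character(0), species = character(0),
               offset = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  }
  attr(truth, "foreground") <- genes[seq_len(n_foreground)]
  attr(truth, "background") <- genes
  attr(truth, "seed") <- as.integer(seed)
  list(promoters = promoters, truth = truth)
}
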