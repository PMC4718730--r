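#' Assemble a pipeline configuration
#'
#' Bundles input paths and every stage parameter; round-trips losslessly
#' through JSON via [write_pipeline_config()] / [read_pipeline_config()].
#' Defaults are the published analysis parameters wherever the study states
#' one (significance, tier thresholds, reads floor, photoperiod, immobility
#' rule).
#'
#' @param counts_path TSV count matrix (required for the enrichment stage).
#' @param promoters_path optional FASTA of promoters (`gene|species` ids).
#' @param matrices_path optional TRANSFAC-style PWM file.
#' @param traces_path optional activity-cohort CSV.
#' @param out_dir output directory.
#' @param enrichment list of [enrichment_config()] arguments.
#' @param tf list: `threshold_fraction`, `window`, `n_foreground`,
#'   `score_method`.
#' @param sleep list: `photoperiod`, `epsilon`.
#' @param seed integer seed for all stochastic stages.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_path = NULL, promoters_path = NULL,
                            matrices_path = NULL, traces_path = NULL,
                            out_dir = "results",
                            enrichment = list(),
                            tf = list(threshold_fraction = 0.85, window = 10,
                                      n_foreground = 48,
                                      score_method = "sum"),
                            sleep = list(photoperiod = c(light = 14, dark = 10),
                                         epsilon = 0),
                            seed = 1L) {
  structure(
    list(counts_path = counts_path, promoters_path = promoters_path,
         matrices_path = matrices_path, traces_path = traces_path,
         out_dir = out_dir, enrichment = enrichment, tf = tf, sleep = sleep,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), character(0))])
  cfg
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", name))
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full analysis pipeline
#'
#' Enrichment calling on the count matrix, then (when promoters and matrices
#' are configured) the TF analysis on the promoters of the enriched set's
#' top genes, then (when traces are configured) cohort sleep scoring. Every
#' output TSV carries the full parameter set as `#param` comment lines;
#' outputs are deterministic given the config seed.
#'
#' @param config a [pipeline_config()] with at least `counts_path` set.
#' @return invisible list of the in-memory stage results; files
#'   `enriched.tsv`, `tf_results.tsv`, `sleep_summary.tsv` are written under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$counts_path)) {
    stop("[config] counts_path is required", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  enr_cfg <- do.call(enrichment_config, config$enrichment)
  enriched <- .stage("enrich", {
    counts <- read_count_matrix(config$counts_path)
    run_enrichment_pipeline(counts, enr_cfg)
  })
  write_results_tsv(
    enriched, file.path(config$out_dir, "enriched.tsv"),
    params = c(unclass(enr_cfg), list(seed = config$seed))
  )
  results$enriched <- enriched

  if (!is.null(config$promoters_path) && !is.null(config$matrices_path)) {
    tf_res <- .stage("tfscan", {
      promoters <- read_promoters(config$promoters_path)
      pwms <- read_transfac(config$matrices_path,
                            threshold_fraction = config$tf$threshold_fraction)
      genes <- unique(vapply(strsplit(names(promoters), "|", fixed = TRUE),
                             `[`, character(1), 1))
      n_fg <- min(config$tf$n_foreground, nrow(enriched))
      fg <- intersect(head(enriched$gene_id, n_fg), genes)
      if (!length(fg)) fg <- head(genes, config$tf$n_foreground)
      run_tf_analysis(promoters, pwms, foreground = fg,
                      window = config$tf$window,
                      score_method = config$tf$score_method)
    })
    write_results_tsv(
      tf_res$enrichment, file.path(config$out_dir, "tf_results.tsv"),
      params = c(config$tf, list(seed = config$seed))
    )
    results$tf <- tf_res
  }

  if (!is.null(config$traces_path)) {
    sleep_scores <- .stage("sleep", {
      cohort <- read_activity_cohort(config$traces_path)
      photoperiod <- unlist(config$sleep$photoperiod)
      score_cohort(cohort, photoperiod = photoperiod,
                   epsilon = config$sleep$epsilon)
    })
    write_results_tsv(
      sleep_scores, file.path(config$out_dir, "sleep_summary.tsv"),
      params = c(list(photoperiod_light = config$sleep$photoperiod[["light"]],
                      photoperiod_dark = config$sleep$photoperiod[["dark"]],
                      epsilon = config$sleep$epsilon, seed = config$seed))
    )
    results$sleep <- sleep_scores
  }
  invisible(results)
}
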