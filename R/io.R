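# Shared TSV/CSV dialects: tab separation, '.' for missing values, '#'
# header comment lines carrying provenance (the full parameter set).

.provenance_lines <- function(params) {
  if (is.null(params)) return(character(0))
  flat <- unlist(params)
  c("#hcrtseq", paste0("#param ", names(flat), "=", as.character(flat)))
}

#' Write a count matrix in the package's TSV dialect
#'
#' Columns: `gene_id`, `length_bp`, then one column per sample. A `#groups`
#' comment line above the header carries the sample-to-group assignment;
#' additional `#param` lines can carry provenance.
#'
#' @param x a [count_matrix()].
#' @param path output file.
#' @param params optional named list echoed as `#param` comment lines.
#' @export
write_count_matrix <- function(x, path, params = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_lines(params), con)
  writeLines(paste(c("#groups", "", unname(x$groups)), collapse = "\t"), con)
  writeLines(paste(c("gene_id", "length_bp", x$samples), collapse = "\t"), con)
  df <- cbind(gene_id = x$gene_ids, length_bp = x$lengths_bp,
              as.data.frame(x$counts))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a count matrix from the package's TSV dialect
#'
#' Strict parser: requires the `#groups` comment line, a header, integer
#' non-negative counts, positive lengths and unique gene ids; parse failures
#' report the offending line or sample.
#'
#' @param path input file.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  lines <- readLines(path)
  groups_line <- grep("^#groups\t", lines)
  if (!length(groups_line)) {
    stop("parse error: missing '#groups' header line in ", path)
  }
  groups <- strsplit(lines[groups_line[1]], "\t")[[1]][-(1:2)]
  header_idx <- groups_line[1] + 1
  while (header_idx <= length(lines) && startsWith(lines[header_idx], "#")) {
    header_idx <- header_idx + 1
  }
  header <- strsplit(lines[header_idx], "\t")[[1]]
  if (length(header) < 3 || header[1] != "gene_id" || header[2] != "length_bp") {
    stop("parse error at line ", header_idx,
         ": expected header 'gene_id\\tlength_bp\\t<samples...>'")
  }
  samples <- header[-(1:2)]
  if (length(groups) != length(samples)) {
    stop("parse error: #groups line lists ", length(groups),
         " groups for ", length(samples), " samples")
  }
  body <- lines[-seq_len(header_idx)]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  fields <- strsplit(body, "\t")
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    stop("parse error at line ",
         header_idx + which(nf != length(header))[1],
         ": wrong number of fields")
  }
  mat <- do.call(rbind, fields)
  gene_ids <- mat[, 1]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) {
    stop("parse error: duplicated gene id(s): ",
         paste(unique(dup), collapse = ", "))
  }
  lengths_bp <- suppressWarnings(as.numeric(mat[, 2]))
  counts <- suppressWarnings(
    matrix(as.numeric(mat[, -(1:2), drop = FALSE]), nrow = nrow(mat))
  )
  if (anyNA(lengths_bp) || anyNA(counts)) {
    bad <- which(apply(is.na(cbind(lengths_bp, counts)), 1, any))[1]
    stop("parse error at line ", header_idx + bad, ": non-numeric value")
  }
  if (any(counts != floor(counts))) {
    stop("parse error: non-integer count values")
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- samples
  count_matrix(counts, lengths_bp, groups)
}

#' Write promoters as FASTA (`gene|species` record ids)
#' @param promoters named character vector (names `gene|species`).
#' @param path output file.
#' @export
write_promoters <- function(promoters, path) {
  set <- Biostrings::DNAStringSet(unlist(as.character(promoters)))
  names(set) <- names(promoters)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read promoters from FASTA into the named-character representation
#' @param path input FASTA.
#' @return named character vector (names `gene|species`).
#' @export
read_promoters <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write an activity cohort as CSV
#' @param cohort data.frame from [simulate_activity_cohort()].
#' @param path output file.
#' @export
write_activity_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an activity cohort CSV
#' @param path input file.
#' @return data.frame with the [simulate_activity_cohort()] columns.
#' @export
read_activity_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("larva_id", "genotype", "minute_index", "activity", "light_phase")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("parse error: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (any(df$activity < 0)) stop("parse error: negative activity values")
  df
}

#' Write a results table as TSV with provenance comments
#' @param df data.frame (list-columns are dropped).
#' @param path output file.
#' @param params optional named list echoed as `#param` comment lines.
#' @export
write_results_tsv <- function(df, path, params = NULL) {
  df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance_lines(params), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "."))
  invisible(path)
}
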