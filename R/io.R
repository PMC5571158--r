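#' Read and write FASTA files
#'
#' Minimal lossless FASTA IO used across the pipeline; ids are the full
#' header lines after `>`, sequences are concatenated wrapped lines.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  if (hdr[1] != 1L) stop("malformed FASTA: sequence before first header, line 1")
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(k) {
    if (starts[k] > ends[k]) stop("empty FASTA record at line ", hdr[k])
    paste(lines[starts[k]:ends[k]], collapse = "")
  }, "")
  stats::setNames(seqs, sub("^>\\s*", "", lines[hdr]))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @param width line-wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  for (k in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[k]), con)
    s <- seqs[[k]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read and write Vienna-style 3-line structure records
#'
#' `>id`, sequence, dot-bracket with an optional trailing energy in
#' parentheses.
#'
#' @param path file path.
#' @return `hairpin_records` with `struct` filled; records without an energy
#'   annotation get energy 0.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3L != 0L)
    stop("malformed Vienna file: line count ", length(lines),
         " is not a multiple of 3")
  idx <- seq.int(1L, length(lines), by = 3L)
  ids <- character(0); seqs <- character(0)
  structs <- character(0); energies <- numeric(0)
  for (k in idx) {
    if (!startsWith(lines[k], ">"))
      stop("malformed Vienna record: expected '>' at line ", k)
    ids <- c(ids, sub("^>\\s*", "", lines[k]))
    seqs <- c(seqs, lines[k + 1L])
    sl <- lines[k + 2L]
    m <- regmatches(sl, regexec("^([().]+)(\\s+\\(\\s*(-?[0-9.]+)\\s*\\))?\\s*$", sl))[[1]]
    if (!length(m) || !nzchar(m[2]))
      stop("malformed structure line at line ", k + 2L)
    structs <- c(structs, m[2])
    energies <- c(energies, if (nzchar(m[4])) as.numeric(m[4]) else 0)
  }
  hairpin_records(seqs, id = ids, struct = structs, energy = energies,
                  source = path)
}

#' @rdname read_vienna
#' @param records `hairpin_records` with structures and energies.
#' @export
write_vienna <- function(records, path) {
  if (any(is.na(records$struct)))
    stop("records must be folded before writing Vienna format")
  con <- file(path, "w"); on.exit(close(con))
  for (r in seq_len(nrow(records))) {
    writeLines(c(paste0(">", records$id[r]), records$seq[r],
                 sprintf("%s (%.2f)", records$struct[r], records$energy[r])),
               con)
  }
  invisible(path)
}

#' Write candidates as BED6
#'
#' 0-based half-open intervals; the score column is 1000 x the averaged
#' ensemble score when present, else 0.
#'
#' @param cand `candidate_hairpins` (or any data.frame with chrom, start,
#'   end, strand).
#' @param path output path.
#' @export
write_bed <- function(cand, path) {
  score <- if ("avg_dt" %in% names(cand)) round(1000 * cand$avg_dt) else 0L
  name <- sprintf("cand_%s_%d_%s", cand$chrom, cand$start, cand$strand)
  df <- data.frame(cand$chrom, cand$start, cand$end, name, score, cand$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Feature-matrix TSV round trip with a JSON schema sidecar
#'
#' The TSV holds an `id` column plus one column per feature; the sidecar
#' (`<path>.schema.json`) records each column's registry group and backend
#' requirement so matrices stay self-describing.
#'
#' @param mat numeric feature matrix with rownames.
#' @param path TSV path.
#' @export
write_tsv_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  schema <- attr(mat, "schema")
  if (is.null(schema)) {
    reg <- feature_registry("partition_function")
    schema <- reg[match(colnames(mat), reg$name), ]
    schema$name <- colnames(mat) # non-registry columns keep their names
  }
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  sidecar <- paste0(path, ".schema.json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(mat, "schema") <- as.data.frame(sc)
  }
  mat
}

#' Write a JSON run manifest
#'
#' Records the configuration, seed, package version and input checksums of
#' a pipeline run so any result file can be regenerated from the manifest
#' plus the original inputs.
#'
#' @param path manifest path.
#' @param config named list of configuration values.
#' @param inputs character vector of input file paths (md5-summed).
#' @export
write_manifest <- function(path, config = list(), inputs = character(0)) {
  manifest <- list(
    tool = "premirna",
    version = as.character(utils::packageVersion("premirna")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    inputs = if (length(inputs))
      stats::setNames(as.list(tools::md5sum(inputs)), inputs) else list())
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
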