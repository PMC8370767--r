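# Readers and writers for the plain-text formats the pipeline exchanges:
# tab-separated matrices (first column = row id, header = sample ids), GMT
# gene-set files, two-column probe maps, clinical tables and limiting-dilution
# well tables.

#' Read a gene-by-sample expression matrix from TSV
#'
#' The file must have a header row of sample identifiers and a first column of
#' row (probe or gene) identifiers.
#'
#' @param path Path to a tab-separated file.
#' @return A numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a matrix as TSV
#'
#' @param mat Matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the row-identifier column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stop("malformed GMT line (need name, description, >=1 gene): ", parts[1L])
    }
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(ln) {
    strsplit(ln, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a probe-to-gene mapping table
#'
#' Two-column TSV (probe, gene) with a header. Probes mapping to more than one
#' gene are dropped with a warning, honouring the requirement that each
#' retained probe maps to exactly one gene.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `probe` and `gene`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("probe", "gene")
  dup <- unique(df$probe[duplicated(df$probe)])
  if (length(dup)) {
    warning(length(dup), " probes map to multiple genes; dropped")
    df <- df[!df$probe %in% dup, , drop = FALSE]
  }
  df[, c("probe", "gene")]
}

#' Read a clinical survival table
#'
#' TSV with columns sample id, survival time and event flag (0 = censored,
#' 1 = death); extra columns are kept.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `sample_id`, `time`, `event`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("sample_id", "time", "event")
  validate_survival_records(df)
  df
}

#' Read a limiting-dilution well-count table
#'
#' TSV with columns dose (cells/well), tested (wells plated), positive (wells
#' with at least one sphere) and group.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `dose`, `tested`, `positive`, `group`.
#' @export
read_lda_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:4] <- c("dose", "tested", "positive", "group")
  validate_lda_data(df)
  df
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
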