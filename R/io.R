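#' FASTA, matrix and feature-table input/output
#'
#' @name io
NULL

#' Read protein records from a FASTA file
#'
#' The first whitespace-separated token of each header is the record id;
#' the remainder (if any) is the display label. Residues are upper-cased.
#'
#' @param path Path to a FASTA file with at least one entry.
#' @return List of [protein_record()]s in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA file '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file has no entries: ", path, call. = FALSE)
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(trimws(headers)))) {
    stop("malformed FASTA header (empty) in ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", trimws(headers))
  rest <- trimws(sub("^\\S+\\s*", "", trimws(headers)))
  labels <- ifelse(nzchar(rest), rest, ids)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  mapply(function(id, label, seq) protein_record(id, seq, label = label),
         ids, labels, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records List of [protein_record()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  seqs <- Biostrings::AAStringSet(vapply(records, function(r) r$residues,
                                         character(1)))
  names(seqs) <- vapply(records, function(r) {
    if (identical(r$id, r$label)) r$id else paste(r$id, r$label)
  }, character(1))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Write a labeled distance matrix as TSV
#'
#' Tab-separated square matrix with a header row and a leading label
#' column.
#'
#' @param D Labeled square matrix.
#' @param path Output path.
#' @param digits Decimal places for display; `NA` keeps full precision.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, digits = NA) {
  out <- if (is.na(digits)) D else round(D, digits)
  df <- data.frame(label = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled distance matrix from TSV
#'
#' Accepts the format written by [write_distance_matrix()]: header row of
#' labels, first column of labels.
#'
#' @param path Path to the TSV file.
#' @return Labeled square numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  labels <- as.character(df[[1L]])
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (nrow(M) != ncol(M)) {
    stop("matrix file is not square: ", nrow(M), " x ", ncol(M), call. = FALSE)
  }
  storage.mode(M) <- "double"
  rownames(M) <- labels
  colnames(M) <- colnames(df)[-1L]
  M
}

#' Write feature vectors as TSV (one row per protein, label first)
#'
#' @param features Named list of numeric vectors, or matrix with row
#'   labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  if (!is.matrix(features)) {
    features <- do.call(rbind, lapply(features, as.numeric)) |>
      `rownames<-`(names(features))
  }
  df <- data.frame(label = rownames(features), features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("label", paste0("f", seq_len(ncol(features))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
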