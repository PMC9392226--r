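#' Protein records and property encoding
#'
#' A protein record holds an accession id, a display label and the
#' residue string. Encoding replaces each residue letter by its value
#' under the active property scale, turning the sequence into a numeric
#' curve of the same length.
#'
#' @name encoding
NULL

#' Construct a protein record
#'
#' @param id Accession string (first token of a FASTA header).
#' @param residues Amino-acid sequence; upper-cased on construction.
#' @param label Display/species name; defaults to the id.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, residues, label = id) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L,
            is.character(label), length(label) == 1L)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues)) stop("empty sequence for record '", id, "'", call. = FALSE)
  structure(list(id = id, label = label, residues = residues),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat("<protein_record>", x$id, if (!identical(x$id, x$label)) paste0("(", x$label, ")"),
      "-", nchar(x$residues), "aa\n")
  invisible(x)
}

#' Encode a protein sequence as a numeric property curve
#'
#' Position i of the result is the property value of residue i, so the
#' curve has exactly one point per residue. Letters outside the standard
#' 20-letter alphabet (B, J, O, U, X, Z, gaps, ...) are a hard error by
#' default; with `nonstandard = "mean"` they are replaced by the mean of
#' the 20 scale values instead.
#'
#' @param x A [protein_record()] or a plain residue string.
#' @param scale A [property_scale()] or a scale name/file accepted by
#'   [load_property_scale()]. Default `"pka_cooh"`.
#' @param nonstandard Policy for letters missing from the scale:
#'   `"error"` (default) or `"mean"`.
#' @return An `encoded_seq`: numeric vector of property values with
#'   `label` attribute.
#' @examples
#' encode_sequence("ACD")  # 2.34 1.71 2.09
#' @export
encode_sequence <- function(x, scale = "pka_cooh",
                            nonstandard = c("error", "mean")) {
  nonstandard <- match.arg(nonstandard)
  if (!inherits(scale, "property_scale")) scale <- load_property_scale(scale)
  if (inherits(x, "protein_record")) {
    residues <- x$residues
    label <- x$label
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    residues <- toupper(gsub("[[:space:]]", "", x))
    label <- NA_character_
  }
  if (!nzchar(residues)) stop("empty sequence", call. = FALSE)
  letters_vec <- strsplit(residues, "")[[1L]]
  values <- unname(scale[letters_vec])
  if (anyNA(values)) {
    bad <- which(is.na(values))
    if (nonstandard == "error") {
      stop("non-standard letter(s) ",
           paste0("'", letters_vec[bad], "'", collapse = ", "),
           " at position(s) ", paste(bad, collapse = ", "), call. = FALSE)
    }
    values[bad] <- mean(as.numeric(scale))
  }
  encoded_seq(values, label = label)
}

#' @rdname encode_sequence
#' @param values Numeric vector of property values.
#' @param label Sequence label.
#' @export
encoded_seq <- function(values, label = NA_character_) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("encoded sequence must be nonempty", call. = FALSE)
  if (any(!is.finite(values))) stop("encoded values must be finite", call. = FALSE)
  structure(values, label = label, class = "encoded_seq")
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat("<encoded_seq>", attr(x, "label"), "- length", length(x), "\n")
  print(as.numeric(x))
  invisible(x)
}

#' Encode a collection of protein records
#'
#' @param records List of [protein_record()]s.
#' @inheritParams encode_sequence
#' @return Named list of `encoded_seq` objects (names = labels).
#' @export
encode_records <- function(records, scale = "pka_cooh",
                           nonstandard = c("error", "mean")) {
  nonstandard <- match.arg(nonstandard)
  if (length(records) == 0L) stop("no records to encode", call. = FALSE)
  if (!inherits(scale, "property_scale")) scale <- load_property_scale(scale)
  out <- lapply(records, encode_sequence, scale = scale, nonstandard = nonstandard)
  names(out) <- vapply(records, function(r) r$label, character(1))
  out
}
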