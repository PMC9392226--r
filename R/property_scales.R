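#' Amino-acid property scales
#'
#' A property scale maps each of the 20 standard amino-acid letters to a
#' real physicochemical value. The built-in `"pka_cooh"` scale holds the
#' dissociation constant of the alpha-carboxyl group, pKa(COOH), which
#' reflects the ionization state of -COOH in solution and is closely tied
#' to the isoelectric point.
#'
#' @name property-scales
NULL

# Standard 20-letter amino-acid alphabet, alphabetical by one-letter code.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# pKa of the alpha-COOH group, in pKa units.
PKA_COOH <- c(
  A = 2.34, R = 2.17, N = 2.02, D = 2.09, C = 1.71,
  E = 2.19, Q = 2.17, G = 2.34, H = 1.82, I = 2.36,
  L = 2.36, K = 2.18, M = 2.28, F = 1.83, P = 1.99,
  S = 2.21, T = 2.63, W = 2.38, Y = 2.20, V = 2.32
)

.scale_registry <- new.env(parent = emptyenv())

#' Construct a property scale
#'
#' @param values Named numeric vector: one finite value per standard
#'   amino-acid letter (exactly the 20 letters ACDEFGHIKLMNPQRSTVWY).
#' @param name Identifier for the scale.
#' @return An object of class `property_scale`: a named numeric vector in
#'   alphabetical letter order with a `name` attribute.
#' @export
property_scale <- function(values, name = "custom") {
  if (is.null(names(values)) || any(names(values) == "")) {
    stop("property scale values must be named by amino-acid letter", call. = FALSE)
  }
  names(values) <- toupper(names(values))
  if (anyDuplicated(names(values))) {
    stop("duplicate amino-acid letters in property scale: ",
         paste(unique(names(values)[duplicated(names(values))]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(AA_ALPHABET, names(values))
  extra <- setdiff(names(values), AA_ALPHABET)
  if (length(missing) > 0L) {
    stop("property scale is missing letters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra) > 0L) {
    stop("property scale has non-standard letters: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  values <- as.numeric(values[AA_ALPHABET])
  names(values) <- AA_ALPHABET
  if (any(!is.finite(values))) {
    stop("property scale values must all be finite numbers", call. = FALSE)
  }
  structure(values, name = name, class = "property_scale")
}

#' @export
print.property_scale <- function(x, ...) {
  cat("<property_scale>", attr(x, "name"), "\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Load a registered or file-based property scale
#'
#' Built-in scales are addressed by name (`"pka_cooh"`). Any other source
#' is read as a two-column delimited text file (letter, value), header
#' optional; this is how user-supplied scales such as hydrophobicity,
#' basicity or relative molecular mass are plugged in.
#'
#' @param source Built-in scale name or path to a scale file.
#' @return A [property_scale()].
#' @examples
#' sc <- load_property_scale("pka_cooh")
#' sc[["A"]]  # 2.34
#' @export
load_property_scale <- function(source) {
  if (!is.character(source) || length(source) != 1L) {
    stop("scale source must be a single name or file path", call. = FALSE)
  }
  if (exists(source, envir = .scale_registry, inherits = FALSE)) {
    return(get(source, envir = .scale_registry, inherits = FALSE))
  }
  if (file.exists(source)) {
    return(read_property_scale(source))
  }
  stop("unknown scale '", source, "' (not a registered name or existing file)",
       call. = FALSE)
}

#' List built-in property scales
#' @return Character vector of registered scale names.
#' @export
list_property_scales <- function() sort(ls(envir = .scale_registry))

#' Read a property scale from a delimited file
#'
#' Expects two columns (letter, value) separated by whitespace, tab or
#' comma; a header row is detected and skipped when its second field is
#' not numeric. Lines starting with `#` are ignored.
#'
#' @param path Path to the scale file.
#' @param name Scale identifier; defaults to the file base name.
#' @return A [property_scale()].
#' @export
read_property_scale <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("scale file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("scale file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "[,\t ]+")
  bad <- vapply(fields, length, integer(1)) < 2L
  if (any(bad)) {
    stop("malformed scale file line: '", lines[which(bad)[1L]], "'", call. = FALSE)
  }
  letters_col <- vapply(fields, `[[`, character(1), 1L)
  values_col <- vapply(fields, `[[`, character(1), 2L)
  num <- suppressWarnings(as.numeric(values_col))
  if (is.na(num[1L]) && length(num) > 1L) {  # header row
    letters_col <- letters_col[-1L]
    num <- num[-1L]
  }
  if (any(is.na(num))) {
    stop("non-numeric value in scale file for letter(s): ",
         paste(letters_col[is.na(num)], collapse = ", "), call. = FALSE)
  }
  property_scale(stats::setNames(num, letters_col), name = name)
}

#' Write a property scale to a tab-separated file
#' @param scale A [property_scale()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_property_scale <- function(scale, path) {
  stopifnot(inherits(scale, "property_scale"))
  utils::write.table(
    data.frame(letter = names(scale), value = as.numeric(scale)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

local({
  assign("pka_cooh", property_scale(PKA_COOH, name = "pka_cooh"),
         envir = .scale_registry)
})
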