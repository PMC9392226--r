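#' Spectral transform of encoded sequences
#'
#' Sequences in a set are truncated to the set's common (minimum) length
#' so every spectrum, and hence every downstream feature vector, has the
#' same dimension; the prefix is kept. The magnitude spectrum at level 1
#' is the element-wise modulus of the discrete Fourier transform
#' \deqn{F(k) = \sum_{n=0}^{N-1} p_n e^{-i 2\pi nk/N}, \quad k = 0,\dots,N-1,}
#' and level L >= 2 applies that operation L times in succession, taking
#' the modulus after each transform. The transform is length-preserving;
#' the DC component (k = 0) is retained and no windowing, zero-padding or
#' detrending is applied.
#'
#' @name spectral
NULL

#' Common length of a sequence set
#'
#' @param sequences Nonempty list of encoded sequences (or any vectors).
#' @return Minimum length over the collection.
#' @export
common_length <- function(sequences) {
  if (length(sequences) == 0L) stop("empty sequence collection", call. = FALSE)
  min(vapply(sequences, length, integer(1)))
}

#' Truncate an encoded sequence to its length-n prefix
#'
#' @param sequence An `encoded_seq` (or numeric vector).
#' @param n Target length, `1 <= n <= length(sequence)`.
#' @return The length-n prefix with the label preserved.
#' @export
truncate_encoded <- function(sequence, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1L || n != floor(n)) {
    stop("truncation length must be a positive integer", call. = FALSE)
  }
  if (n > length(sequence)) {
    stop("truncation length ", n, " exceeds sequence length ", length(sequence),
         call. = FALSE)
  }
  encoded_seq(as.numeric(sequence)[seq_len(n)], label = attr(sequence, "label"))
}

#' Magnitude FFT spectrum at a given level
#'
#' @param sequence An `encoded_seq` (or numeric vector), nonempty.
#' @param level Positive integer; number of iterated modulus transforms
#'   (default 2, the setting used throughout the benchmark analyses).
#' @return A `spectrum_seq`: nonnegative numeric vector of the input
#'   length, with `label` and `level` attributes.
#' @export
magnitude_spectrum <- function(sequence, level = 2L) {
  if (!is.numeric(level) || length(level) != 1L || level < 1L || level != floor(level)) {
    stop("level must be a positive integer", call. = FALSE)
  }
  x <- as.numeric(sequence)
  if (length(x) == 0L) stop("empty sequence", call. = FALSE)
  for (i in seq_len(level)) x <- Mod(stats::fft(x))
  structure(x, label = attr(sequence, "label"), level = as.integer(level),
            class = "spectrum_seq")
}

#' @export
print.spectrum_seq <- function(x, ...) {
  cat("<spectrum_seq>", attr(x, "label"), "- length", length(x),
      "- level", attr(x, "level"), "\n")
  print(as.numeric(x))
  invisible(x)
}

#' Truncate a set of encoded sequences to their common length
#'
#' @param sequences List of encoded sequences.
#' @return List of sequences all truncated to `common_length(sequences)`.
#' @export
truncate_to_common <- function(sequences) {
  n <- common_length(sequences)
  lapply(sequences, truncate_encoded, n = n)
}
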