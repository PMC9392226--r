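#' Sliding-window Higuchi fractal dimension
#'
#' The Higuchi estimator measures the fractal dimension of a 1-D signal
#' from how the mean "curve length" of stride-m subsampled versions of
#' the signal scales with the stride. For a window z(1..d), the stride-m
#' subsequence starting at n is z(n), z(n+m), ..., z(n + floor((d-n)/m)*m);
#' its normalized curve length is
#' \deqn{H_n(m) = \frac{d-1}{\lfloor (d-n)/m \rfloor \, m^2}
#'       \sum_{i=1}^{\lfloor (d-n)/m \rfloor} |z(n+im) - z(n+(i-1)m)|,}
#' the per-stride length H(m) averages H_n(m) over the valid start
#' offsets n = 1..m, and the fractal dimension is the least-squares slope
#' of log H(m) against log(1/m). A smooth ramp gives slope 1; white noise
#' approaches 2. Sliding a width-d window over a length-M signal yields
#' the feature vector of length M - d + 1.
#'
#' Numerical policy: start offsets with no increments
#' (floor((d-n)/m) = 0) are excluded from the H(m) average; strides with
#' H(m) = 0 in a non-constant window are dropped from the regression
#' (log 0 undefined); a window with no variation at all, or fewer than
#' two usable strides, returns `constant_value`.
#'
#' @name hfd
NULL

#' Stride-m subsequences of a signal
#'
#' @param signal Numeric vector of length M.
#' @param m Stride, `1 <= m <= M - 1`.
#' @return List of m numeric vectors; element n holds
#'   `signal[n], signal[n + m], ...`.
#' @examples
#' hfd_subsequences(1:6, 2)  # list(c(1,3,5), c(2,4,6))
#' @export
hfd_subsequences <- function(signal, m) {
  M <- length(signal)
  if (!is.numeric(m) || length(m) != 1L || m < 1L || m > M - 1L || m != floor(m)) {
    stop("stride m must be an integer in [1, M-1]", call. = FALSE)
  }
  lapply(seq_len(m), function(n) signal[seq(n, n + (M - n) %/% m * m, by = m)])
}

#' Normalized curve length of one stride-m subsequence
#'
#' @param window Numeric vector of length d.
#' @param n Start offset within the window.
#' @param m Stride.
#' @return The normalized curve length H_n(m); see the formula above.
#' @export
curve_length <- function(window, n, m) {
  d <- length(window)
  k <- (d - n) %/% m
  if (k < 1L) stop("no increments for n = ", n, ", m = ", m,
                   " in a window of width ", d, call. = FALSE)
  idx <- n + (0:k) * m
  sum(abs(diff(window[idx]))) * (d - 1) / (k * m^2)
}

#' Higuchi fractal dimension of a single window
#'
#' @param window Numeric vector of length d (>= 3).
#' @param m_max Maximum stride; default `floor(d / 2)` guarantees at
#'   least two increments for the n = 1 offset. Must allow at least two
#'   strides (`m_max >= 2`).
#' @param constant_value Value returned for a window with no variation
#'   (default 1.0: a flat signal is a smooth one-dimensional object).
#' @return The estimated fractal dimension (regression slope), or
#'   `constant_value` for degenerate windows.
#' @examples
#' window_hfd(0:5, m_max = 2)  # 1: linear ramp
#' @export
window_hfd <- function(window, m_max = max(2L, length(window) %/% 2L),
                       constant_value = 1.0) {
  d <- length(window)
  if (d < 3L) stop("window width must be at least 3", call. = FALSE)
  if (!is.numeric(m_max) || length(m_max) != 1L || m_max < 2L || m_max > d - 1L) {
    stop("m_max must be an integer in [2, d-1]", call. = FALSE)
  }
  if (all(window == window[1L])) return(constant_value)
  H <- vapply(seq_len(m_max), function(m) {
    valid_n <- which((d - seq_len(m)) %/% m >= 1L)
    if (length(valid_n) == 0L) return(NA_real_)
    mean(vapply(valid_n, function(n) curve_length(window, n, m), numeric(1)))
  }, numeric(1))
  usable <- which(!is.na(H) & H > 0)
  if (length(usable) < 2L) return(constant_value)
  x <- log(1 / usable)
  y <- log(H[usable])
  # OLS slope of y on x with intercept
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Sliding-window HFD feature vector
#'
#' Applies [window_hfd()] to every width-d window of the signal.
#'
#' @param spectrum A `spectrum_seq` or numeric vector of length M >= d.
#' @param window_width Window width d (default 9).
#' @param m_max Maximum stride passed to [window_hfd()]; default
#'   `floor(window_width / 2)`.
#' @param constant_value Fallback for zero-variation windows.
#' @return A `feature_vec`: numeric vector of length M - d + 1 with a
#'   `label` attribute.
#' @export
sliding_hfd <- function(spectrum, window_width = 9L,
                        m_max = max(2L, window_width %/% 2L),
                        constant_value = 1.0) {
  z <- as.numeric(spectrum)
  M <- length(z)
  d <- window_width
  if (!is.numeric(d) || length(d) != 1L || d < 3L || d != floor(d)) {
    stop("window width must be an integer >= 3", call. = FALSE)
  }
  if (M < d) stop("signal length ", M, " is shorter than window width ", d,
                  call. = FALSE)
  values <- vapply(seq_len(M - d + 1L), function(j) {
    window_hfd(z[j:(j + d - 1L)], m_max = m_max, constant_value = constant_value)
  }, numeric(1))
  structure(values, label = attr(spectrum, "label"), class = "feature_vec")
}

#' @export
print.feature_vec <- function(x, ...) {
  cat("<feature_vec>", attr(x, "label"), "- length", length(x), "\n")
  print(as.numeric(x))
  invisible(x)
}
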