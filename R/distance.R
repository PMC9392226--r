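#' Cosine distance matrix, single linkage and correlation reports
#'
#' Similarity between two feature vectors A and B is the cosine of the
#' angle between them, C = A.B / (||A|| ||B||), and the distance is
#' D = 1 - C, so identical directions give 0 and opposite directions 2.
#' The tree is built by single-linkage agglomeration (inter-cluster
#' distance = minimum pairwise member distance). Agreement with a
#' reference distance matrix is measured per species by the Pearson
#' correlation of matching matrix rows, classified against the two-sided
#' critical values of the correlation coefficient at 5% and 1%.
#'
#' @name distance-phylogeny
NULL

#' Cosine similarity of two vectors
#'
#' @param a,b Numeric vectors of equal length, both non-zero.
#' @return A.B / (||A|| ||B||), in [-1, 1].
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("vectors differ in length (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector",
                               call. = FALSE)
  s <- sum(a * b) / (na * nb)
  min(1, max(-1, s))
}

#' Pairwise cosine distance matrix of feature vectors
#'
#' @param features Named list of equal-length numeric vectors, or a
#'   matrix with one row per item (rownames = labels). At least 2 items.
#' @return Labeled symmetric matrix with `D[i,j] = 1 - cos(F_i, F_j)`
#'   and an exactly zero diagonal.
#' @export
cosine_distance_matrix <- function(features) {
  if (is.matrix(features)) {
    labels <- rownames(features)
    features <- lapply(seq_len(nrow(features)), function(i) features[i, ])
    names(features) <- labels
  }
  n <- length(features)
  if (n < 2L) stop("need at least 2 feature vectors", call. = FALSE)
  lens <- vapply(features, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop("feature vectors differ in length", call. = FALSE)
  }
  labels <- names(features)
  if (is.null(labels)) labels <- paste0("seq", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- 1 - cosine_similarity(features[[i]], features[[j]])
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Single-linkage tree from a distance matrix
#'
#' @param D Labeled symmetric distance matrix with zero diagonal.
#' @return An object of class `hclust` (merge order, non-decreasing
#'   merge heights, leaf labels).
#' @export
single_linkage <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("D must be a square matrix", call. = FALSE)
  }
  if (nrow(D) < 2L) stop("need at least 2 leaves", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-12) stop("D must be symmetric", call. = FALSE)
  stats::hclust(stats::as.dist(D), method = "single")
}

#' Pearson correlation coefficient of two rows
#'
#' @param a,b Numeric vectors of equal length >= 3, neither constant.
#' @return Pearson product-moment correlation in [-1, 1].
#' @export
pearson_cc <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("rows differ in length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant row", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Two-sided critical value of the Pearson correlation
#'
#' For sample size n the correlation coefficient under the null has
#' t = r sqrt((n-2)/(1-r^2)) ~ t(n-2); inverting at the two-sided alpha
#' quantile gives r_crit = sqrt(t^2 / (t^2 + n - 2)). For n = 8 this
#' yields 0.707 (5%) and 0.834 (1%); for n = 10, 0.632 and 0.765.
#'
#' @param n Sample size (>= 3).
#' @param alpha Two-sided significance level in (0, 1).
#' @return The critical value of |r| with n - 2 degrees of freedom.
#' @export
cc_critical_value <- function(n, alpha) {
  if (!is.numeric(n) || length(n) != 1L || n < 3L) {
    stop("n must be at least 3", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)", call. = FALSE)
  }
  t <- stats::qt(1 - alpha / 2, df = n - 2)
  sqrt(t^2 / (t^2 + n - 2))
}

#' Row-wise correlation agreement with a reference distance matrix
#'
#' For each label, correlates the full row of `ours` (diagonal included,
#' so n = number of species) with the matching row of `reference` and
#' classifies |c| against the 5% and 1% critical values:
#' `|c| <= c_0.05` is "none", `c_0.05 < |c| <= c_0.01` is "linear",
#' `|c| > c_0.01` is "strongly linear".
#'
#' @param ours,reference Labeled square distance matrices with identical
#'   labels in identical order.
#' @return A data frame with columns `label`, `cc`, `classification`,
#'   plus attributes `n`, `crit_0.05`, `crit_0.01`.
#' @export
correlation_report <- function(ours, reference) {
  if (!identical(dim(ours), dim(reference))) {
    stop("matrices differ in dimension", call. = FALSE)
  }
  if (!identical(rownames(ours), rownames(reference))) {
    stop("matrices must have identical labels in identical order", call. = FALSE)
  }
  n <- nrow(ours)
  c05 <- cc_critical_value(n, 0.05)
  c01 <- cc_critical_value(n, 0.01)
  cc <- vapply(seq_len(n), function(i) pearson_cc(ours[i, ], reference[i, ]),
               numeric(1))
  cls <- ifelse(abs(cc) > c01, "strongly linear",
                ifelse(abs(cc) > c05, "linear", "none"))
  structure(
    data.frame(label = rownames(ours), cc = cc, classification = cls,
               stringsAsFactors = FALSE, row.names = NULL),
    n = n, crit_0.05 = c05, crit_0.01 = c01
  )
}
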