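# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# O(N^2) direct evaluation of the DFT sum.
naive_dft <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k) {
    sum(x * exp(-2i * pi * (0:(N - 1)) * k / N))
  }, complex(1))
}

# Per-window loop for the sliding Higuchi estimator.
naive_sliding_hfd <- function(z, d, m_max, constant_value = 1.0) {
  out <- numeric(length(z) - d + 1)
  for (j in seq_along(out)) {
    out[j] <- window_hfd(z[j:(j + d - 1)], m_max = m_max,
                         constant_value = constant_value)
  }
  out
}

# Direct pairwise-loop cosine distance matrix.
naive_distance_matrix <- function(features) {
  n <- length(features)
  labels <- names(features)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- features[[i]]; b <- features[[j]]
      D[i, j] <- 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }
  }
  D
}

# Exhaustive O(n^3) single-linkage agglomerator: scans every pair of
# active clusters at every step. Returns merge heights and the partition
# (list of sorted member vectors) after each merge.
naive_single_linkage <- function(D) {
  labels <- rownames(D)
  clusters <- as.list(labels)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- min(D[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    heights <- c(heights, best)
    partitions <- c(partitions, list(canonical_partition(clusters)))
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, character(1), 1L))]
}

# Partition after each merge of an hclust object, same canonical form.
hclust_partitions <- function(hc) {
  n <- length(hc$labels)
  comp <- vector("list", nrow(hc$merge))
  members <- function(k) if (k < 0) hc$labels[-k] else comp[[k]]
  active <- as.list(-(seq_len(n)))
  out <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    m <- hc$merge[k, ]
    comp[[k]] <- c(members(m[1]), members(m[2]))
    active <- active[!(active %in% m)]
    active <- c(active, k)
    out[[k]] <- canonical_partition(lapply(active, members))
  }
  out
}

# Random symmetric distance matrix with zero diagonal.
random_distance_matrix <- function(n, labels = LETTERS[seq_len(n)]) {
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  D[upper.tri(D)] <- runif(n * (n - 1) / 2)
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  D
}

# Random residue string over the standard alphabet.
random_protein <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               len, replace = TRUE), collapse = "")
}

# True iff every clade maps to exactly one cluster when the tree is cut
# into n_clades groups (for single linkage this is equivalent to every
# clade merging fully before any cross-clade merge).
clades_recovered <- function(tree, clades) {
  ct <- stats::cutree(tree, k = length(unique(clades)))
  all(vapply(split(seq_along(ct), clades), function(g) {
    length(unique(ct[g])) == 1L
  }, logical(1)))
}
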