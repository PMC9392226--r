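test_that("cosine similarity matches closed-form cases and errors on bad input", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  expect_equal(cosine_similarity(c(1, 1), c(-1, -1)), -1.0)
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "length")
  expect_error(cosine_similarity(c(0, 0), c(1, 2)), "zero vector")
})

test_that("distance matrix is symmetric, zero-diagonal, bounded and matches the pairwise loop", {
  set.seed(5)
  for (i in 1:10) {
    feats <- setNames(lapply(1:5, function(j) rnorm(12)), paste0("s", 1:5))
    D <- cosine_distance_matrix(feats)
    expect_equal(D, t(D))
    expect_equal(unname(diag(D)), rep(0, 5))
    expect_true(all(D >= 0 & D <= 2))
    expect_equal(D, naive_distance_matrix(feats), tolerance = 1e-12)
    # positive rescaling of any one vector leaves D unchanged
    feats2 <- feats
    feats2[[3]] <- feats2[[3]] * 17.3
    expect_equal(cosine_distance_matrix(feats2), D, tolerance = 1e-12)
  }
})

test_that("identical feature vectors are at distance exactly zero", {
  feats <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 1, 2))
  D <- cosine_distance_matrix(feats)
  expect_identical(D["a", "b"], 0)
})

test_that("single linkage reproduces hand agglomeration and the naive oracle", {
  D <- matrix(c(0, .1, .5, .1, 0, .4, .5, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- single_linkage(D)
  expect_equal(hc$height, c(0.1, 0.4))
  expect_equal(canonical_partition(list(c("A", "B"), "C")),
               hclust_partitions(hc)[[1]])

  D2 <- matrix(c(0, .3, .3, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(single_linkage(D2)$height, 0.3)

  set.seed(77)
  for (trial in 1:100) {
    D <- random_distance_matrix(6)
    hc <- single_linkage(D)
    oracle <- naive_single_linkage(D)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-12)
    expect_identical(hclust_partitions(hc), oracle$partitions)
  }
})

test_that("single-linkage merge heights are non-decreasing and permutation-stable", {
  set.seed(88)
  for (trial in 1:20) {
    D <- random_distance_matrix(7, labels = paste0("sp", 1:7))
    hc <- single_linkage(D)
    expect_true(all(diff(hc$height) >= 0))
    perm <- sample(7)
    hc2 <- single_linkage(D[perm, perm])
    expect_equal(hc2$height, hc$height, tolerance = 1e-12)
    expect_identical(hclust_partitions(hc2)[[6]], hclust_partitions(hc)[[6]])
  }
})

test_that("Pearson correlation matches the direct covariance formula", {
  expect_equal(pearson_cc(c(1, 2, 5), c(1, 2, 5)), 1.0)
  expect_equal(pearson_cc(c(1, 2, 5), -c(1, 2, 5)), -1.0)
  set.seed(6)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    direct <- mean((a - mean(a)) * (b - mean(b))) /
      (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
    expect_equal(pearson_cc(a, b), direct, tolerance = 1e-12)
  }
  expect_error(pearson_cc(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_cc(1:2, 1:2), "at least 3")
})

test_that("correlation critical values reproduce the published thresholds", {
  expect_equal(round(cc_critical_value(8, 0.05), 3), 0.707)
  expect_equal(round(cc_critical_value(8, 0.01), 3), 0.834)
  expect_equal(round(cc_critical_value(10, 0.05), 3), 0.632)
  expect_equal(round(cc_critical_value(10, 0.01), 3), 0.765)
  expect_error(cc_critical_value(2, 0.05), "at least 3")
  expect_error(cc_critical_value(8, 1.5), "alpha")
})

test_that("correlation report classifies rows against the critical values", {
  set.seed(9)
  D <- random_distance_matrix(8, labels = paste0("sp", 1:8))
  rep_self <- correlation_report(D, D)
  expect_equal(rep_self$cc, rep(1, 8))
  expect_true(all(rep_self$classification == "strongly linear"))
  expect_equal(attr(rep_self, "n"), 8L)

  # synthetic rows with known correlation against a fixed reference
  base <- c(0, 0.2, 0.5, 0.9, 1.1, 1.4, 1.8, 2.0)
  make_rows <- function(cc_target) {
    set.seed(4)
    noise <- resid(lm(rnorm(8) ~ base))
    noise <- noise / sd(noise)
    z <- cc_target * scale(base)[, 1] + sqrt(1 - cc_target^2) * noise
    z
  }
  for (target in c(0.75, 0.90)) {
    r <- pearson_cc(make_rows(target), base)
    expect_equal(r, target, tolerance = 1e-9)
  }
  cls <- function(c, n) {
    if (abs(c) > cc_critical_value(n, 0.01)) "strongly linear"
    else if (abs(c) > cc_critical_value(n, 0.05)) "linear" else "none"
  }
  expect_equal(cls(0.75, 8), "linear")
  expect_equal(cls(0.90, 8), "strongly linear")
  expect_equal(cls(0.5, 8), "none")

  D2 <- D; rownames(D2) <- colnames(D2) <- paste0("x", 1:8)
  expect_error(correlation_report(D, D2), "identical labels")
})
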