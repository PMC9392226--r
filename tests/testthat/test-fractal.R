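test_that("stride-m subsequences enumerate start offsets correctly", {
  z <- 1:6
  expect_equal(hfd_subsequences(z, 2), list(c(1, 3, 5), c(2, 4, 6)))
  expect_equal(hfd_subsequences(z, 3), list(c(1, 4), c(2, 5), c(3, 6)))
  expect_equal(hfd_subsequences(1:5, 1), list(1:5))
  expect_error(hfd_subsequences(z, 6), "stride")
  expect_error(hfd_subsequences(z, 0), "stride")
})

test_that("normalized curve length matches hand-evaluated ramps and constants", {
  ramp <- c(0, 1, 2, 3, 4, 5)
  expect_equal(curve_length(ramp, n = 1, m = 1), 5.0)
  expect_equal(curve_length(ramp, n = 1, m = 2), 2.5)
  expect_equal(curve_length(rep(3, 9), n = 2, m = 3), 0.0)
  expect_error(curve_length(ramp, n = 5, m = 2), "no increments")
})

test_that("window HFD is 1 for ramps and the fallback for constants", {
  expect_equal(window_hfd(c(0, 1, 2, 3, 4, 5), m_max = 2), 1.0, tolerance = 1e-9)
  # ramps of any slope/offset/width
  for (d in c(6, 9, 15)) {
    expect_equal(window_hfd(7 - 0.3 * seq_len(d)), 1.0, tolerance = 1e-9)
  }
  expect_equal(window_hfd(rep(3, 9)), 1.0)
  expect_equal(window_hfd(rep(3, 9), constant_value = -1), -1)
  expect_error(window_hfd(1:9, m_max = 1), "m_max")
  expect_error(window_hfd(1:9, m_max = 9), "m_max")
})

test_that("window HFD is invariant to positive scaling and offsets", {
  set.seed(11)
  for (i in 1:25) {
    w <- rnorm(9)
    f <- window_hfd(w)
    expect_equal(window_hfd(2.7 * w), f, tolerance = 1e-9)
    expect_equal(window_hfd(w + 13.5), f, tolerance = 1e-9)
    expect_equal(window_hfd(0.004 * w - 2), f, tolerance = 1e-9)
    expect_true(is.finite(f))
  }
})

test_that("white-noise windows have mean HFD near 2", {
  set.seed(99)
  vals <- vapply(seq_len(10000), function(i) window_hfd(rnorm(9), m_max = 4),
                 numeric(1))
  expect_gte(mean(vals), 1.7)
  expect_lte(mean(vals), 2.1)
})

test_that("sliding HFD equals the per-window loop and has length M - d + 1", {
  set.seed(33)
  for (i in 1:10) {
    M <- sample(9:80, 1)
    z <- rnorm(M)
    fv <- sliding_hfd(z, window_width = 9, m_max = 4)
    expect_length(fv, M - 9 + 1)
    expect_equal(as.numeric(fv), naive_sliding_hfd(z, 9, 4))
  }
  # single window when M = d
  expect_length(sliding_hfd(rnorm(9), window_width = 9), 1L)
  expect_error(sliding_hfd(rnorm(5), window_width = 9), "shorter")
})

test_that("zero-variation stretches in a spectrum fall back to the constant value", {
  z <- c(rep(0, 12), rnorm(12))
  fv <- sliding_hfd(z, window_width = 9, constant_value = 1.0)
  expect_equal(as.numeric(fv)[1:4], rep(1.0, 4))
  expect_true(all(is.finite(fv)))
})
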