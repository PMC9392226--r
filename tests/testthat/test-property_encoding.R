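test_that("built-in pKa(COOH) scale is complete and matches the published values", {
  sc <- load_property_scale("pka_cooh")
  expect_s3_class(sc, "property_scale")
  expect_length(sc, 20L)
  expect_setequal(names(sc), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  expect_true(all(is.finite(sc)))
  expect_equal(sc[["A"]], 2.34)
  expect_equal(sc[["T"]], 2.63)
  expect_equal(sc[["C"]], 1.71)
  expect_equal(sc[["Y"]], 2.20)
  expect_equal(sc[["W"]], 2.38)
})

test_that("unknown and malformed scale sources are rejected", {
  expect_error(load_property_scale("no_such_scale"), "unknown scale")
  expect_error(property_scale(c(A = 1)), "missing letters")
  expect_error(property_scale(setNames(rep(1, 21), c(names(ffp:::PKA_COOH), "X"))),
               "non-standard")
  expect_error(property_scale(c(ffp:::PKA_COOH[-1], A = NaN)), "finite")
})

test_that("scale files round-trip and bad files error", {
  sc <- load_property_scale("pka_cooh")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_property_scale(sc, path)
  back <- read_property_scale(path)
  expect_equal(as.numeric(back), as.numeric(sc))
  expect_equal(names(back), names(sc))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A 1.0", "a 2.0"), dup)
  expect_error(read_property_scale(dup), "duplicate")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A one"), bad)
  expect_error(read_property_scale(bad), "non-numeric")
})

test_that("encoding is position-wise, length-preserving and case-insensitive", {
  expect_equal(as.numeric(encode_sequence("ACD")), c(2.34, 1.71, 2.09))
  expect_equal(as.numeric(encode_sequence("acd")), c(2.34, 1.71, 2.09))
  # concatenation property on random sequences
  set.seed(42)
  for (i in 1:10) {
    x <- random_protein(sample(5:40, 1))
    y <- random_protein(sample(5:40, 1))
    expect_equal(as.numeric(encode_sequence(paste0(x, y))),
                 c(as.numeric(encode_sequence(x)), as.numeric(encode_sequence(y))))
  }
  # determinism, bit for bit
  expect_identical(as.numeric(encode_sequence("WTFESR")),
                   as.numeric(encode_sequence("WTFESR")))
})

test_that("empty sequences and non-standard letters follow the configured policy", {
  expect_error(encode_sequence(""), "empty")
  expect_error(protein_record("x", ""), "empty")
  expect_error(encode_sequence("ACXD"), "position\\(s\\) 3")
  expect_error(encode_sequence("BACD"), "'B'")
  mean_val <- mean(as.numeric(load_property_scale("pka_cooh")))
  expect_equal(as.numeric(encode_sequence("AXA", nonstandard = "mean"))[2], mean_val)
})

test_that("worked-example fragments encode to 30-point curves differing at 4 known positions", {
  ex <- example_proteins()
  p1 <- encode_sequence(ex$P1)
  p2 <- encode_sequence(ex$P2)
  expect_length(p1, 30L)
  expect_length(p2, 30L)
  expect_equal(as.numeric(p1)[1:3], c(2.38, 2.63, 1.83))  # W, T, F
  diff_letters <- which(strsplit(ex$P1$residues, "")[[1]] !=
                          strsplit(ex$P2$residues, "")[[1]])
  expect_equal(diff_letters, c(2L, 11L, 14L, 27L))
  expect_equal(which(as.numeric(p1) != as.numeric(p2)), diff_letters)
})
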