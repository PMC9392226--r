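#' End-to-end pipeline configuration
#'
#' The defaults (property scale pKa(COOH), FFT level 2, sliding-window
#' width 9, m_max 4, cosine distance, 4 display decimals) reproduce the
#' settings used for the benchmark analyses.
#'
#' @param property_scale Built-in scale name, scale file path, or a
#'   [property_scale()] object.
#' @param fft_level Iterated magnitude-FFT level (positive integer).
#' @param window_width HFD sliding-window width d.
#' @param m_max Maximum Higuchi stride.
#' @param rounding Display decimals for written matrices.
#' @param nonstandard Policy for non-standard residue letters.
#' @param constant_value HFD value for zero-variation windows.
#' @return A `ffp_config` list.
#' @export
ffp_config <- function(property_scale = "pka_cooh", fft_level = 2L,
                       window_width = 9L, m_max = 4L, rounding = 4L,
                       nonstandard = c("error", "mean"),
                       constant_value = 1.0) {
  nonstandard <- match.arg(nonstandard)
  stopifnot(fft_level >= 1L, window_width >= 3L,
            m_max >= 2L, m_max <= window_width - 1L)
  structure(list(property_scale = property_scale,
                 fft_level = as.integer(fft_level),
                 window_width = as.integer(window_width),
                 m_max = as.integer(m_max),
                 distance = "cosine",
                 rounding = as.integer(rounding),
                 nonstandard = nonstandard,
                 constant_value = constant_value),
            class = "ffp_config")
}

#' Run the full alignment-free pipeline
#'
#' Encode each record under the property scale, truncate all curves to
#' the set's common (minimum) length, take the iterated magnitude FFT,
#' slide the Higuchi fractal-dimension window over each spectrum, build
#' the pairwise cosine distance matrix and the single-linkage tree.
#' With a common length N and window width d, every feature vector has
#' length N - d + 1.
#'
#' @param records List of at least 2 [protein_record()]s (or a FASTA
#'   path).
#' @param config A [ffp_config()].
#' @return A `ffp_result` list: `features` (matrix, one labeled row per
#'   protein), `distance` (labeled matrix), `tree` (`hclust`),
#'   `common_length`, `labels` and `config`.
#' @examples
#' recs <- example_proteins()
#' res <- ffp_pipeline(recs)
#' res$distance
#' @export
ffp_pipeline <- function(records, config = ffp_config()) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_fasta(records)
  }
  if (length(records) < 2L) stop("need at least 2 records", call. = FALSE)
  labels <- vapply(records, function(r) r$label, character(1))
  if (anyDuplicated(labels)) {
    stop("duplicate record labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  encoded <- encode_records(records, scale = config$property_scale,
                            nonstandard = config$nonstandard)
  n_common <- common_length(encoded)
  if (n_common < config$window_width) {
    stop("common length ", n_common, " is shorter than the window width ",
         config$window_width, call. = FALSE)
  }
  truncated <- lapply(encoded, truncate_encoded, n = n_common)
  spectra <- lapply(truncated, magnitude_spectrum, level = config$fft_level)
  feats <- lapply(spectra, sliding_hfd,
                  window_width = config$window_width,
                  m_max = config$m_max,
                  constant_value = config$constant_value)
  fmat <- do.call(rbind, lapply(feats, as.numeric))
  rownames(fmat) <- labels
  D <- cosine_distance_matrix(feats)
  tree <- single_linkage(D)
  structure(list(features = fmat, distance = D, tree = tree,
                 common_length = n_common, labels = labels, config = config),
            class = "ffp_result")
}

#' @export
print.ffp_result <- function(x, ...) {
  cat("<ffp_result>", length(x$labels), "proteins, common length",
      x$common_length, "->", ncol(x$features), "features each\n")
  cat("distance matrix (rounded to", x$config$rounding, "decimals):\n")
  print(round(x$distance, x$config$rounding))
  invisible(x)
}

#' Write pipeline outputs to files
#'
#' @param result A `ffp_result` from [ffp_pipeline()].
#' @param matrix_path,tree_path,features_path,log_path Output paths;
#'   `NULL` skips that file.
#' @return Named character vector of the files written, invisibly.
#' @export
write_ffp_result <- function(result, matrix_path = NULL, tree_path = NULL,
                             features_path = NULL, log_path = NULL) {
  written <- character(0)
  if (!is.null(matrix_path)) {
    write_distance_matrix(result$distance, matrix_path,
                          digits = result$config$rounding)
    written["matrix"] <- matrix_path
  }
  if (!is.null(tree_path)) {
    write_newick(result$tree, tree_path)
    written["tree"] <- tree_path
  }
  if (!is.null(features_path)) {
    write_features(result$features, features_path)
    written["features"] <- features_path
  }
  if (!is.null(log_path)) {
    cfg <- result$config
    scale_id <- if (inherits(cfg$property_scale, "property_scale")) {
      attr(cfg$property_scale, "name")
    } else as.character(cfg$property_scale)
    writeLines(c(
      paste0("ffp version: ", as.character(utils::packageVersion("ffp"))),
      paste0("R version: ", R.version.string),
      paste0("n_proteins: ", length(result$labels)),
      paste0("common_length: ", result$common_length),
      paste0("n_features: ", ncol(result$features)),
      paste0("property_scale: ", scale_id),
      paste0("fft_level: ", cfg$fft_level),
      paste0("window_width: ", cfg$window_width),
      paste0("m_max: ", cfg$m_max),
      paste0("distance: ", cfg$distance),
      paste0("rounding: ", cfg$rounding),
      paste0("nonstandard: ", cfg$nonstandard)
    ), log_path)
    written["log"] <- log_path
  }
  invisible(written)
}
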