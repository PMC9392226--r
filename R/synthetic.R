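#' Synthetic protein families with known clade structure
#'
#' Generates sequence families by point substitution from a random
#' ancestor: one ancestor per clade is derived from a shared root by
#' `between` substitutions, and each member by `within` substitutions
#' from its clade ancestor. Positions and replacement letters are drawn
#' uniformly over the 20-letter alphabet; a replacement always differs
#' from the current letter, so mutation counts are exact Hamming
#' distances from the respective ancestor. With `between > within` the
#' clades are separable and serve as ground truth for clade-recovery
#' experiments. No indels and no substitution-rate matrix: the generator
#' probes distance-based clustering, not realistic molecular evolution.
#'
#' @param n_clades Number of clades.
#' @param seqs_per_clade Sequences per clade.
#' @param length Residue count of every sequence.
#' @param within Substitutions per member relative to its clade ancestor.
#' @param between Substitutions per clade ancestor relative to the root;
#'   must exceed `within`.
#' @param seed Integer seed; the output is a pure function of the
#'   arguments.
#' @return List with `records` (list of [protein_record()]s, labels
#'   `cladeX_seqY`) and `clades` (integer vector of true clade ids,
#'   named by label).
#' @examples
#' fam <- synthetic_family(3, 3, length = 150, within = 2, between = 30,
#'                         seed = 7)
#' table(fam$clades)
#' @export
synthetic_family <- function(n_clades, seqs_per_clade, length = 150L,
                             within = 2L, between = 30L, seed = 1L) {
  stopifnot(n_clades >= 1L, seqs_per_clade >= 1L, length >= 1L,
            within >= 0L, between >= 0L)
  if (between <= within) {
    stop("between-clade mutations must exceed within-clade mutations",
         call. = FALSE)
  }
  if (between > length || within > length) {
    stop("sequence length ", length, " too small for the requested ",
         "mutation counts", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  mutate <- function(seq_chars, k) {
    if (k == 0L) return(seq_chars)
    pos <- sample.int(length(seq_chars), k)
    for (p in pos) {
      seq_chars[p] <- sample(setdiff(AA_ALPHABET, seq_chars[p]), 1L)
    }
    seq_chars
  }

  root <- sample(AA_ALPHABET, length, replace = TRUE)
  records <- list()
  clades <- integer(0)
  for (cl in seq_len(n_clades)) {
    ancestor <- mutate(root, between)
    for (s in seq_len(seqs_per_clade)) {
      member <- mutate(ancestor, within)
      lab <- sprintf("clade%d_seq%d", cl, s)
      records[[lab]] <- protein_record(lab, paste(member, collapse = ""))
      clades[lab] <- cl
    }
  }
  list(records = unname(records), clades = clades)
}

#' Write a synthetic family as FASTA plus a clade-truth TSV
#'
#' @param family Output of [synthetic_family()].
#' @param fasta_path FASTA output path.
#' @param truth_path Optional TSV path (columns `label`, `clade`).
#' @return `fasta_path`, invisibly.
#' @export
write_synthetic_family <- function(family, fasta_path, truth_path = NULL) {
  write_fasta(family$records, fasta_path)
  if (!is.null(truth_path)) {
    utils::write.table(
      data.frame(label = names(family$clades), clade = unname(family$clades)),
      truth_path, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(fasta_path)
}
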