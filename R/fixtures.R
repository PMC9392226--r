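#' Bundled example sequences and benchmark dataset metadata
#'
#' Two 30-residue Saccharomyces cerevisiae protein fragments (P1, P2)
#' that differ at exactly four positions serve as a worked example for
#' the encoding and pipeline. Four benchmark datasets commonly used for
#' alignment-free protein comparison are described by their NCBI
#' accession metadata (species label, accession id, sequence length):
#' one set of 8 mitochondrial ND6 sequences and three beta-globin sets
#' of 10, 11 and 17 species. Sequences themselves are not bundled; users
#' fetch them from NCBI by accession and supply a FASTA file.
#'
#' @name fixtures
NULL

P1_SEQ <- "WTFESRNDPAKDPVILWLNGGPGCSSLTGL"
P2_SEQ <- "WFFESRNDPAMDPIILWLNGGPGCSSFTGL"

.benchmark_sets <- list(
  ND6Set = data.frame(
    label = c("Human", "Gorilla", "C.Chimp", "Wallaroo",
              "H.Seal", "G.Seal", "Rat", "Mouse"),
    accession = c("YP_003024037", "NP_008223", "NP_008197", "NP_007405",
                  "NP_006939", "NP_007080", "AP_004903", "NP_904339"),
    length = c(174L, 174L, 174L, 167L, 175L, 175L, 172L, 172L),
    stringsAsFactors = FALSE
  ),
  `10-BetaSet` = data.frame(
    label = c("Human", "Gorilla", "Gibbon", "G.Panda", "Goose",
              "Swan", "Goat", "Sheep", "Bovine", "Bison"),
    accession = c("AAA16334", "P02024", "P02025", "P18983", "P02117",
                  "P68945", "AAA30913", "NP_001091117", "CAA25111", "P09422"),
    length = c(147L, 147L, 146L, 147L, 146L, 146L, 145L, 145L, 145L, 145L),
    stringsAsFactors = FALSE
  ),
  `11-BetaSet` = data.frame(
    label = c("Human", "Lemur", "Mouse", "Goat", "Rabbit", "C.Chimp",
              "Gorilla", "Rat", "Bovine", "Opossum", "Gallus"),
    accession = c("AAA16334", "AAA36822", "ADD52696", "AAA30913", "CAA24251",
                  "P68873", "P02024", "CAA33250", "CAA25111", "AAA30976",
                  "CAA23700"),
    length = c(147L, 147L, 147L, 145L, 147L, 147L, 147L, 147L, 145L,
               147L, 147L),
    stringsAsFactors = FALSE
  ),
  `17-BetaSet` = data.frame(
    label = c("Human", "Gorilla", "Chimp", "Cattle", "Banteng", "Goat",
              "Sheep", "E.Hare", "Rabbit", "H.Mouse", "W.Mouse", "S.Mouse",
              "N.Rat", "Opossum", "Guttata", "Gallus", "M.Duck"),
    accession = c("ALU64020", "P02024", "P68873", "CAA25111", "BAJ05126",
                  "AAA30913", "ABC86525", "CAA68429", "CAA24251", "ADD52660",
                  "ACY03394", "ACY03377", "CAA29887", "AAA30976", "CH46399",
                  "CAA23700", "CAA33756"),
    length = c(147L, 147L, 147L, 145L, 145L, 145L, 145L, 147L, 147L,
               147L, 147L, 147L, 147L, 147L, 147L, 147L, 147L),
    stringsAsFactors = FALSE
  )
)

#' Bundled worked-example protein fragments
#'
#' @return List of two [protein_record()]s named `P1` and `P2`, 30
#'   residues each, differing at positions 2, 11, 14 and 27.
#' @export
example_proteins <- function() {
  list(P1 = protein_record("P1", P1_SEQ, label = "P1"),
       P2 = protein_record("P2", P2_SEQ, label = "P2"))
}

#' Benchmark dataset accession metadata
#'
#' @param set Optional set name: one of `"ND6Set"`, `"10-BetaSet"`,
#'   `"11-BetaSet"`, `"17-BetaSet"`. Omit for all four.
#' @return A data frame with columns `label`, `accession`, `length`, or
#'   a named list of such data frames.
#' @export
benchmark_sets <- function(set = NULL) {
  if (is.null(set)) return(.benchmark_sets)
  if (!set %in% names(.benchmark_sets)) {
    stop("unknown benchmark set '", set, "'; available: ",
         paste(names(.benchmark_sets), collapse = ", "), call. = FALSE)
  }
  .benchmark_sets[[set]]
}

#' All bundled fixtures in one list
#'
#' @return List with elements `P1`, `P2` ([protein_record()]s), `scale`
#'   (the built-in pKa(COOH) [property_scale()]) and `sets` (the four
#'   benchmark metadata tables).
#' @export
ffp_fixtures <- function() {
  ex <- example_proteins()
  list(P1 = ex$P1, P2 = ex$P2,
       scale = load_property_scale("pka_cooh"),
       sets = benchmark_sets())
}
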