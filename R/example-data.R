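#' Worked example cohort of ten female FMR1 genotypes
#'
#' Ten two-allele female genotypes with fully resolved repeat structures,
#' spanning normal through premutation alleles, the common
#' (CGG)9/(CGG)10 + AGG building-block patterns, several rarer AGG
#' layouts, a two-premutation carrier and one allele carrying a
#' non-canonical CTG interruption. Notation strings are kept in the
#' typeset form (underscored counts, bare interruption token) that the
#' tolerant parser accepts; [parse_structure_notation()] canonicalizes
#' them.
#'
#' @return A tibble with columns `female` (1-10), `allele`
#'   (`"smaller"`/`"larger"`), `repeat_length`, `n_agg` and `notation`.
#' @examples
#' co <- example_cohort()
#' parse_structure_notation(co$notation[co$female == 3 & co$allele == "larger"])
#' @export
example_cohort <- function() {
  tibble::tribble(
    ~female, ~allele, ~repeat_length, ~n_agg, ~notation,
    1L, "smaller", 22L, 1L, "(CGG)_9_(AGG)_1_(CGG)_12_",
    1L, "larger",  69L, 0L, "(CGG)_69_",
    2L, "smaller", 65L, 2L, "(CGG)_9_(AGG)_1_(CGG)_9_(AGG)_1_(CGG)_45_",
    2L, "larger",  73L, 2L, "(CGG)_9_(AGG)_1_(CGG)_7_(AGG)_1_(CGG)_55_",
    3L, "smaller", 33L, 2L, "(CGG)_9_(AGG)_1_(CGG)_9_(AGG)_1_(CGG)_13_",
    3L, "larger",  69L, 2L, "(CGG)_9_(AGG)_1_(CGG)_9_(AGG)_1_(CGG)_49_",
    4L, "smaller", 30L, 2L, "(CGG)_10_(AGG)_1_(CGG)_9_(AGG)_1_(CGG)_9_",
    4L, "larger",  89L, 2L, "(CGG)_9_(AGG)_1_(CGG)_9_(AGG)_1_(CGG)_69_",
    5L, "smaller", 44L, 1L, "(CGG)_9_(AGG)_1_(CGG)_34_",
    5L, "larger",  66L, 2L, "(CGG)_9_(AGG)_1_(CGG)_9_(AGG)_1_(CGG)_46_",
    6L, "smaller", 32L, 2L, "(CGG)_9_(AGG)_1_(CGG)_12_(AGG)_1_(CGG)_9_",
    6L, "larger",  45L, 2L, "(CGG)_9_(AGG)_1_(CGG)_9_(AGG)_1_(CGG)_25_",
    7L, "smaller", 34L, 2L, "(CGG)_9_(AGG)_1_(CGG)_14_(AGG)_1_(CGG)_9_",
    7L, "larger",  49L, 1L, "(CGG)_9_(AGG)_1_(CGG)_39_",
    8L, "smaller", 30L, 2L, "(CGG)_10_(AGG)_1_(CGG)_9_(AGG)_1_(CGG)_9_",
    8L, "larger",  49L, 3L, "(CGG)_10_(AGG)_1_(CGG)_9_(AGG)_1_(CGG)_18_(AGG)_1_(CGG)_9_",
    9L, "smaller", 30L, 1L, "(CGG)_20_(AGG)_1_(CGG)_9_",
    9L, "larger",  69L, 2L, "(CGG)_9_(AGG)_1_(CGG)_7_(AGG)_1_(CGG)_51_",
    10L, "smaller", 40L, 3L, "(CGG)_10_(AGG)_1_(CGG)_9_(AGG)_1_(CGG)_9_(AGG)_1_(CGG)_9_",
    10L, "larger",  45L, 2L, "(CGG)_7_CTG(CGG)_1_(AGG)_1_(CGG)_9_(AGG)_1_(CGG)_25_"
  )
}

#' Default placeholder flank anchors
#'
#' The amplicon flanks of a real assay depend on the primer design and are
#' supplied by the operator; these 24 nt placeholder anchors are synthetic
#' stand-ins used by the simulator and the examples. They satisfy the
#' anchor invariants (length >= 12, no CGG-triplet run).
#'
#' @param max_anchor_mismatches Passed through to [anchor_config()].
#' @return An [anchor_config()].
#' @export
default_anchors <- function(max_anchor_mismatches = 2L) {
  anchor_config(
    flank5 = "TCAGGCGCTCAGCTCCGTTTCGGT",
    flank3 = "CTGGGCCTCGAGCGCCCGCAGCCC",
    max_anchor_mismatches = max_anchor_mismatches
  )
}

#' Default sample barcodes
#'
#' Eight synthetic 16 nt barcodes, mutually (and against each other's
#' reverse complements) at least 8 mismatches apart, comfortably above the
#' manifest distance requirement at the default one-mismatch budget.
#'
#' @param n Number of barcodes to return (1-8).
#' @return Character vector of barcode sequences.
#' @export
default_barcodes <- function(n = 8L) {
  bcs <- c(
    "AAAACTCCATGTGTAA",
    "CTCCGGAAGTAGAATC",
    "CATATCTCGTGAACCC",
    "CCTGCACGCCCTAAAG",
    "TACAATTAGGATATTC",
    "ATCCCTACACTGTATA",
    "TGCCGAACGTTCTAAT",
    "AAACGACTTAGCAACA"
  )
  stopifnot(n >= 1L, n <= length(bcs))
  bcs[seq_len(n)]
}
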