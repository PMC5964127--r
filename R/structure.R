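#' Build a repeat structure from triplet blocks
#'
#' A repeat structure is the ordered 5'->3' sequence of triplet blocks that
#' makes up one allele's CGG tract, e.g. `(CGG)9(AGG)1(CGG)12` for a
#' 22-repeat allele with a single AGG interruption after nine CGGs.
#' Adjacent blocks with the same motif are merged so that blocks are always
#' maximal runs.
#'
#' @param blocks A data frame with columns `motif` (3-letter DNA string) and
#'   `count` (positive integer copies of the motif).
#' @return An object of class `repeat_structure`: a list with the block
#'   tibble plus derived fields `total_triplets`, `agg_count`,
#'   `agg_positions` (1-based triplet index of the first triplet of each AGG
#'   block, counted from the 5' end) and `noncanonical` (a tibble of
#'   motif/position for blocks that are neither CGG nor AGG).
#' @examples
#' s <- repeat_structure(data.frame(motif = c("CGG", "AGG", "CGG"),
#'                                  count = c(9, 1, 12)))
#' s$total_triplets  # 22
#' s$agg_positions   # 10
#' @export
repeat_structure <- function(blocks) {
  blocks <- tibble::as_tibble(blocks)
  if (!all(c("motif", "count") %in% names(blocks))) {
    rlang::abort("`blocks` must have columns `motif` and `count`")
  }
  if (nrow(blocks) == 0L) {
    rlang::abort("a repeat structure needs at least one block")
  }
  motif <- toupper(as.character(blocks$motif))
  count <- blocks$count
  if (any(nchar(motif) != 3L) || any(!grepl("^[ACGT]{3}$", motif))) {
    rlang::abort("every motif must be a 3-letter string over A/C/G/T")
  }
  if (any(is.na(count)) || any(count < 1) || any(count != as.integer(count))) {
    rlang::abort("every block count must be a positive integer")
  }
  count <- as.integer(count)

  # merge adjacent identical motifs so blocks are maximal runs
  grp <- cumsum(c(TRUE, motif[-1] != motif[-length(motif)]))
  motif <- motif[!duplicated(grp)]
  count <- as.integer(tapply(count, grp, sum))

  start <- cumsum(c(1L, count[-length(count)]))
  nc <- !motif %in% c("CGG", "AGG")
  structure(
    list(
      blocks = tibble::tibble(motif = motif, count = count),
      total_triplets = sum(count),
      agg_count = sum(count[motif == "AGG"]),
      agg_positions = start[motif == "AGG"],
      noncanonical = tibble::tibble(motif = motif[nc], position = start[nc])
    ),
    class = "repeat_structure"
  )
}

#' @export
print.repeat_structure <- function(x, ...) {
  cat("<repeat_structure> ", format_structure_notation(x), "\n", sep = "")
  cat("  total triplets: ", x$total_triplets,
      " | AGG count: ", x$agg_count, sep = "")
  if (length(x$agg_positions)) {
    cat(" at ", paste(x$agg_positions, collapse = ", "), sep = "")
  }
  cat("\n")
  if (nrow(x$noncanonical)) {
    cat("  non-canonical: ",
        paste0(x$noncanonical$motif, "@", x$noncanonical$position,
               collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
format.repeat_structure <- function(x, ...) format_structure_notation(x)

#' Parse block notation into a repeat structure
#'
#' Reads the standard block notation used for FMR1 repeat structures,
#' e.g. `"(CGG)9(AGG)1(CGG)12"`. The canonical grammar is
#' `STRUCTURE := BLOCK+ ; BLOCK := "(" MOTIF ")" COUNT` with
#' `MOTIF := [ACGT]{3}` and `COUNT := [1-9][0-9]*`, no internal whitespace.
#' Two tolerances accommodate typeset renderings of the same notation:
#' underscores around counts (`"(CGG)_9_"`) are accepted, and a bare motif
#' token without parentheses or count (e.g. the `CTG` in
#' `"(CGG)_7_CTG(CGG)_1_..."`) is read as a single copy of that motif.
#'
#' @param text A single notation string. Leading/trailing whitespace is
#'   trimmed; anything else must match the grammar.
#' @return A [repeat_structure()].
#' @examples
#' parse_structure_notation("(CGG)9(AGG)1(CGG)12")
#' parse_structure_notation("(CGG)_9_(AGG)_1_(CGG)_12_")  # typeset form
#' @export
parse_structure_notation <- function(text) {
  if (length(text) != 1L || is.na(text) || !is.character(text)) {
    rlang::abort("`text` must be a single notation string")
  }
  text <- trimws(text)
  if (!nzchar(text)) {
    rlang::abort("empty structure notation")
  }
  n <- nchar(text)
  pos <- 1L
  motifs <- character()
  counts <- integer()
  block_re <- "^\\(([ACGTacgt]{3})\\)_?(0|[1-9][0-9]*)_?"
  bare_re <- "^([ACGTacgt]{3})"
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexec(block_re, rest))[[1]]
    if (length(m)) {
      cnt <- suppressWarnings(as.integer(m[3]))
      if (is.na(cnt) || cnt < 1L) {
        # count starts right after "(MOT)" and an optional underscore
        rlang::abort(sprintf(
          "zero block count at offset %d in structure notation",
          pos + 5L + grepl("^\\([ACGTacgt]{3}\\)_", m[1])
        ))
      }
      motifs <- c(motifs, toupper(m[2]))
      counts <- c(counts, cnt)
      pos <- pos + nchar(m[1])
      next
    }
    m <- regmatches(rest, regexec(bare_re, rest))[[1]]
    if (length(m)) {
      motifs <- c(motifs, toupper(m[2]))
      counts <- c(counts, 1L)
      pos <- pos + 3L
      next
    }
    rlang::abort(sprintf(
      "malformed structure notation at offset %d: \"%s\"",
      pos, substr(text, pos, min(n, pos + 11L))
    ))
  }
  repeat_structure(tibble::tibble(motif = motifs, count = counts))
}

#' Format a repeat structure in canonical block notation
#'
#' The inverse of [parse_structure_notation()]. Canonical output uses plain
#' `(MOTIF)count` tokens with uppercase motifs and no underscores, so
#' `parse_structure_notation(format_structure_notation(x))` reproduces `x`
#' block for block.
#'
#' @param structure A [repeat_structure()].
#' @return A single notation string.
#' @export
format_structure_notation <- function(structure) {
  stopifnot(inherits(structure, "repeat_structure"))
  paste0("(", structure$blocks$motif, ")", structure$blocks$count,
         collapse = "")
}

#' Expand a repeat structure to its nucleotide sequence
#'
#' Realizes the DNA tract the notation denotes: motifs concatenated in
#' 5'->3' order, each repeated its block count. The result has length
#' `3 * total_triplets`.
#'
#' @param structure A [repeat_structure()].
#' @return A single DNA string.
#' @examples
#' expand_structure(parse_structure_notation("(CGG)2(AGG)1"))  # "CGGCGGAGG"
#' @export
expand_structure <- function(structure) {
  stopifnot(inherits(structure, "repeat_structure"))
  paste0(strrep(structure$blocks$motif, structure$blocks$count),
         collapse = "")
}

#' Classify an allele by repeat length
#'
#' Applies the standard FMR1 diagnostic size classes: fewer than 45 repeats
#' is normal, 45-54 intermediate (gray zone), 55-200 premutation, and more
#' than 200 a full mutation.
#'
#' @param total_triplets Integer vector of repeat lengths (total triplets
#'   in the tract, interruptions included). Must be positive.
#' @return Character vector with values `"normal"`, `"intermediate"`,
#'   `"premutation"` or `"full_mutation"`.
#' @examples
#' classify_allele(c(30, 49, 69, 230))
#' @export
classify_allele <- function(total_triplets) {
  if (length(total_triplets) == 0L) return(character())
  if (any(is.na(total_triplets)) || any(total_triplets < 1) ||
      any(total_triplets != as.integer(total_triplets))) {
    rlang::abort("`total_triplets` must be positive integers")
  }
  dplyr::case_when(
    total_triplets < 45 ~ "normal",
    total_triplets <= 54 ~ "intermediate",
    total_triplets <= 200 ~ "premutation",
    TRUE ~ "full_mutation"
  )
}

# class order used for monotonicity checks and report sorting
allele_class_levels <- c("normal", "intermediate", "premutation", "full_mutation")
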