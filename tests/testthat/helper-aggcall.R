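# Shared fixtures, all built in code.

# A random repeat structure without any placement convention: arbitrary
# motifs (mostly CGG runs with scattered interruptions), adjacent motifs
# distinct. Used for grammar/expansion round-trip properties.
rand_structure_any <- function(max_blocks = 7L, max_count = 30L) {
  n <- sample(1:max_blocks, 1L)
  motifs <- character(n)
  pool <- c("CGG", "AGG", "CTG", "TGG", "CAG", "GGC")
  prev <- ""
  for (i in seq_len(n)) {
    m <- sample(setdiff(pool, prev), 1L, prob = NULL)
    motifs[i] <- m
    prev <- m
  }
  counts <- sample(1:max_count, n, replace = TRUE)
  repeat_structure(tibble::tibble(motif = motifs, count = counts))
}

# Build an error-free synthetic read around a structure (or notation).
make_read <- function(x, anchors = default_anchors(), barcode = "") {
  s <- if (inherits(x, "repeat_structure")) x else parse_structure_notation(x)
  paste0(barcode, anchors$flank5, expand_structure(s), anchors$flank3)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Error-free read tibble for a set of structures, `n` reads each.
reads_for <- function(notations, n, anchors = default_anchors()) {
  rows <- purrr::imap(notations, function(nt, a) {
    tibble::tibble(
      read_id = sprintf("a%d_r%03d", a, seq_len(n)),
      sequence = make_read(nt, anchors)
    )
  })
  purrr::list_rbind(rows)
}
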