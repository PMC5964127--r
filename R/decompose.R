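#' Anchor configuration for locating the repeat tract
#'
#' The repeat tract is found by searching the read for two flanking anchor
#' sequences (typically the amplicon sequence immediately 5' and 3' of the
#' CGG tract). Anchors must be at least 12 nt long and must not themselves
#' contain a run of three or more CGG triplets, otherwise they could match
#' inside the tract.
#'
#' @param flank5,flank3 DNA strings anchoring the tract on each side.
#' @param max_anchor_mismatches Maximum Hamming mismatches tolerated per
#'   anchor match (ungapped scan).
#' @return An object of class `anchor_config`.
#' @seealso [default_anchors()] for the shipped placeholder pair.
#' @export
anchor_config <- function(flank5, flank3, max_anchor_mismatches = 2L) {
  for (fl in list(flank5, flank3)) {
    if (!is.character(fl) || length(fl) != 1L || !grepl("^[ACGT]+$", fl)) {
      rlang::abort("anchors must be single DNA strings over A/C/G/T")
    }
    if (nchar(fl) < 12L) {
      rlang::abort("anchors must be at least 12 nt long")
    }
    if (grepl("CGGCGGCGG", fl, fixed = TRUE)) {
      rlang::abort("anchors must not contain a run of 3 or more CGG triplets")
    }
  }
  if (max_anchor_mismatches < 0) {
    rlang::abort("`max_anchor_mismatches` must be >= 0")
  }
  structure(
    list(flank5 = flank5, flank3 = flank3,
         max_anchor_mismatches = as.integer(max_anchor_mismatches)),
    class = "anchor_config"
  )
}

# Best ungapped match of `pattern` in `subject` (both DNAString-able):
# smallest mismatch count wins, ties broken leftmost. NULL when nothing
# matches within the budget.
best_anchor_match <- function(pattern, subject, max_mm) {
  for (k in 0:max_mm) {
    hits <- Biostrings::matchPattern(pattern, subject, max.mismatch = k,
                                     with.indels = FALSE)
    if (length(hits) > 0L) {
      return(list(start = Biostrings::start(hits)[1L],
                  end = Biostrings::end(hits)[1L],
                  mismatches = k))
    }
  }
  NULL
}

locate_on_strand <- function(subject, anchors) {
  m5 <- best_anchor_match(anchors$flank5, subject,
                          anchors$max_anchor_mismatches)
  if (is.null(m5)) return(NULL)
  m3 <- NULL
  for (k in 0:anchors$max_anchor_mismatches) {
    hits <- Biostrings::matchPattern(anchors$flank3, subject,
                                     max.mismatch = k, with.indels = FALSE)
    if (length(hits) > 0L) {
      ok <- Biostrings::start(hits) > m5$end
      if (any(ok)) {
        i <- which(ok)[1L]
        m3 <- list(start = Biostrings::start(hits)[i],
                   end = Biostrings::end(hits)[i], mismatches = k)
        break
      }
    }
  }
  if (is.null(m3)) return(NULL)
  tract <- if (m3$start - m5$end >= 2L) {
    as.character(Biostrings::subseq(subject, m5$end + 1L, m3$start - 1L))
  } else {
    ""
  }
  list(tract = tract, flank5_mismatches = m5$mismatches,
       flank3_mismatches = m3$mismatches)
}

#' Locate the repeat tract within a read
#'
#' Scans the read (and, if needed, its reverse complement) for the two
#' flanking anchors with an ungapped Hamming search, and returns the
#' substring strictly between the best 5' anchor match and the first 3'
#' anchor match downstream of it. A read where either anchor cannot be
#' found on either strand is reported as a `no_anchor` outcome, not an
#' error.
#'
#' @param read A single DNA string.
#' @param anchors An [anchor_config()].
#' @return A list with `status` (`"ok"` or `"no_anchor"`), `tract` (DNA
#'   string, possibly empty) and `strand` (`"forward"` or `"reverse"`).
#' @export
locate_repeat <- function(read, anchors) {
  stopifnot(inherits(anchors, "anchor_config"))
  if (!is.character(read) || length(read) != 1L || is.na(read)) {
    rlang::abort("`read` must be a single DNA string")
  }
  subject <- Biostrings::DNAString(read)
  hit <- locate_on_strand(subject, anchors)
  if (!is.null(hit)) {
    return(list(status = "ok", tract = hit$tract, strand = "forward"))
  }
  hit <- locate_on_strand(Biostrings::reverseComplement(subject), anchors)
  if (!is.null(hit)) {
    return(list(status = "ok", tract = hit$tract, strand = "reverse"))
  }
  list(status = "no_anchor", tract = NA_character_, strand = NA_character_)
}

#' Choose the triplet reading frame of a tract
#'
#' Residual indels in a consensus read can shift the triplet frame, so the
#' frame is recovered empirically: offsets 0, 1 and 2 are scored by the
#' fraction of complete triplets that belong to the known motif set, and
#' the best-scoring offset wins (ties resolved toward offset 0, then 1).
#'
#' @param tract DNA string of at least 3 nt.
#' @param known_motifs Character vector of triplets counted as canonical
#'   when scoring a frame. The default covers the repeat motif, the AGG
#'   interruption, and the non-canonical interruptions reported at this
#'   locus (CTG, TGG), so that rare interruptions do not depress the score
#'   of the correct frame.
#' @return A list with `frame_offset` (0, 1 or 2) and `canonical_fraction`.
#' @export
select_frame <- function(tract,
                         known_motifs = c("CGG", "AGG", "CTG", "TGG")) {
  n <- nchar(tract)
  if (is.na(n) || n < 3L) rlang::abort("`tract` must be at least 3 nt")
  best_off <- 0L
  best_frac <- -1
  for (off in 0:2) {
    n_trip <- (n - off) %/% 3L
    if (n_trip < 1L) next
    starts <- off + 1L + 3L * (seq_len(n_trip) - 1L)
    trips <- substring(tract, starts, starts + 2L)
    frac <- mean(trips %in% known_motifs)
    if (frac > best_frac) {
      best_frac <- frac
      best_off <- off
    }
  }
  list(frame_offset = best_off, canonical_fraction = best_frac)
}

#' Decompose a tract into a repeat structure
#'
#' Reads consecutive complete triplets from the given frame offset and
#' collapses maximal runs of identical motifs into blocks. Leftover bases
#' (fewer than 3 at either end) are trimmed, not reported as blocks; their
#' counts are attached as the `"trimmed"` attribute (`c(left, right)`).
#'
#' @param tract DNA string.
#' @param frame_offset Integer 0, 1 or 2; `nchar(tract) - frame_offset`
#'   must be at least 3.
#' @return A [repeat_structure()].
#' @export
decompose_sequence <- function(tract, frame_offset = 0L) {
  n <- nchar(tract)
  frame_offset <- as.integer(frame_offset)
  stopifnot(frame_offset %in% 0:2)
  if (n - frame_offset < 3L) {
    rlang::abort("tract too short to decompose at this frame offset")
  }
  n_trip <- (n - frame_offset) %/% 3L
  starts <- frame_offset + 1L + 3L * (seq_len(n_trip) - 1L)
  trips <- substring(tract, starts, starts + 2L)
  runs <- rle(trips)
  out <- repeat_structure(tibble::tibble(motif = runs$values,
                                         count = runs$lengths))
  attr(out, "trimmed") <- c(left = frame_offset,
                            right = (n - frame_offset) %% 3L)
  out
}

read_call_row <- function(read_id, qc_status, strand = NA_character_,
                          frame_offset = NA_integer_,
                          canonical_fraction = NA_real_,
                          structure = NULL) {
  tibble::tibble(
    read_id = read_id,
    qc_status = qc_status,
    strand = strand,
    frame_offset = frame_offset,
    canonical_fraction = canonical_fraction,
    total_triplets = if (is.null(structure)) NA_integer_ else structure$total_triplets,
    agg_count = if (is.null(structure)) NA_integer_ else structure$agg_count,
    notation = if (is.null(structure)) NA_character_ else format_structure_notation(structure),
    structure = list(structure)
  )
}

#' Call the repeat structure of a single read
#'
#' Composes [locate_repeat()], [select_frame()] and [decompose_sequence()]
#' and applies the per-read QC gate. A read passes only when both anchors
#' are found, the tract is at least 3 nt, leftover bases do not remain at
#' both ends of the chosen frame, and the canonical triplet fraction
#' reaches `min_canonical_fraction`. Reads failing QC carry the matching
#' status (`no_anchor`, `frameshifted`, `low_quality`) and no structure;
#' every read yields a call.
#'
#' @param read A single DNA string.
#' @param anchors An [anchor_config()].
#' @param min_canonical_fraction QC threshold on the fraction of tract
#'   triplets that are CGG, AGG or a known interruption (default 0.9).
#' @param known_interruptions Non-canonical triplets treated as expected at
#'   this locus when scoring frames and QC.
#' @param read_id Identifier carried into the result.
#' @return A one-row tibble with columns `read_id`, `qc_status`, `strand`,
#'   `frame_offset`, `canonical_fraction`, `total_triplets`, `agg_count`,
#'   `notation` and a `structure` list-column.
#' @export
call_read <- function(read, anchors,
                      min_canonical_fraction = 0.9,
                      known_interruptions = c("CTG", "TGG"),
                      read_id = NA_character_) {
  loc <- locate_repeat(read, anchors)
  if (loc$status == "no_anchor") {
    return(read_call_row(read_id, "no_anchor"))
  }
  if (is.na(loc$tract) || nchar(loc$tract) < 3L) {
    return(read_call_row(read_id, "low_quality", strand = loc$strand))
  }
  known <- unique(c("CGG", "AGG", known_interruptions))
  fr <- select_frame(loc$tract, known_motifs = known)
  n <- nchar(loc$tract)
  leftover_left <- fr$frame_offset > 0L
  leftover_right <- (n - fr$frame_offset) %% 3L > 0L
  if ((n - fr$frame_offset) < 3L || (leftover_left && leftover_right)) {
    return(read_call_row(read_id, "frameshifted", strand = loc$strand,
                         frame_offset = fr$frame_offset,
                         canonical_fraction = fr$canonical_fraction))
  }
  if (fr$canonical_fraction < min_canonical_fraction) {
    return(read_call_row(read_id, "low_quality", strand = loc$strand,
                         frame_offset = fr$frame_offset,
                         canonical_fraction = fr$canonical_fraction))
  }
  s <- decompose_sequence(loc$tract, fr$frame_offset)
  read_call_row(read_id, "pass", strand = loc$strand,
                frame_offset = fr$frame_offset,
                canonical_fraction = fr$canonical_fraction,
                structure = s)
}

#' Call repeat structures for a set of reads
#'
#' Vectorized wrapper around [call_read()]: takes a tibble of reads and
#' returns one call per read.
#'
#' @param reads A data frame with columns `read_id` and `sequence`.
#' @inheritParams call_read
#' @return A tibble with one row per read (see [call_read()]).
#' @export
call_reads <- function(reads, anchors,
                       min_canonical_fraction = 0.9,
                       known_interruptions = c("CTG", "TGG")) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  purrr::map2(
    reads$sequence, reads$read_id,
    \(sq, id) call_read(sq, anchors,
                        min_canonical_fraction = min_canonical_fraction,
                        known_interruptions = known_interruptions,
                        read_id = id)
  ) |>
    purrr::list_rbind()
}
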