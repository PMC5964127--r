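hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Barcode manifest
#'
#' Maps sample identifiers to the barcode sequence incorporated during the
#' amplicon PCR. Barcodes must all have the same length and be mutually at
#' least `2 * max_barcode_mismatches + 1` Hamming distance apart, so that a
#' read within the mismatch budget of one barcode can never be within
#' budget of another.
#'
#' @param entries A data frame with columns `sample_id` and `barcode`.
#' @param max_barcode_mismatches Mismatches tolerated when matching a read
#'   prefix against a barcode (default 1).
#' @return A tibble of class `barcode_manifest` with the mismatch budget
#'   attached as an attribute.
#' @export
barcode_manifest <- function(entries, max_barcode_mismatches = 1L) {
  entries <- tibble::as_tibble(entries)
  if (!all(c("sample_id", "barcode") %in% names(entries)) ||
      nrow(entries) == 0L) {
    rlang::abort("manifest needs non-empty columns `sample_id` and `barcode`")
  }
  entries$barcode <- toupper(entries$barcode)
  if (any(!grepl("^[ACGT]+$", entries$barcode))) {
    rlang::abort("barcodes must be DNA strings over A/C/G/T")
  }
  if (length(unique(nchar(entries$barcode))) != 1L) {
    rlang::abort("all barcodes must have the same length")
  }
  if (anyDuplicated(entries$sample_id)) {
    rlang::abort("sample_id values must be unique")
  }
  max_barcode_mismatches <- as.integer(max_barcode_mismatches)
  need <- 2L * max_barcode_mismatches + 1L
  n <- nrow(entries)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        d <- hamming(entries$barcode[i], entries$barcode[j])
        if (d < need) {
          rlang::abort(sprintf(
            "barcodes for samples '%s' and '%s' are only %d mismatches apart (need >= %d for max_barcode_mismatches = %d)",
            entries$sample_id[i], entries$sample_id[j], d, need,
            max_barcode_mismatches
          ))
        }
      }
    }
  }
  structure(entries,
            max_barcode_mismatches = max_barcode_mismatches,
            class = c("barcode_manifest", class(entries)))
}

#' Read a barcode manifest from a two-column TSV
#'
#' The file has columns `sample_id` and `barcode` (a header line is
#' optional). The distance invariant is validated on load.
#'
#' @param path Path to the TSV file.
#' @inheritParams barcode_manifest
#' @return A [barcode_manifest()].
#' @export
read_barcode_manifest <- function(path, max_barcode_mismatches = 1L) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("sample_id", first, fixed = TRUE)
  df <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("sample_id", "barcode"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  barcode_manifest(df, max_barcode_mismatches = max_barcode_mismatches)
}

#' Demultiplex reads by barcode
#'
#' Matches the prefix of each read (in both orientations) against every
#' barcode in the manifest. A read is assigned when exactly one barcode
#' lies within the mismatch budget; reads matching zero barcodes stay
#' unassigned (the manifest distance invariant makes a two-barcode match
#' impossible). Assigned reads are re-oriented so the barcode is at the
#' start and the barcode bases are stripped before downstream calling.
#'
#' @param reads A data frame with columns `read_id` and `sequence`.
#' @param manifest A [barcode_manifest()].
#' @return A tibble with columns `read_id`, `sample_id` (`NA` for
#'   unassigned reads), `sequence` (oriented and barcode-stripped for
#'   assigned reads, original otherwise) and `barcode_mismatches`.
#' @export
demultiplex <- function(reads, manifest) {
  stopifnot(inherits(manifest, "barcode_manifest"),
            all(c("read_id", "sequence") %in% names(reads)))
  max_mm <- attr(manifest, "max_barcode_mismatches")
  bc_len <- nchar(manifest$barcode[1L])
  bcs <- manifest$barcode

  one <- function(sq) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sq)))
    best_sample <- NA_character_
    best_mm <- NA_integer_
    best_seq <- sq
    n_hit <- 0L
    for (i in seq_along(bcs)) {
      for (orient in c("fwd", "rev")) {
        s <- if (orient == "fwd") sq else rc
        if (nchar(s) < bc_len) next
        d <- hamming(substr(s, 1L, bc_len), bcs[i])
        if (d <= max_mm) {
          n_hit <- n_hit + 1L
          best_sample <- manifest$sample_id[i]
          best_mm <- d
          best_seq <- substr(s, bc_len + 1L, nchar(s))
          break  # a barcode matches at most once per read
        }
      }
    }
    if (n_hit == 1L) {
      list(sample_id = best_sample, sequence = best_seq,
           barcode_mismatches = best_mm)
    } else {
      list(sample_id = NA_character_, sequence = sq,
           barcode_mismatches = NA_integer_)
    }
  }

  hits <- purrr::map(reads$sequence, one)
  tibble::tibble(
    read_id = reads$read_id,
    sample_id = purrr::map_chr(hits, "sample_id"),
    sequence = purrr::map_chr(hits, "sequence"),
    barcode_mismatches = purrr::map_int(hits, "barcode_mismatches")
  )
}

insufficient_coverage <- function(sample_id, n_pass, min_reads) {
  rlang::abort(
    sprintf("sample '%s': only %d pass reads (need >= %d per allele)",
            sample_id, n_pass, min_reads),
    class = "aggcall_insufficient_coverage"
  )
}

#' Split pass reads into one or two allele clusters
#'
#' One-dimensional clustering on repeat length: read lengths are sorted and
#' split at the largest inter-read gap. Two clusters are accepted only when
#' that gap is at least `min_length_separation` triplets and each side has
#' at least `min_reads_per_allele` reads; otherwise all reads form one
#' cluster. When a single length cluster results, a second pass looks for
#' two distinct block patterns at the same length, each supported by at
#' least `min_reads_per_allele` reads — the equal-length, different-AGG
#' case — and splits on structure if found.
#'
#' @param calls A tibble of pass read calls (from [call_reads()]).
#' @param min_reads_per_allele Minimum pass reads required per allele
#'   (default 10).
#' @param min_length_separation Minimum length gap, in triplets, accepted
#'   as evidence of two alleles (default 2).
#' @return The input tibble with an integer `cluster` column (1 = shorter
#'   allele). Raises a condition of class `aggcall_insufficient_coverage`
#'   when fewer than `min_reads_per_allele` pass calls are supplied.
#' @export
cluster_reads <- function(calls, min_reads_per_allele = 10L,
                          min_length_separation = 2L) {
  stopifnot(all(c("total_triplets", "notation") %in% names(calls)))
  n <- nrow(calls)
  if (n < min_reads_per_allele) {
    insufficient_coverage(
      if ("sample_id" %in% names(calls) && n > 0L) calls$sample_id[1L] else "?",
      n, min_reads_per_allele
    )
  }
  len <- calls$total_triplets
  ord <- order(len)
  sorted <- len[ord]
  cluster <- rep(1L, n)
  if (n >= 2L) {
    gaps <- diff(sorted)
    g <- which.max(gaps)  # ties -> leftmost split
    if (gaps[g] >= min_length_separation &&
        g >= min_reads_per_allele && (n - g) >= min_reads_per_allele) {
      cut <- sorted[g]  # everything <= cut is the shorter allele
      cluster <- ifelse(len <= cut, 1L, 2L)
      calls$cluster <- cluster
      return(calls)
    }
  }

  # second pass: equal-length alleles that differ in block pattern
  tab <- sort(table(calls$notation), decreasing = TRUE)
  strong <- names(tab)[tab >= min_reads_per_allele]
  if (length(strong) >= 2L) {
    a <- strong[1L]
    b <- strong[2L]
    len_a <- calls$total_triplets[match(a, calls$notation)]
    len_b <- calls$total_triplets[match(b, calls$notation)]
    if (len_a == len_b && a != b) {
      first <- min(a, b)   # deterministic: lexicographically smaller = cluster 1
      second <- max(a, b)
      cluster <- dplyr::case_when(
        calls$notation == first ~ 1L,
        calls$notation == second ~ 2L,
        # deviant reads go with the better-supported pattern
        .default = if (tab[[first]] >= tab[[second]]) 1L else 2L
      )
    }
  }
  calls$cluster <- cluster
  calls
}

#' Consensus structure of one read cluster
#'
#' The consensus is the modal exact block list among the cluster's
#' structures; ties are broken toward the structure whose total length is
#' closest to the cluster median, then toward the lexicographically
#' smallest canonical notation, so the result is independent of read
#' order.
#'
#' @param cluster_calls A non-empty tibble of pass read calls.
#' @return A one-row tibble: `notation`, `structure` (list-column),
#'   `total_triplets`, `agg_count`, `allele_class`, `n_supporting_reads`,
#'   `cluster_size`, `support_ratio` and `length_spread` (max - min
#'   supporting read length).
#' @export
consensus_structure <- function(cluster_calls) {
  stopifnot(nrow(cluster_calls) >= 1L)
  tab <- table(cluster_calls$notation)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {
    med <- stats::median(cluster_calls$total_triplets)
    cand_len <- vapply(
      top, \(nt) cluster_calls$total_triplets[match(nt, cluster_calls$notation)],
      integer(1)
    )
    d <- abs(cand_len - med)
    top <- top[d == min(d)]
    top <- sort(top)[1L]
  }
  s <- cluster_calls$structure[[match(top, cluster_calls$notation)]]
  n_support <- as.integer(tab[[top]])
  tibble::tibble(
    notation = format_structure_notation(s),
    structure = list(s),
    total_triplets = s$total_triplets,
    agg_count = s$agg_count,
    allele_class = classify_allele(s$total_triplets),
    n_supporting_reads = n_support,
    cluster_size = nrow(cluster_calls),
    support_ratio = n_support / nrow(cluster_calls),
    length_spread = as.integer(diff(range(cluster_calls$total_triplets)))
  )
}

#' Call the allele structures of one sample
#'
#' Runs per-read calling, filters to pass reads, phases them into one or
#' two allele clusters and reports a consensus structure per allele,
#' ordered by ascending repeat length. A single cluster is reported as a
#' possible homozygote — true homozygosity and allele dropout cannot be
#' distinguished from the read set alone, so the call is flagged rather
#' than resolved.
#'
#' @param reads A data frame with columns `read_id` and `sequence`
#'   (barcode already stripped).
#' @param sample_id Sample identifier carried into the result.
#' @param anchors An [anchor_config()].
#' @inheritParams call_read
#' @inheritParams cluster_reads
#' @return An object of class `sample_call`: a list with `sample_id`,
#'   `alleles` (tibble, one row per allele), `zygosity_note`,
#'   `n_reads_total`, `n_reads_pass` and the per-read `read_calls` tibble.
#' @export
call_sample <- function(reads, sample_id = "sample",
                        anchors = default_anchors(),
                        min_canonical_fraction = 0.9,
                        known_interruptions = c("CTG", "TGG"),
                        min_reads_per_allele = 10L,
                        min_length_separation = 2L) {
  calls <- call_reads(reads, anchors,
                      min_canonical_fraction = min_canonical_fraction,
                      known_interruptions = known_interruptions)
  pass <- dplyr::filter(calls, .data$qc_status == "pass")
  pass$sample_id <- rep(sample_id, nrow(pass))
  clustered <- cluster_reads(pass,
                             min_reads_per_allele = min_reads_per_allele,
                             min_length_separation = min_length_separation)
  alleles <- clustered |>
    dplyr::group_by(.data$cluster) |>
    dplyr::group_map(\(df, key) consensus_structure(df)) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$total_triplets, .data$notation)
  alleles <- dplyr::bind_cols(
    tibble::tibble(allele = seq_len(nrow(alleles))), alleles
  )
  structure(
    list(
      sample_id = sample_id,
      alleles = alleles,
      zygosity_note = if (nrow(alleles) == 2L) "two_alleles"
                      else "single_cluster_possible_homozygote",
      n_reads_total = nrow(reads),
      n_reads_pass = nrow(pass),
      read_calls = calls
    ),
    class = "sample_call"
  )
}

#' @export
print.sample_call <- function(x, ...) {
  cat("<sample_call> ", x$sample_id, ": ", nrow(x$alleles), " allele(s), ",
      x$n_reads_pass, "/", x$n_reads_total, " reads pass\n", sep = "")
  for (i in seq_len(nrow(x$alleles))) {
    a <- x$alleles[i, ]
    cat(sprintf("  allele %d: %d repeats, %d AGG, %s  [%s; %d/%d reads]\n",
                a$allele, a$total_triplets, a$agg_count, a$allele_class,
                a$notation, a$n_supporting_reads, a$cluster_size))
  }
  if (x$zygosity_note != "two_alleles") {
    cat("  note: single cluster — possible homozygote or allele dropout\n")
  }
  invisible(x)
}
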