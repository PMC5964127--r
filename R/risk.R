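#' Expansion-risk anchor table
#'
#' Maps (repeat length bin, AGG interruption count) of a maternal
#' premutation allele to the published risk, in percent, that the allele
#' expands to a full mutation in one transmission. The table is
#' anchor-based: it stores point values from the risk literature and is
#' never interpolated — a query that falls outside every bin returns
#' not-available with its nearest bounds instead of an invented number,
#' which is the safe behaviour in a counseling context.
#'
#' Validated invariants: bins non-overlapping per AGG count; risks within
#' \[0, 100\]; for a fixed AGG count risk non-decreasing with length; for
#' overlapping length bins risk non-increasing in AGG count.
#'
#' @param entries A data frame with columns `length_min`, `length_max`,
#'   `agg_count`, `risk_percent` and `source`.
#' @return A tibble of class `risk_table`.
#' @seealso [default_risk_table()], [load_risk_table()]
#' @export
risk_table <- function(entries) {
  entries <- tibble::as_tibble(entries)
  need <- c("length_min", "length_max", "agg_count", "risk_percent")
  if (!all(need %in% names(entries))) {
    rlang::abort(paste("risk table needs columns",
                       paste(need, collapse = ", ")))
  }
  if (!"source" %in% names(entries)) entries$source <- NA_character_
  if (nrow(entries) == 0L) {
    return(structure(entries, class = c("risk_table", class(entries))))
  }
  entries$length_min <- as.integer(entries$length_min)
  entries$length_max <- as.integer(entries$length_max)
  entries$agg_count <- as.integer(entries$agg_count)
  entries$risk_percent <- as.numeric(entries$risk_percent)

  bad <- which(entries$risk_percent < 0 | entries$risk_percent > 100 |
                 is.na(entries$risk_percent))
  if (length(bad)) {
    rlang::abort(sprintf("risk_percent outside [0, 100] in entries: %s",
                         paste(bad, collapse = ", ")))
  }
  bad <- which(entries$length_min > entries$length_max)
  if (length(bad)) {
    rlang::abort(sprintf("length_min > length_max in entries: %s",
                         paste(bad, collapse = ", ")))
  }

  entry_label <- function(i) {
    sprintf("[%d-%d, %d AGG -> %g%%]", entries$length_min[i],
            entries$length_max[i], entries$agg_count[i],
            entries$risk_percent[i])
  }

  # per-AGG: bins must not overlap and risk must be non-decreasing in length
  for (agg in unique(entries$agg_count)) {
    idx <- which(entries$agg_count == agg)
    idx <- idx[order(entries$length_min[idx])]
    if (length(idx) < 2L) next
    for (k in seq_len(length(idx) - 1L)) {
      i <- idx[k]; j <- idx[k + 1L]
      if (entries$length_min[j] <= entries$length_max[i]) {
        rlang::abort(sprintf("overlapping length bins for %d AGG: %s and %s",
                             agg, entry_label(i), entry_label(j)))
      }
      if (entries$risk_percent[j] < entries$risk_percent[i]) {
        rlang::abort(sprintf(
          "risk must be non-decreasing with length for %d AGG: %s then %s",
          agg, entry_label(i), entry_label(j)))
      }
    }
  }

  # across AGG counts: more AGGs never raises the risk at the same length
  n <- nrow(entries)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (entries$agg_count[i] < entries$agg_count[j] &&
          entries$length_min[i] <= entries$length_max[j] &&
          entries$length_min[j] <= entries$length_max[i] &&
          entries$risk_percent[i] < entries$risk_percent[j]) {
        rlang::abort(sprintf(
          "risk must be non-increasing in AGG count at overlapping lengths: %s vs %s",
          entry_label(i), entry_label(j)))
      }
    }
  }
  structure(entries, class = c("risk_table", class(entries)))
}

#' Load a risk table from a TSV config file
#'
#' The file has columns `length_min`, `length_max`, `agg_count`,
#' `risk_percent` and `source`. All [risk_table()] invariants are enforced
#' on load; violations raise an error naming the offending entries.
#'
#' @param path Path to the TSV file.
#' @return A [risk_table()].
#' @export
load_risk_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    length_min = readr::col_integer(),
    length_max = readr::col_integer(),
    agg_count = readr::col_integer(),
    risk_percent = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  risk_table(df)
}

#' The shipped default risk anchors
#'
#' Eight anchors covering the risk values most used in counseling
#' premutation carriers: AGG-free alleles under 60 repeats (2.6%), 69
#' repeats (22.9%), 75 repeats (77%) and 95-100 repeats (100%); and
#' 2-AGG alleles of 69 (0.5%), 75 (12%), 80-84 (~30%, flagged approximate)
#' and 85-89 repeats (60%). Values derive from the published
#' transmission-risk literature (Yrigollen et al.); unlisted cells are
#' deliberately not interpolated.
#'
#' @return A [risk_table()].
#' @export
default_risk_table <- function() {
  load_risk_table(system.file("extdata", "fmr1_risk_anchors.tsv",
                              package = "aggcall", mustWork = TRUE))
}

#' Estimate the expansion risk of one allele
#'
#' Looks up (repeat length, AGG count) in a [risk_table()]. Only
#' intermediate and premutation alleles are eligible: normal and
#' full-mutation alleles return a `not_applicable` outcome. An eligible
#' allele that matches no bin returns `not_available` together with the
#' nearest lower/upper length anchors at the same AGG count, so the
#' counselor sees the bracketing published values rather than an
#' invented one.
#'
#' @param total_triplets Allele repeat length.
#' @param agg_count Number of AGG interruptions.
#' @param table A [risk_table()] (default: the shipped anchors).
#' @param high_cutoff,low_cutoff Category thresholds in percent: risk >=
#'   `high_cutoff` is "high", risk < `low_cutoff` is "low", otherwise
#'   "moderate".
#' @return An object of class `risk_estimate`: a list with `status`
#'   (`"available"`, `"not_available"`, `"not_applicable"`),
#'   `risk_percent`, `category`, `matched_entry` and `nearest_bounds`.
#' @examples
#' estimate_expansion_risk(75, 2)   # 12% (moderate)
#' estimate_expansion_risk(69, 0)   # 22.9% (high)
#' @export
estimate_expansion_risk <- function(total_triplets, agg_count,
                                    table = default_risk_table(),
                                    high_cutoff = 20, low_cutoff = 5) {
  stopifnot(inherits(table, "risk_table"))
  total_triplets <- as.integer(total_triplets)
  agg_count <- as.integer(agg_count)
  cls <- classify_allele(total_triplets)
  out <- list(
    total_triplets = total_triplets,
    agg_count = agg_count,
    allele_class = cls,
    status = "not_applicable",
    risk_percent = NA_real_,
    category = NA_character_,
    matched_entry = NULL,
    nearest_bounds = NULL
  )
  class(out) <- "risk_estimate"
  if (!cls %in% c("intermediate", "premutation")) {
    return(out)
  }
  hit <- which(table$agg_count == agg_count &
                 table$length_min <= total_triplets &
                 table$length_max >= total_triplets)
  if (length(hit) == 1L) {
    out$status <- "available"
    out$risk_percent <- table$risk_percent[hit]
    out$category <- if (out$risk_percent >= high_cutoff) "high"
                    else if (out$risk_percent < low_cutoff) "low"
                    else "moderate"
    out$matched_entry <- table[hit, ]
    return(out)
  }
  out$status <- "not_available"
  same <- table[table$agg_count == agg_count, , drop = FALSE]
  if (nrow(same)) {
    lower <- same[same$length_max < total_triplets, , drop = FALSE]
    upper <- same[same$length_min > total_triplets, , drop = FALSE]
    bounds <- dplyr::bind_rows(
      if (nrow(lower)) dplyr::mutate(
        lower[which.max(lower$length_max), ], bound = "lower"),
      if (nrow(upper)) dplyr::mutate(
        upper[which.min(upper$length_min), ], bound = "upper")
    )
    if (nrow(bounds)) out$nearest_bounds <- bounds
  }
  out
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat("<risk_estimate> ", x$total_triplets, " repeats, ", x$agg_count,
      " AGG (", x$allele_class, ")\n", sep = "")
  if (x$status == "available") {
    cat(sprintf("  expansion risk: %g%% (%s)\n", x$risk_percent, x$category))
  } else if (x$status == "not_available") {
    cat("  no anchor for this length/AGG combination\n")
    if (!is.null(x$nearest_bounds)) {
      for (i in seq_len(nrow(x$nearest_bounds))) {
        b <- x$nearest_bounds[i, ]
        cat(sprintf("  nearest %s anchor: %d-%d repeats, %d AGG -> %g%%\n",
                    b$bound, b$length_min, b$length_max, b$agg_count,
                    b$risk_percent))
      }
    }
  } else {
    cat("  not applicable: allele is", x$allele_class, "\n")
  }
  invisible(x)
}

#' Prioritize the allele with the lower expansion risk
#'
#' Compares two intermediate/premutation alleles — for instance embryo
#' haplotypes during preimplantation diagnosis — and selects the one with
#' the lower expansion risk. When both risks are available in the table
#' the comparison is on risk; when either is not, the fallback ordering is
#' fewer repeats, then more AGGs, which is the direction the table's
#' monotonicity invariants guarantee.
#'
#' @param a,b Length-2 numeric vectors `c(total_triplets, agg_count)`.
#' @param table A [risk_table()].
#' @return A list of class `allele_priority`: `selected` (`"a"` or `"b"`),
#'   `total_triplets` and `agg_count` of the selected allele, `basis`
#'   (`"risk"` or `"length_agg"`), `tie` flag and both risk estimates.
#' @examples
#' prioritize_alleles(c(65, 2), c(73, 2))$total_triplets  # 65
#' @export
prioritize_alleles <- function(a, b, table = default_risk_table()) {
  stopifnot(length(a) == 2L, length(b) == 2L)
  ra <- estimate_expansion_risk(a[1], a[2], table)
  rb <- estimate_expansion_risk(b[1], b[2], table)
  tie <- FALSE
  if (ra$status == "available" && rb$status == "available") {
    basis <- "risk"
    if (ra$risk_percent < rb$risk_percent) {
      sel <- "a"
    } else if (rb$risk_percent < ra$risk_percent) {
      sel <- "b"
    } else {
      sel <- "a"; tie <- TRUE
    }
  } else {
    basis <- "length_agg"
    if (a[1] != b[1]) {
      sel <- if (a[1] < b[1]) "a" else "b"      # fewer repeats = lower risk
    } else if (a[2] != b[2]) {
      sel <- if (a[2] > b[2]) "a" else "b"      # more AGGs = lower risk
    } else {
      sel <- "a"; tie <- TRUE
    }
  }
  chosen <- if (sel == "a") a else b
  structure(
    list(selected = sel,
         total_triplets = as.integer(chosen[1]),
         agg_count = as.integer(chosen[2]),
         basis = basis, tie = tie, risk_a = ra, risk_b = rb),
    class = "allele_priority"
  )
}

#' @export
print.allele_priority <- function(x, ...) {
  cat(sprintf(
    "<allele_priority> select allele '%s': %d repeats, %d AGG (basis: %s%s)\n",
    x$selected, x$total_triplets, x$agg_count, x$basis,
    if (x$tie) ", tie" else ""))
  invisible(x)
}
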