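cohort_bin_labels <- c("<20",
                       paste(seq(20, 90, by = 5), seq(24, 94, by = 5), sep = "-"),
                       "95-100", ">100")

bin_repeat_length <- function(total_triplets) {
  breaks <- c(-Inf, seq(19, 94, by = 5), 100, Inf)
  cut(total_triplets, breaks = breaks, labels = cohort_bin_labels,
      right = TRUE)
}

#' Cohort cross-tab of repeat size against AGG count
#'
#' Bins every allele into the conventional 5-repeat size bins (20-24
#' through 90-94, then 95-100, with catch-all bins outside that range)
#' against its AGG interruption count (0, 1, 2, 3+), with marginals.
#' Non-canonical interruptions do not contribute to the AGG count.
#'
#' @param calls Either a list of `sample_call` objects or a data frame of
#'   alleles with columns `total_triplets` and `agg_count`.
#' @return A tibble of class `cohort_summary`: one row per occupied size
#'   bin, AGG-count columns `0`, `1`, `2`, `3+`, a `n_alleles` row
#'   marginal, and attributes `agg_marginals` and `n_total`.
#' @export
summarize_cohort <- function(calls) {
  alleles <- if (is.data.frame(calls)) {
    tibble::as_tibble(calls)
  } else if (is.list(calls) && all(vapply(calls, inherits, logical(1),
                                          "sample_call"))) {
    purrr::map(calls, \(x) x$alleles) |> purrr::list_rbind()
  } else {
    rlang::abort("`calls` must be a data frame of alleles or a list of sample_call objects")
  }
  if (nrow(alleles) == 0L) rlang::abort("no alleles to summarize")
  stopifnot(all(c("total_triplets", "agg_count") %in% names(alleles)))

  agg_lvls <- c("0", "1", "2", "3+")
  df <- tibble::tibble(
    repeat_range = bin_repeat_length(alleles$total_triplets),
    agg = factor(ifelse(alleles$agg_count >= 3, "3+",
                        as.character(alleles$agg_count)),
                 levels = agg_lvls)
  )
  wide <- df |>
    dplyr::count(.data$repeat_range, .data$agg, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "agg", values_from = "n",
                       values_fill = 0L) |>
    dplyr::mutate(
      n_alleles = as.integer(rowSums(dplyr::pick(dplyr::all_of(agg_lvls))))
    ) |>
    dplyr::filter(.data$n_alleles > 0L) |>
    dplyr::arrange(.data$repeat_range)
  agg_marginals <- colSums(wide[, agg_lvls, drop = FALSE])
  structure(wide,
            agg_marginals = agg_marginals,
            n_total = sum(wide$n_alleles),
            class = c("cohort_summary", class(wide)))
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary> ", attr(x, "n_total"), " alleles\n", sep = "")
  NextMethod()
  m <- attr(x, "agg_marginals")
  cat("alleles with N AGG triplets: ",
      paste(names(m), m, sep = "=", collapse = "  "), "\n", sep = "")
  invisible(x)
}
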