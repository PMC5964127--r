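#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the allele calls of a sample
#'
#' @param x A `sample_call` (from [call_sample()]).
#' @param ... Unused.
#' @return A tibble with one row per called allele: repeat length, AGG
#'   count and positions, canonical notation, allele class and read
#'   support.
#' @method tidy sample_call
#' @export
tidy.sample_call <- function(x, ...) {
  x$alleles |>
    dplyr::mutate(
      sample_id = x$sample_id,
      agg_positions = vapply(.data$structure, function(s)
        paste(s$agg_positions, collapse = ","), character(1)),
      .before = 1L
    ) |>
    dplyr::select(-"structure")
}

#' One-row QC summary of a sample call
#'
#' @param x A `sample_call`.
#' @param ... Unused.
#' @return A one-row tibble: read counts, pass rate, number of alleles,
#'   zygosity note and the minimum consensus support ratio.
#' @method glance sample_call
#' @export
glance.sample_call <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id,
    n_reads_total = x$n_reads_total,
    n_reads_pass = x$n_reads_pass,
    pass_rate = x$n_reads_pass / max(x$n_reads_total, 1L),
    n_alleles = nrow(x$alleles),
    zygosity_note = x$zygosity_note,
    min_support_ratio = min(x$alleles$support_ratio)
  )
}

#' Tidy a pipeline run into one row per allele
#'
#' @param x A `pipeline_result` (from [run_pipeline()]).
#' @param ... Unused.
#' @return The pipeline's allele table without the structure list-column.
#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) {
  dplyr::select(x$allele_table, -"structure")
}
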