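#' Histogram of per-read repeat lengths
#'
#' The length signal that drives allele phasing: pass reads of a
#' two-allele female form two modes separated by the allele size
#' difference.
#'
#' @param calls A tibble of read calls (from [call_reads()]); only pass
#'   reads are drawn.
#' @return A ggplot object.
#' @export
plot_read_lengths <- function(calls) {
  pass <- dplyr::filter(calls, .data$qc_status == "pass")
  ggplot2::ggplot(pass, ggplot2::aes(x = .data$total_triplets)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::labs(x = "repeat length (triplets)", y = "pass reads") +
    ggplot2::theme_minimal()
}

#' @rdname plot_read_lengths
#' @param object A `sample_call`; consensus allele lengths are marked.
#' @param ... Unused.
#' @method autoplot sample_call
#' @export
autoplot.sample_call <- function(object, ...) {
  plot_read_lengths(object$read_calls) +
    ggplot2::geom_vline(xintercept = object$alleles$total_triplets,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::ggtitle(object$sample_id)
}

#' Heatmap of a cohort summary
#'
#' @param object A `cohort_summary` (from [summarize_cohort()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_summary
#' @export
autoplot.cohort_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("repeat_range", "0", "1", "2", "3+")],
    cols = -"repeat_range", names_to = "agg", values_to = "n"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$agg, y = .data$repeat_range,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::labs(x = "AGG interruptions", y = "repeat size bin",
                  fill = "alleles") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
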