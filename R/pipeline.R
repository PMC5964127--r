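default_pipeline_config <- function() {
  anc <- default_anchors()
  list(
    flank5 = anc$flank5,
    flank3 = anc$flank3,
    max_anchor_mismatches = 2L,
    min_canonical_fraction = 0.9,
    known_interruptions = c("CTG", "TGG"),
    min_reads_per_allele = 10L,
    min_length_separation = 2L,
    max_barcode_mismatches = 1L,
    risk_table = NULL  # path to a TSV; NULL = shipped default anchors
  )
}

#' Read the pipeline configuration file
#'
#' A YAML key/value file; recognized keys are `flank5`, `flank3`,
#' `max_anchor_mismatches`, `min_canonical_fraction`,
#' `known_interruptions`, `min_reads_per_allele`, `min_length_separation`,
#' `max_barcode_mismatches` and `risk_table` (path to a risk TSV). Missing
#' keys take package defaults; `NULL` returns the defaults outright.
#'
#' @param path Path to the YAML file, or `NULL`.
#' @return A named list of settings.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) rlang::abort(paste("config file not found:", path))
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    rlang::warn(paste("ignoring unknown config keys:",
                      paste(unknown, collapse = ", ")))
  }
  for (k in intersect(names(user), names(cfg))) cfg[[k]] <- user[[k]]
  cfg
}

#' Read amplicon reads from FASTQ or FASTA
#'
#' Format is sniffed from the first character of the file (`@` = FASTQ,
#' `>` = FASTA).
#'
#' @param path Path to the reads file.
#' @return A tibble with columns `read_id` and `sequence`.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) rlang::abort(paste("reads file not found:", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) rlang::abort(paste("reads file is empty:", path))
  fmt <- if (startsWith(first, "@")) "fastq"
         else if (startsWith(first, ">")) "fasta"
         else rlang::abort("reads file is neither FASTQ nor FASTA")
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  if (length(ss) == 0L) rlang::abort(paste("reads file is empty:", path))
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(ss)),
    sequence = unname(as.character(ss))
  )
}

risk_fields <- function(est) {
  list(
    status = est$status,
    risk_percent = if (is.na(est$risk_percent)) NULL else est$risk_percent,
    category = if (is.na(est$category)) NULL else est$category,
    nearest_bounds = if (is.null(est$nearest_bounds)) NULL else
      lapply(seq_len(nrow(est$nearest_bounds)), function(i) {
        b <- est$nearest_bounds[i, ]
        list(bound = b$bound, length_min = b$length_min,
             length_max = b$length_max, agg_count = b$agg_count,
             risk_percent = b$risk_percent)
      })
  )
}

sample_report <- function(sc, table, n_reads_demuxed = NA_integer_) {
  alleles <- lapply(seq_len(nrow(sc$alleles)), function(i) {
    a <- sc$alleles[i, ]
    s <- a$structure[[1L]]
    est <- estimate_expansion_risk(a$total_triplets, a$agg_count, table)
    list(
      allele = a$allele,
      total_triplets = a$total_triplets,
      agg_count = a$agg_count,
      agg_positions = as.integer(s$agg_positions),
      noncanonical = if (nrow(s$noncanonical)) as.list(s$noncanonical) else NULL,
      notation = a$notation,
      allele_class = a$allele_class,
      n_supporting_reads = a$n_supporting_reads,
      cluster_size = a$cluster_size,
      support_ratio = a$support_ratio,
      length_spread = a$length_spread,
      risk = if (est$status == "not_applicable") NULL else risk_fields(est)
    )
  })
  list(
    sample_id = sc$sample_id,
    status = "ok",
    zygosity_note = sc$zygosity_note,
    qc = list(n_reads = n_reads_demuxed, n_reads_pass = sc$n_reads_pass),
    alleles = alleles
  )
}

#' Run the full calling pipeline on one sequencing pool
#'
#' Demultiplexes the pooled reads by barcode, calls both allele structures
#' per sample, attaches expansion-risk estimates for intermediate and
#' premutation alleles, and (optionally) writes machine-readable
#' (`report.json`) and human-readable (`report.tsv`, `cohort.tsv`)
#' reports. Samples with insufficient pass coverage are recorded in the
#' report and the run continues; malformed or empty inputs are usage
#' errors.
#'
#' @param reads_file FASTQ or FASTA of pooled amplicon reads.
#' @param manifest_file Two-column TSV mapping sample_id to barcode.
#' @param config_file Optional YAML config (see [read_pipeline_config()]).
#' @param out_dir Optional output directory for `report.json`,
#'   `report.tsv` and `cohort.tsv`.
#' @return A list of class `pipeline_result`: `samples` (named list of
#'   [call_sample()] results or error records), `report` (nested report
#'   list), `allele_table` (tidy tibble of all called alleles), `cohort`
#'   (a [summarize_cohort()] tibble or `NULL`), and `n_unassigned`.
#' @export
run_pipeline <- function(reads_file, manifest_file, config_file = NULL,
                         out_dir = NULL) {
  cfg <- read_pipeline_config(config_file)
  reads <- read_reads(reads_file)
  manifest <- read_barcode_manifest(
    manifest_file, max_barcode_mismatches = cfg$max_barcode_mismatches)
  anchors <- anchor_config(cfg$flank5, cfg$flank3,
                           max_anchor_mismatches = cfg$max_anchor_mismatches)
  table <- if (is.null(cfg$risk_table)) default_risk_table()
           else load_risk_table(cfg$risk_table)

  demux <- demultiplex(reads, manifest)
  n_unassigned <- sum(is.na(demux$sample_id))

  samples <- list()
  reports <- list()
  allele_rows <- list()
  for (sid in manifest$sample_id) {
    sub <- demux[!is.na(demux$sample_id) & demux$sample_id == sid, ]
    res <- tryCatch(
      call_sample(sub, sample_id = sid, anchors = anchors,
                  min_canonical_fraction = cfg$min_canonical_fraction,
                  known_interruptions = cfg$known_interruptions,
                  min_reads_per_allele = cfg$min_reads_per_allele,
                  min_length_separation = cfg$min_length_separation),
      aggcall_insufficient_coverage = function(e) e
    )
    if (inherits(res, "aggcall_insufficient_coverage")) {
      samples[[sid]] <- res
      reports[[sid]] <- list(sample_id = sid, status = "insufficient_coverage",
                             message = conditionMessage(res),
                             qc = list(n_reads = nrow(sub)))
    } else {
      samples[[sid]] <- res
      reports[[sid]] <- sample_report(res, table, n_reads_demuxed = nrow(sub))
      allele_rows[[sid]] <- dplyr::mutate(res$alleles, sample_id = sid,
                                          .before = 1L)
    }
  }
  allele_table <- purrr::list_rbind(allele_rows)
  cohort <- if (nrow(allele_table) > 0L) summarize_cohort(allele_table) else NULL

  out <- structure(
    list(samples = samples, report = unname(reports),
         allele_table = allele_table, cohort = cohort,
         n_unassigned = n_unassigned, config = cfg),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_reports(out, out_dir, table)
  invisible(out)
}

write_reports <- function(result, out_dir, table = default_risk_table()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(pipeline = "aggcall", n_unassigned_reads = result$n_unassigned,
         samples = result$report),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  tsv <- result$allele_table
  if (nrow(tsv) > 0L) {
    risk <- lapply(seq_len(nrow(tsv)), function(i) {
      estimate_expansion_risk(tsv$total_triplets[i], tsv$agg_count[i], table)
    })
    tsv <- tsv |>
      dplyr::mutate(
        agg_positions = vapply(.data$structure, function(s)
          paste(s$agg_positions, collapse = ","), character(1)),
        noncanonical = vapply(.data$structure, function(s)
          paste(paste0(s$noncanonical$motif, "@", s$noncanonical$position),
                collapse = ","), character(1)),
        risk_status = vapply(risk, function(r) r$status, character(1)),
        risk_percent = vapply(risk, function(r) r$risk_percent, numeric(1)),
        risk_category = vapply(risk, function(r) r$category, character(1))
      ) |>
      dplyr::select(-"structure")
    readr::write_tsv(tsv, file.path(out_dir, "report.tsv"))
  }
  if (!is.null(result$cohort)) {
    readr::write_tsv(result$cohort, file.path(out_dir, "cohort.tsv"))
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  ok <- sum(vapply(x$samples, inherits, logical(1), "sample_call"))
  cat("<pipeline_result> ", length(x$samples), " sample(s), ", ok,
      " called, ", x$n_unassigned, " unassigned reads\n", sep = "")
  invisible(x)
}
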