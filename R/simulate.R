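#' Simulation configuration
#'
#' Describes one simulated sample: its one or two allele structures, the
#' per-allele read coverage, the per-base error model, coverage bias
#' against the longer allele, and the barcode/flank layout of the
#' amplicon. A seed is mandatory so every simulation is reproducible.
#'
#' @param alleles Character vector of 1 or 2 structure-notation strings.
#' @param coverage_per_allele Reads per allele before bias (default 30).
#' @param p_sub,p_ins,p_del Per-base substitution / insertion / deletion
#'   probabilities, each in \[0, 0.2\]. Defaults of 0.002 reflect the
#'   residual error of high-accuracy consensus reads.
#' @param allelic_bias Multiplier in (0, 1\] applied to the longer
#'   allele's coverage (1 = no bias).
#' @param barcode,flank5,flank3 Amplicon layout; each read is
#'   `barcode + flank5 + tract + flank3` before errors.
#' @param seed Integer seed (required).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(alleles,
                       coverage_per_allele = 30L,
                       p_sub = 0.002, p_ins = 0.002, p_del = 0.002,
                       allelic_bias = 1,
                       barcode = default_barcodes(1L),
                       flank5 = default_anchors()$flank5,
                       flank3 = default_anchors()$flank3,
                       seed = NULL) {
  if (is.null(seed)) rlang::abort("`seed` is required for reproducibility")
  if (length(alleles) < 1L || length(alleles) > 2L) {
    rlang::abort("`alleles` must contain 1 or 2 structure notations")
  }
  probs <- c(p_sub = p_sub, p_ins = p_ins, p_del = p_del)
  if (any(probs < 0) || any(probs > 0.2)) {
    rlang::abort("error probabilities must lie in [0, 0.2]")
  }
  if (coverage_per_allele < 1L) rlang::abort("coverage must be >= 1")
  if (allelic_bias <= 0 || allelic_bias > 1) {
    rlang::abort("`allelic_bias` must be in (0, 1]")
  }
  structure(
    list(alleles = alleles,
         coverage_per_allele = as.integer(coverage_per_allele),
         p_sub = p_sub, p_ins = p_ins, p_del = p_del,
         allelic_bias = allelic_bias,
         barcode = barcode, flank5 = flank5, flank3 = flank3,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Apply iid per-base substitutions, insertions (after a base) and
# deletions to one sequence; returns the mutated sequence plus event
# counts. Consumes RNG state.
inject_errors <- function(sq, p_sub, p_ins, p_del) {
  b <- strsplit(sq, "", fixed = TRUE)[[1]]
  n <- length(b)
  del <- stats::runif(n) < p_del
  sub <- stats::runif(n) < p_sub & !del
  ins <- stats::runif(n) < p_ins
  if (any(sub)) {
    cur <- b[sub]
    # substitute with a uniformly chosen different base
    repl <- vapply(cur, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
                   character(1), USE.NAMES = FALSE)
    b[sub] <- repl
  }
  keep <- ifelse(del, "", b)
  insert <- ifelse(ins, NA_character_, "")
  if (any(ins)) {
    insert[ins] <- sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE)
  }
  list(sequence = paste0(keep, insert, collapse = ""),
       n_sub = sum(sub), n_ins = sum(ins), n_del = sum(del))
}

#' Simulate barcoded amplicon reads for one sample
#'
#' Emits `coverage_per_allele` reads per allele (the longer allele scaled
#' by `allelic_bias`, rounded), each built as barcode + 5' flank +
#' expanded tract + 3' flank with iid substitutions, insertions and
#' deletions applied at the configured rates. Each read is emitted on a
#' random strand (single-molecule reads come in both orientations). The
#' ground-truth manifest records the source allele and injected error
#' counts of every read. A fixed seed makes the output byte-identical
#' across runs.
#'
#' @param config A [sim_config()].
#' @param sample_id Identifier used in read names and the truth manifest.
#' @return A list with `reads` (tibble: `read_id`, `sequence`, `quality`)
#'   and `truth` (tibble: `read_id`, `allele`, `notation`, `strand`,
#'   `n_sub`, `n_ins`, `n_del`).
#' @export
simulate_sample <- function(config, sample_id = "sim") {
  stopifnot(inherits(config, "sim_config"))
  structures <- lapply(config$alleles, parse_structure_notation)
  totals <- vapply(structures, function(s) s$total_triplets, integer(1))

  n_reads <- rep(config$coverage_per_allele, length(structures))
  if (length(structures) == 2L) {
    longer <- if (totals[2L] >= totals[1L]) 2L else 1L
    n_reads[longer] <- as.integer(round(config$coverage_per_allele *
                                          config$allelic_bias))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  rows <- list()
  k <- 0L
  for (a in seq_along(structures)) {
    template <- paste0(config$barcode, config$flank5,
                       expand_structure(structures[[a]]), config$flank3)
    for (r in seq_len(n_reads[a])) {
      k <- k + 1L
      err <- inject_errors(template, config$p_sub, config$p_ins, config$p_del)
      strand <- sample(c("forward", "reverse"), 1L)
      sq <- if (strand == "reverse") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(err$sequence)))
      } else {
        err$sequence
      }
      rows[[k]] <- tibble::tibble(
        read_id = sprintf("%s_a%d_r%03d", sample_id, a, r),
        sequence = sq,
        allele = a,
        notation = format_structure_notation(structures[[a]]),
        strand = strand,
        n_sub = err$n_sub, n_ins = err$n_ins, n_del = err$n_del
      )
    }
  }
  all <- purrr::list_rbind(rows)
  list(
    reads = tibble::tibble(read_id = all$read_id, sequence = all$sequence,
                           quality = strrep("I", nchar(all$sequence))),
    truth = dplyr::select(all, -"sequence")
  )
}

#' Write simulated reads as FASTQ and the truth manifest as TSV
#'
#' @param sim Result of [simulate_sample()] (or several bound together).
#' @param fastq_path Output FASTQ path.
#' @param truth_path Optional output TSV path for the ground truth.
#' @return `fastq_path`, invisibly.
#' @export
write_sim_fastq <- function(sim, fastq_path, truth_path = NULL) {
  seqs <- Biostrings::DNAStringSet(sim$reads$sequence)
  names(seqs) <- sim$reads$read_id
  qual <- Biostrings::BStringSet(sim$reads$quality)
  Biostrings::writeXStringSet(seqs, fastq_path, format = "fastq",
                              qualities = qual)
  if (!is.null(truth_path)) readr::write_tsv(sim$truth, truth_path)
  invisible(fastq_path)
}

#' Draw a random repeat structure with conventional AGG placement
#'
#' Builds a structure of the requested total length whose AGG
#' interruptions follow the common 5' building-block layout: units of 9
#' or 10 CGGs each followed by one AGG, then an uninterrupted CGG tail.
#' When the requested AGG count does not fit the length it is reduced to
#' the largest feasible count. Consumes RNG state; seed outside.
#'
#' @param total_triplets Total repeat length (>= 2).
#' @param n_agg Requested number of AGG interruptions.
#' @return A [repeat_structure()].
#' @export
random_structure <- function(total_triplets, n_agg = 0L) {
  total_triplets <- as.integer(total_triplets)
  stopifnot(total_triplets >= 2L)
  n_agg <- min(as.integer(n_agg), (total_triplets - 1L) %/% 11L)
  n_agg <- max(n_agg, 0L)
  repeat {
    units <- if (n_agg > 0L) sample(9:10, n_agg, replace = TRUE) else integer()
    tail <- total_triplets - sum(units) - n_agg
    if (tail >= 1L) break
    n_agg <- n_agg - 1L
  }
  motifs <- c(rbind(rep("CGG", n_agg), rep("AGG", n_agg)), "CGG")
  counts <- c(rbind(units, rep(1L, n_agg)), tail)
  repeat_structure(tibble::tibble(motif = motifs, count = counts))
}
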