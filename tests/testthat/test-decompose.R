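anc <- default_anchors()

test_that("anchors are validated", {
  expect_error(anchor_config("ACGTACGT", anc$flank3), "12 nt")
  expect_error(anchor_config(paste0("ACGT", "CGGCGGCGG", "ACGT"), anc$flank3),
               "CGG")
  expect_error(anchor_config("ACGTNACGTACGTA", anc$flank3), "A/C/G/T")
})

test_that("the tract is located between the flanks on either strand", {
  tract <- expand_structure(parse_structure_notation("(CGG)9(AGG)1(CGG)12"))
  read <- paste0(anc$flank5, tract, anc$flank3)

  loc <- locate_repeat(read, anc)
  expect_equal(loc$status, "ok")
  expect_equal(loc$strand, "forward")
  expect_equal(nchar(loc$tract), 66L)
  expect_equal(loc$tract, tract)

  loc_rc <- locate_repeat(revcomp(read), anc)
  expect_equal(loc_rc$status, "ok")
  expect_equal(loc_rc$strand, "reverse")
  expect_equal(loc_rc$tract, tract)

  # anchors only: empty tract is returned, not an error
  loc0 <- locate_repeat(paste0(anc$flank5, anc$flank3), anc)
  expect_equal(loc0$status, "ok")
  expect_equal(nchar(loc0$tract), 0L)

  # missing 3' flank on both strands
  miss <- locate_repeat(paste0(anc$flank5, tract), anc)
  expect_equal(miss$status, "no_anchor")
})

test_that("frame selection maximizes the known-triplet fraction", {
  tract <- expand_structure(parse_structure_notation("(CGG)9(AGG)1(CGG)12"))
  fr <- select_frame(tract)
  expect_equal(fr$frame_offset, 0L)
  expect_equal(fr$canonical_fraction, 1)

  # exhaustive scoring oracle, independent of the implementation
  brute <- function(tr, known = c("CGG", "AGG", "CTG", "TGG")) {
    sapply(0:2, function(off) {
      k <- (nchar(tr) - off) %/% 3
      if (k < 1) return(-Inf)
      st <- off + 1 + 3 * (seq_len(k) - 1)
      mean(substring(tr, st, st + 2) %in% known)
    })
  }
  shifted <- paste0("G", tract)
  fr2 <- select_frame(shifted)
  expect_equal(fr2$canonical_fraction, max(brute(shifted)))
  expect_equal(fr2$canonical_fraction, 1)
  expect_equal(fr2$frame_offset, which.max(brute(shifted)) - 1L)

  set.seed(11)
  for (i in 1:20) {
    rnd <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    fr3 <- select_frame(rnd)
    expect_equal(fr3$canonical_fraction, max(brute(rnd)))
    expect_lt(fr3$canonical_fraction, 0.5)
  }
})

test_that("decomposition recovers block structures including non-canonical motifs", {
  f2 <- "(CGG)9(AGG)1(CGG)7(AGG)1(CGG)55"
  s <- decompose_sequence(expand_structure(parse_structure_notation(f2)), 0L)
  expect_equal(format_structure_notation(s), f2)
  expect_equal(s$total_triplets, 73L)
  expect_equal(s$agg_count, 2L)

  f10 <- "(CGG)7(CTG)1(CGG)1(AGG)1(CGG)9(AGG)1(CGG)25"
  s10 <- decompose_sequence(expand_structure(parse_structure_notation(f10)), 0L)
  expect_equal(s10$total_triplets, 45L)
  expect_equal(s10$agg_count, 2L)
  expect_equal(s10$noncanonical$motif, "CTG")

  s2 <- decompose_sequence("CGGCGG", 0L)
  expect_equal(s2$blocks$motif, "CGG")
  expect_equal(s2$blocks$count, 2L)

  # leftover bases are trimmed, not turned into blocks
  s3 <- decompose_sequence("ACGGCGGCG", 1L)
  expect_equal(s3$blocks$count, 2L)
  expect_equal(attr(s3, "trimmed"), c(left = 1L, right = 2L))
})

test_that("per-read QC gates pass/no_anchor/frameshifted/low_quality correctly", {
  f3p <- "(CGG)9(AGG)1(CGG)9(AGG)1(CGG)49"
  read <- make_read(f3p)
  cr <- call_read(read, anc, read_id = "clean")
  expect_equal(cr$qc_status, "pass")
  expect_equal(cr$total_triplets, 69L)
  expect_equal(cr$agg_count, 2L)
  expect_equal(cr$notation, f3p)

  expect_equal(call_read(paste0(anc$flank5, expand_structure(
    parse_structure_notation(f3p))), anc)$qc_status, "no_anchor")

  # single-base deletion at every tract position: a pass is never emitted
  # with canonical fraction below threshold, and pass lengths stay within
  # one triplet of truth
  tract <- expand_structure(parse_structure_notation(f3p))
  for (pos in seq_len(nchar(tract))) {
    mut <- paste0(substr(tract, 1, pos - 1),
                  substr(tract, pos + 1, nchar(tract)))
    cr <- call_read(paste0(anc$flank5, mut, anc$flank3), anc)
    if (cr$qc_status == "pass") {
      expect_gte(cr$canonical_fraction, 0.9)
      expect_lte(abs(cr$total_triplets - 69L), 1L)
    } else {
      expect_true(cr$qc_status %in% c("frameshifted", "low_quality"))
    }
  }
})

test_that("calls are strand-symmetric and round-trip on random canonical structures", {
  set.seed(12)
  for (i in 1:100) {
    len <- sample(10:120, 1)
    s <- random_structure(len, sample(0:3, 1))
    read <- make_read(s)
    cr <- call_read(read, anc, read_id = "f")
    expect_equal(cr$qc_status, "pass")
    expect_identical(cr$structure[[1]]$blocks, s$blocks)
    cr_rc <- call_read(revcomp(read), anc)
    expect_identical(cr_rc$notation, cr$notation)
    expect_equal(cr_rc$strand, "reverse")
  }
})
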