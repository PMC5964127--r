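anc <- default_anchors()

test_that("manifest validation enforces barcode distance and shape", {
  m <- barcode_manifest(data.frame(sample_id = c("A", "B", "C"),
                                   barcode = default_barcodes(3)))
  expect_s3_class(m, "barcode_manifest")

  expect_error(
    barcode_manifest(data.frame(sample_id = c("A", "B"),
                                barcode = c("ACGTACGTACGTACGT",
                                            "ACGTACGTACGTACGA")),
                     max_barcode_mismatches = 1),
    "mismatches apart"
  )
  expect_error(
    barcode_manifest(data.frame(sample_id = c("A", "B"),
                                barcode = c("ACGTACGT", "ACGTACGTACGT"))),
    "same length"
  )
})

test_that("reads demultiplex to the unique barcode within budget", {
  bcs <- default_barcodes(3)
  m <- barcode_manifest(data.frame(sample_id = c("A", "B", "C"), barcode = bcs))
  body <- make_read("(CGG)30", anchors = anc)

  exact <- tibble::tibble(read_id = "r1", sequence = paste0(bcs[1], body))
  expect_equal(demultiplex(exact, m)$sample_id, "A")

  # one barcode mismatch: assigned at budget 1, unassigned at budget 0
  bc_mut <- paste0("T", substr(bcs[1], 2, 16))
  stopifnot(substr(bcs[1], 1, 1) != "T")
  one_mm <- tibble::tibble(read_id = "r2", sequence = paste0(bc_mut, body))
  expect_equal(demultiplex(one_mm, m)$sample_id, "A")
  m0 <- barcode_manifest(data.frame(sample_id = c("A", "B", "C"),
                                    barcode = bcs),
                         max_barcode_mismatches = 0)
  expect_true(is.na(demultiplex(one_mm, m0)$sample_id))

  # reverse-strand reads are recognized, re-oriented and stripped
  rc_read <- tibble::tibble(read_id = "r3",
                            sequence = revcomp(paste0(bcs[2], body)))
  d <- demultiplex(rc_read, m)
  expect_equal(d$sample_id, "B")
  expect_equal(d$sequence, body)
})

test_that("an error-free pool splits exactly by sample", {
  bcs <- default_barcodes(3)
  m <- barcode_manifest(data.frame(sample_id = paste0("S", 1:3), barcode = bcs))
  pool <- purrr::list_rbind(purrr::map(1:3, function(k) {
    cfg <- sim_config(alleles = c("(CGG)9(AGG)1(CGG)12", "(CGG)69"),
                      coverage_per_allele = 15, p_sub = 0, p_ins = 0,
                      p_del = 0, barcode = bcs[k], seed = 100 + k)
    simulate_sample(cfg, paste0("S", k))$reads
  }))
  set.seed(1); pool <- pool[sample.int(nrow(pool)), ]
  d <- demultiplex(pool, m)
  expect_equal(unname(table(d$sample_id)[paste0("S", 1:3)]),
               rep(30L, 3), ignore_attr = TRUE)
  expect_equal(sum(is.na(d$sample_id)), 0L)
})

test_that("length clustering splits two alleles and respects its guards", {
  calls22 <- call_reads(reads_for("(CGG)9(AGG)1(CGG)12", 50), anc)
  calls69 <- call_reads(reads_for("(CGG)69", 50), anc)
  two <- cluster_reads(dplyr::bind_rows(calls22, calls69))
  expect_equal(unname(table(two$cluster)), c(50L, 50L), ignore_attr = TRUE)
  expect_true(all(two$total_triplets[two$cluster == 1] == 22))

  one <- cluster_reads(call_reads(reads_for("(CGG)30", 60), anc))
  expect_true(all(one$cluster == 1L))

  expect_error(cluster_reads(calls22[1:5, ]),
               class = "aggcall_insufficient_coverage")
})

test_that("equal-length alleles with different AGG patterns split on structure", {
  a <- "(CGG)9(AGG)1(CGG)20"
  b <- "(CGG)30"
  calls <- call_reads(dplyr::bind_rows(reads_for(a, 25), reads_for(b, 25)), anc)
  cl <- cluster_reads(calls)
  expect_equal(sort(unique(cl$cluster)), c(1L, 2L))
  expect_equal(unname(table(cl$cluster)), c(25L, 25L), ignore_attr = TRUE)
  # cluster 1 is the lexicographically smaller notation at equal length
  expect_true(all(cl$notation[cl$cluster == 1] == b))
})

test_that("consensus is modal, tie-broken deterministically, permutation-invariant", {
  f4 <- "(CGG)9(AGG)1(CGG)9(AGG)1(CGG)69"
  clean <- call_reads(reads_for(f4, 35), anc)
  deviant <- call_reads(reads_for("(CGG)9(AGG)1(CGG)9(AGG)1(CGG)68", 5), anc)
  cons <- consensus_structure(dplyr::bind_rows(clean, deviant))
  expect_equal(cons$notation, f4)
  expect_equal(cons$total_triplets, 89L)
  expect_equal(cons$agg_count, 2L)
  expect_equal(cons$n_supporting_reads, 35L)
  expect_equal(cons$length_spread, 1L)

  # exact 20/20 tie: output must not depend on read order
  tie <- dplyr::bind_rows(call_reads(reads_for("(CGG)40", 20), anc),
                          call_reads(reads_for("(CGG)9(AGG)1(CGG)30", 20), anc))
  ref <- consensus_structure(tie)
  set.seed(33)
  for (i in 1:5) {
    perm <- tie[sample.int(nrow(tie)), ]
    expect_identical(consensus_structure(perm)$notation, ref$notation)
  }
})

test_that("a two-premutation female phases into both published structures", {
  f2a <- "(CGG)9(AGG)1(CGG)9(AGG)1(CGG)45"
  f2b <- "(CGG)9(AGG)1(CGG)7(AGG)1(CGG)55"
  cfg <- sim_config(alleles = c(f2a, f2b), coverage_per_allele = 40, seed = 1)
  sim <- simulate_sample(cfg, "female2")
  sc <- call_sample(sim$reads, "female2")
  expect_equal(nrow(sc$alleles), 2L)
  expect_equal(sc$alleles$notation, c(f2a, f2b))
  expect_equal(sc$alleles$total_triplets, c(65L, 73L))
  expect_equal(sc$alleles$allele_class, rep("premutation", 2))
  expect_equal(sc$zygosity_note, "two_alleles")
  # the consensus support ratio is reported per allele for auditability
  expect_true(all(sc$alleles$support_ratio > 0 & sc$alleles$support_ratio <= 1))
  expect_true(all(sc$alleles$n_supporting_reads <= sc$alleles$cluster_size))
})

test_that("homozygous-looking samples are flagged, not resolved", {
  cfg <- sim_config(alleles = c("(CGG)9(AGG)1(CGG)20", "(CGG)9(AGG)1(CGG)20"),
                    coverage_per_allele = 15, p_sub = 0, p_ins = 0, p_del = 0,
                    seed = 5)
  sc <- call_sample(simulate_sample(cfg, "hom")$reads, "hom")
  expect_equal(nrow(sc$alleles), 1L)
  expect_equal(sc$zygosity_note, "single_cluster_possible_homozygote")
})

test_that("error-free two-allele samples are recovered exactly when resolvable", {
  set.seed(77)
  for (i in 1:10) {
    l1 <- sample(20:90, 1)
    l2 <- l1 + sample(2:30, 1)
    s1 <- random_structure(l1, sample(0:2, 1))
    s2 <- random_structure(l2, sample(0:2, 1))
    cfg <- sim_config(alleles = c(format_structure_notation(s1),
                                  format_structure_notation(s2)),
                      coverage_per_allele = 12, p_sub = 0, p_ins = 0,
                      p_del = 0, seed = 1000 + i)
    sc <- call_sample(simulate_sample(cfg, "det")$reads, "det")
    expect_equal(sc$alleles$notation,
                 c(format_structure_notation(s1), format_structure_notation(s2)))
  }
})

test_that("sample calls are independent of read order", {
  cfg <- sim_config(alleles = c("(CGG)9(AGG)1(CGG)12", "(CGG)69"),
                    coverage_per_allele = 20, seed = 9)
  sim <- simulate_sample(cfg, "perm")
  ref <- call_sample(sim$reads, "perm")
  set.seed(8)
  shuf <- sim$reads[sample.int(nrow(sim$reads)), ]
  sc <- call_sample(shuf, "perm")
  expect_identical(sc$alleles$notation, ref$alleles$notation)
  expect_identical(sc$alleles$n_supporting_reads, ref$alleles$n_supporting_reads)
})
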