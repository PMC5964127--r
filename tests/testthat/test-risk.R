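test_that("the shipped anchor table loads with all invariants", {
  tab <- default_risk_table()
  expect_s3_class(tab, "risk_table")
  expect_equal(nrow(tab), 8L)
  expect_true(all(tab$risk_percent >= 0 & tab$risk_percent <= 100))
  expect_true(grepl("approximate", tab$source[tab$length_min == 80]))
})

test_that("invalid tables are rejected with offending entries named", {
  expect_error(
    risk_table(data.frame(length_min = c(70, 75), length_max = c(70, 75),
                          agg_count = 2, risk_percent = c(15, 12))),
    "non-decreasing with length"
  )
  expect_error(
    risk_table(data.frame(length_min = c(60, 65), length_max = c(66, 70),
                          agg_count = 0, risk_percent = c(10, 20))),
    "overlapping"
  )
  expect_error(
    risk_table(data.frame(length_min = 70, length_max = 70,
                          agg_count = 0, risk_percent = 120)),
    "\\[0, 100\\]"
  )
  # more AGGs must never raise the risk at the same length
  expect_error(
    risk_table(data.frame(length_min = c(70, 70), length_max = c(74, 74),
                          agg_count = c(0, 2), risk_percent = c(10, 40))),
    "non-increasing in AGG"
  )
})

test_that("an empty table is valid and every query is not-available", {
  empty <- risk_table(data.frame(length_min = integer(), length_max = integer(),
                                 agg_count = integer(),
                                 risk_percent = numeric()))
  est <- estimate_expansion_risk(75, 2, empty)
  expect_equal(est$status, "not_available")
  expect_null(est$nearest_bounds)
})

test_that("random monotone tables load; random violations are caught", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    lo <- sort(sample(55:180, n))
    hi <- pmin(lo + sample(0:3, n, replace = TRUE), c(lo[-1] - 1L, 200L))
    risks <- sort(stats::runif(n, 0, 100))
    tab <- risk_table(data.frame(length_min = lo, length_max = hi,
                                 agg_count = 1L, risk_percent = risks))
    expect_s3_class(tab, "risk_table")
    if (n >= 2 && risks[1] < risks[n]) {
      expect_error(risk_table(data.frame(length_min = lo, length_max = hi,
                                         agg_count = 1L,
                                         risk_percent = rev(risks))),
                   "non-decreasing")
    }
  }
})

test_that("estimates return matched risks with counseling categories", {
  expect_equal(estimate_expansion_risk(75, 2)$risk_percent, 12)
  e69 <- estimate_expansion_risk(69, 0)
  expect_equal(e69$risk_percent, 22.9)
  expect_equal(e69$category, "high")
  e69b <- estimate_expansion_risk(69, 2)
  expect_equal(e69b$risk_percent, 0.5)
  expect_equal(e69b$category, "low")
  expect_equal(estimate_expansion_risk(75, 2)$category, "moderate")
})

test_that("unlisted cells return not-available with bracketing anchors", {
  est <- estimate_expansion_risk(72, 2)
  expect_equal(est$status, "not_available")
  expect_true(is.na(est$risk_percent))
  expect_equal(est$nearest_bounds$length_min[est$nearest_bounds$bound == "lower"], 69L)
  expect_equal(est$nearest_bounds$length_min[est$nearest_bounds$bound == "upper"], 75L)
})

test_that("normal and full-mutation alleles are not-applicable", {
  expect_equal(estimate_expansion_risk(30, 2)$status, "not_applicable")
  expect_equal(estimate_expansion_risk(230, 0)$status, "not_applicable")
  # intermediate alleles are eligible (even if no anchor matches)
  expect_equal(estimate_expansion_risk(49, 1)$status, "not_available")
})

test_that("estimates are pure functions of their inputs", {
  a <- estimate_expansion_risk(75, 0)
  b <- estimate_expansion_risk(75, 0)
  expect_identical(a[names(a) != "matched_entry"], b[names(b) != "matched_entry"])
  expect_equal(a$risk_percent, b$risk_percent)
})

test_that("prioritization selects the lower-risk allele", {
  p <- prioritize_alleles(c(65, 2), c(73, 2))
  expect_equal(p$selected, "a")
  expect_equal(p$total_triplets, 65L)
  expect_equal(p$basis, "length_agg")  # neither 65 nor 73 has a 2-AGG anchor

  p2 <- prioritize_alleles(c(75, 0), c(75, 2))
  expect_equal(p2$selected, "b")
  expect_equal(p2$basis, "risk")       # 77% vs 12%

  p3 <- prioritize_alleles(c(69, 2), c(69, 2))
  expect_true(p3$tie)
})
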