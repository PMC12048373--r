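make_eval_scene <- function() {
  # four baseline lesions: a true pair, a mismatch, a dropout, a false positive
  baseline <- make_lesions(rbind(c(0, 0, 0), c(40, 0, 0), c(80, 0, 0), c(120, 0, 0)),
                           ids = c("B1", "B2", "B3", "B4"),
                           true_ids = c("T7", "T9", "T5", NA))
  followup <- make_lesions(rbind(c(1, 0, 0), c(41, 0, 0)),
                           ids = c("F1", "F2"),
                           true_ids = c("T7", "T8"))
  truth <- c(T7 = "T7", T9 = "T9", T5 = "T5", T8 = "T8")
  list(baseline = baseline, followup = followup, truth = truth)
}

test_that("outcome classification covers all four root causes", {
  sc <- make_eval_scene()
  matches <- structure(list(
    pairs = data.frame(baseline_id = c("B1", "B2"),
                       followup_id = c("F1", "F2"),
                       distance_mm = c(1, 1), stringsAsFactors = FALSE),
    unmatched_baseline = c("B3", "B4"), unmatched_followup = character(0),
    threshold_mm = 15), class = "match_result")
  oc <- classify_outcomes(sc$baseline, sc$followup, matches, sc$truth)
  expect_equal(oc$outcome[oc$lesion_id == "B1"], "correct_match")
  expect_equal(oc$outcome[oc$lesion_id == "B2"], "incorrect_assignment")
  expect_equal(oc$outcome[oc$lesion_id == "B3"], "missed_matching")
  expect_equal(oc$outcome[oc$lesion_id == "B4"], "false_positive_detection")
  expect_equal(oc$followup_detected, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("disappeared nodules are excluded before classification", {
  sc <- make_eval_scene()
  truth <- sc$truth; truth["T5"] <- "disappeared"
  matches <- pair_nodules(sc$baseline, sc$followup)
  oc <- classify_outcomes(sc$baseline, sc$followup, matches, truth)
  expect_false("B3" %in% oc$lesion_id)
  expect_equal(nrow(oc), 3L)
})

test_that("a match to an unknown follow-up lesion is rejected", {
  sc <- make_eval_scene()
  matches <- structure(list(
    pairs = data.frame(baseline_id = "B1", followup_id = "F99",
                       distance_mm = 1, stringsAsFactors = FALSE),
    unmatched_baseline = character(0), unmatched_followup = character(0),
    threshold_mm = 15), class = "match_result")
  expect_error(classify_outcomes(sc$baseline, sc$followup, matches, sc$truth),
               "inconsistent match result")
})

test_that("compute_rates reproduces both denominators and flags empty ones", {
  oc <- data.frame(
    case_id = rep(c("c1", "c2"), each = 5),
    lesion_id = sprintf("L%d", 1:10),
    outcome = c(rep("correct_match", 4), "false_positive_detection",
                rep("correct_match", 2), "missed_matching",
                "missed_matching", "incorrect_assignment"),
    localization = "parenchymal", count_bin = NA_character_,
    stringsAsFactors = FALSE)
  oc$followup_detected <- oc$outcome %in% c("correct_match", "incorrect_assignment")
  tb <- compute_rates(oc)
  expect_equal(tb$overall_rate$value, 6 / 9)
  expect_equal(tb$conditional_rate$value, 6 / 7)
  expect_equal(tb$false_positive_fraction$value, 1 / 10)
  expect_equal(tb$per_case_rates, c(c1 = 1, c2 = 2 / 5))
  # all-correct toy case: per-case rate 100%
  toy <- oc[oc$outcome == "correct_match" & oc$case_id == "c1", ]
  expect_equal(unname(compute_rates(toy)$per_case_rates), 1)
  # zero denominator is flagged, not NaN
  fp_only <- oc[oc$outcome == "false_positive_detection", ]
  tb2 <- compute_rates(fp_only)
  expect_false(tb2$overall_rate$defined)
  expect_true(is.na(tb2$overall_rate$value))
})

test_that("compute_rates is invariant under row permutation", {
  rc <- reference_cohort()
  set.seed(13)
  t1 <- compute_rates(rc$outcomes, rc$followup_detected)
  t2 <- compute_rates(rc$outcomes[sample(nrow(rc$outcomes)), ],
                      rc$followup_detected)
  expect_equal(t1$overall_rate, t2$overall_rate)
  expect_equal(t1$counts, t2$counts)
  expect_equal(t1$by_localization, t2$by_localization)
})

test_that("chi-square matches the closed-form oracle and its residuals square-sum to it", {
  set.seed(29)
  # trivial no-association table
  flat <- chi2_independence(matrix(10, 2, 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p_value, 1)
  expect_true(all(flat$pearson_residuals == 0))
  for (rep in 1:25) {
    tab <- matrix(sample(1:20, 6, replace = TRUE), 3, 2)
    res <- suppressWarnings(chi2_independence(tab))
    expect_equal(res$chi2, oracle_chi2(tab), tolerance = 1e-10)
    expect_equal(sum(res$pearson_residuals^2), res$chi2, tolerance = 1e-9)
    expect_equal(res$df, 2)
    expect_equal(res$p_value, pchisq(res$chi2, 2, lower.tail = FALSE))
    expect_equal(res$expected,
                 outer(rowSums(tab), colSums(tab)) / sum(tab),
                 ignore_attr = TRUE)
  }
  expect_error(chi2_independence(rbind(c(0, 0), c(1, 2))), "degenerate")
  expect_error(chi2_independence(matrix(1, 1, 2)), "degenerate")
})

test_that("Mann-Whitney agrees with exhaustive enumeration and handles modes", {
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty group")
  # identical samples: no separation
  same <- mann_whitney_u(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9), mode = "asymptotic")
  expect_gte(same$p_value, 0.99)
  # frozen exact case: complete separation of 3 vs 3
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)   # 2/20 arrangements
  expect_equal(r$method, "exact")
  set.seed(37)
  for (rep in 1:10) {
    a <- runif(sample(3:8, 1)); b <- runif(sample(3:8, 1))
    got <- mann_whitney_u(a, b)
    orc <- oracle_mwu_exact(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$U, orc$U)
    expect_equal(got$p_value, orc$p_value, tolerance = 1e-12)
  }
  # exact and asymptotic agree closely at n = 8 vs 8
  for (rep in 1:5) {
    a <- runif(8); b <- runif(8)
    pe <- mann_whitney_u(a, b, mode = "exact")$p_value
    pa <- mann_whitney_u(a, b, mode = "asymptotic")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("stratification reproduces the reference localization analysis", {
  rc <- reference_cohort()
  s <- suppressWarnings(stratify(rc$outcomes, "localization"))
  expect_equal(unname(s$observed_binary[, "correct"]), c(504, 292, 136, 32))
  expect_equal(unname(s$observed_binary[, "incorrect"]), c(45, 54, 29, 13))
  expect_equal(s$rates$rate, c(504 / 549, 292 / 346, 136 / 165, 32 / 45))
  expect_lt(s$chi2_binary$p_value, 0.001)
  # false positives excluded from localization strata
  expect_equal(sum(s$observed_binary), 1105)
  # residual export is tidy and complete
  expect_equal(nrow(s$residuals), nrow(s$observed_rootcause) *
                 ncol(s$observed_rootcause))
  expect_error(stratify(rc$outcomes, "count_bin"), "invalid stratum")
})

test_that("single-lesion-per-stratum all-correct table has zero residuals", {
  oc <- data.frame(case_id = "c", lesion_id = c("a", "b"),
                   outcome = "correct_match",
                   localization = c("parenchymal", "peripheral"),
                   count_bin = NA_character_, followup_detected = TRUE,
                   stringsAsFactors = FALSE)
  s <- stratify(oc, "localization")
  expect_null(s$chi2_rootcause)   # a single outcome column: no association test
  expect_equal(s$rates$rate[1:2], c(1, 1))
})
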