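#' Classify per-lesion matching outcomes against ground truth
#'
#' Assigns each selected baseline lesion exactly one outcome from the study's
#' root-cause taxonomy:
#' \describe{
#'   \item{false_positive_detection}{the baseline detection is not a true
#'     nodule (`true_lesion_id` missing) — a non-nodular structure wrongly
#'     registered as a nodule.}
#'   \item{correct_match}{the accepted pair links the lesion to its true
#'     counterpart at follow-up.}
#'   \item{incorrect_assignment}{the accepted pair links it to a different
#'     nodule than its true counterpart.}
#'   \item{missed_matching}{a true nodule, still present at follow-up, with
#'     no accepted pair (counterpart undetected or outside the distance
#'     threshold).}
#' }
#' Lesions whose truth link is `"disappeared"` (truly vanished at follow-up)
#' are excluded before classification.
#'
#' @param selected_baseline data frame of the selected baseline lesions.
#' @param followup_detections data frame of follow-up detections.
#' @param matches `match_result` from [pair_nodules()].
#' @param truth_links named character vector mapping each baseline
#'   `true_lesion_id` to its follow-up true id, or `"disappeared"`.
#' @param count_bin optional per-exam nodule-count bin label attached to
#'   every outcome record (`"<20"`, `"20-50"`, `">50"`, or `NA`).
#' @return Data frame of outcome records: `case_id`, `lesion_id`, `outcome`,
#'   `localization`, `count_bin`, and `followup_detected` (was the true
#'   counterpart among the follow-up detections?).
#' @export
classify_outcomes <- function(selected_baseline, followup_detections, matches,
                              truth_links, count_bin = NA_character_) {
  stopifnot(inherits(matches, "match_result"))
  if (NROW(selected_baseline) == 0L)
    return(data.frame(case_id = character(0), lesion_id = character(0),
                      outcome = character(0), localization = character(0),
                      count_bin = character(0), followup_detected = logical(0),
                      stringsAsFactors = FALSE))
  fu_ids <- as.character(followup_detections$lesion_id)
  bad <- setdiff(matches$pairs$followup_id, fu_ids)
  if (length(bad) > 0L)
    stop("inconsistent match result: matched follow-up lesion(s) absent from detections: ",
         paste(bad, collapse = ", "))
  fu_true <- stats::setNames(as.character(followup_detections$true_lesion_id), fu_ids)
  pair_of <- stats::setNames(as.character(matches$pairs$followup_id),
                             as.character(matches$pairs$baseline_id))

  lookup <- function(map, key) {
    if (!is.na(key) && key %in% names(map)) map[[key]] else NULL
  }
  out <- lapply(seq_len(nrow(selected_baseline)), function(i) {
    row <- selected_baseline[i, ]
    tid <- row$true_lesion_id
    if (!is.na(tid) && identical(lookup(truth_links, tid), "disappeared"))
      return(NULL)
    partner <- lookup(pair_of, as.character(row$lesion_id))
    outcome <-
      if (is.na(tid)) "false_positive_detection"
      else if (is.null(partner)) "missed_matching"
      else {
        linked <- lookup(truth_links, tid)
        if (is.null(linked)) linked <- tid
        pt <- fu_true[[partner]]
        if (!is.na(pt) && identical(pt, linked)) "correct_match"
        else "incorrect_assignment"
      }
    data.frame(case_id = row$case_id, lesion_id = row$lesion_id,
               outcome = outcome, localization = row$localization,
               count_bin = count_bin,
               followup_detected = !is.na(tid) && tid %in% fu_true,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(case_id = character(0), lesion_id = character(0),
                      outcome = character(0), localization = character(0),
                      count_bin = character(0), followup_detected = logical(0),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

outcome_levels <- c("correct_match", "missed_matching",
                    "incorrect_assignment", "false_positive_detection")

#' Aggregate matching outcomes into rate tables
#'
#' Computes the study's headline quantities from per-lesion outcome records:
#' \itemize{
#'   \item overall matching rate = correct / (total lesions - false
#'     positives), i.e. correct among true nodules;
#'   \item conditional matching rate = correct / number of lesions whose
#'     true counterpart was detected at follow-up (both-scans denominator);
#'   \item per-case rates (correct / evaluated true nodules within each
#'     case) with their median and IQR;
#'   \item outcome counts overall and cross-tabulated by localization and by
#'     nodule-count bin.
#' }
#' A rate with a zero denominator is reported as `NA` with its `defined`
#' flag set to `FALSE`, never as silent `NaN`.
#'
#' @param outcomes outcome data frame from [classify_outcomes()] (rows from
#'   several cases may be concatenated).
#' @param followup_detected optional character vector of baseline lesion ids
#'   whose true counterpart was detected at follow-up; by default taken from
#'   the `followup_detected` column.
#' @return Object of class `outcome_table`.
#' @export
compute_rates <- function(outcomes, followup_detected = NULL) {
  stopifnot(NROW(outcomes) > 0L)
  oc <- factor(outcomes$outcome, levels = outcome_levels)
  if (anyNA(oc)) stop("unknown outcome category")
  counts <- table(oc)
  n_total <- nrow(outcomes)
  n_fp <- sum(oc == "false_positive_detection")
  n_correct <- sum(oc == "correct_match")
  n_nodules <- n_total - n_fp
  if (is.null(followup_detected))
    followup_detected <- outcomes$lesion_id[outcomes$followup_detected]
  n_detected_both <- length(unique(followup_detected))

  rate <- function(num, den) {
    if (den > 0) list(value = num / den, numerator = num, denominator = den,
                      defined = TRUE)
    else list(value = NA_real_, numerator = num, denominator = den,
              defined = FALSE)
  }

  per_case <- vapply(split(as.character(oc), outcomes$case_id), function(x) {
    x <- x[x != "false_positive_detection"]
    if (length(x) == 0L) NA_real_ else mean(x == "correct_match")
  }, numeric(1))
  per_case <- per_case[!is.na(per_case)]

  structure(list(
    counts = counts,
    by_localization = table(localization = outcomes$localization, outcome = oc),
    by_count_bin = table(count_bin = factor(outcomes$count_bin,
                                            levels = c("<20", "20-50", ">50")),
                         outcome = oc),
    overall_rate = rate(n_correct, n_nodules),
    conditional_rate = rate(n_correct, n_detected_both),
    false_positive_fraction = rate(n_fp, n_total),
    missed_fraction = rate(sum(oc == "missed_matching"), n_nodules),
    incorrect_fraction = rate(sum(oc == "incorrect_assignment"), n_nodules),
    not_matched_fraction = rate(n_nodules - n_correct, n_nodules),
    per_case_rates = per_case,
    per_case_median = if (length(per_case)) stats::median(per_case) else NA_real_,
    per_case_iqr = if (length(per_case))
      stats::quantile(per_case, c(0.25, 0.75), names = FALSE) else c(NA_real_, NA_real_)
  ), class = "outcome_table")
}

#' @export
print.outcome_table <- function(x, ...) {
  fmt <- function(r) if (r$defined)
    sprintf("%.1f%% (%d/%d)", 100 * r$value, r$numerator, r$denominator)
  else "undefined (zero denominator)"
  cat("<outcome_table>\n")
  cat("  lesions evaluated:   ", sum(x$counts), "\n")
  cat("  overall rate:        ", fmt(x$overall_rate), "\n")
  cat("  conditional rate:    ", fmt(x$conditional_rate), "\n")
  cat("  false positives:     ", fmt(x$false_positive_fraction), "\n")
  cat("  missed matching:     ", fmt(x$missed_fraction), "\n")
  cat("  incorrect assignment:", fmt(x$incorrect_fraction), "\n")
  if (length(x$per_case_rates))
    cat(sprintf("  per-case rate: median %.1f%% (IQR %.1f-%.1f%%), n = %d\n",
                100 * x$per_case_median, 100 * x$per_case_iqr[1],
                100 * x$per_case_iqr[2], length(x$per_case_rates)))
  invisible(x)
}

#' Chi-square test of independence with Pearson residuals
#'
#' Pearson chi-square on an r x c contingency table, without continuity
#' correction, with expected cells from the row/column margins and the
#' per-cell Pearson residuals (O - E) / sqrt(E) whose squares sum to the
#' statistic. Warns when any expected cell is below 5.
#'
#' @param observed numeric matrix of non-negative counts, at least 2 x 2.
#' @return Object of class `contingency_result`: list with `observed`,
#'   `expected`, `chi2`, `df`, `p_value`, `pearson_residuals`.
#' @examples
#' chi2_independence(rbind(c(504, 45), c(292, 54), c(136, 29), c(32, 13)))
#' @export
chi2_independence <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || !all(is.finite(observed)))
    stop("observed counts must be finite and non-negative")
  if (nrow(observed) < 2L || ncol(observed) < 2L)
    stop("degenerate table: need at least 2 rows and 2 columns")
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    stop("degenerate table: zero row or column margin")
  ht <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  if (any(ht$expected < 5))
    warning("some expected cell counts are below 5; chi-square approximation may be poor")
  structure(list(observed = observed,
                 expected = ht$expected,
                 chi2 = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value,
                 pearson_residuals = ht$residuals),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> chi2 = %.3f, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Mann-Whitney U test between two groups of per-case rates
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. In `"auto"` mode the
#' exact null distribution is enumerated when the smaller group has at most
#' 8 observations and there are no ties; otherwise the normal approximation
#' with tie correction is used.
#'
#' @param group_a,group_b numeric vectors, each non-empty.
#' @param mode `"auto"`, `"exact"`, or `"asymptotic"`.
#' @return List with `U` (the U statistic for `group_a`), `p_value`
#'   (two-sided), and `method`.
#' @export
mann_whitney_u <- function(group_a, group_b,
                           mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("empty group")
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  exact <- switch(mode,
                  auto = min(length(group_a), length(group_b)) <= 8L && !ties,
                  exact = TRUE,
                  asymptotic = FALSE)
  if (exact && ties)
    stop("exact mode requires data without ties")
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact,
                       correct = !exact, alternative = "two.sided"))
  list(U = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "asymptotic")
}

#' Stratified outcome tables and association statistics
#'
#' Builds the observed contingency tables relating a stratifier (nodule
#' localization, or per-exam nodule-count bin) to matching outcome, both as
#' the binary correct-versus-incorrect table and as the full root-cause
#' table, runs the chi-square analysis on each, and reports per-stratum
#' correct-matching rates. For localization strata false-positive detections
#' are excluded (localization describes true nodules); for count-bin strata
#' they are kept as their own root-cause column.
#'
#' @param outcomes outcome data frame from [classify_outcomes()].
#' @param by `"localization"` or `"count_bin"`.
#' @param include_false_positives override the stratifier-specific default.
#' @return List with `observed_binary`, `observed_rootcause`, `rates`
#'   (per-stratum correct rate with denominators), `chi2_binary`,
#'   `chi2_rootcause`, and `residuals` (tidy data frame of Pearson residuals
#'   and expected counts for association plots).
#' @export
stratify <- function(outcomes, by = c("localization", "count_bin"),
                     include_false_positives = NULL) {
  by <- match.arg(by)
  if (is.null(include_false_positives))
    include_false_positives <- (by == "count_bin")
  strata <- outcomes[[by]]
  if (anyNA(strata))
    stop("invalid stratum: missing ", by, " labels")
  known <- if (by == "localization")
    c("parenchymal", "peripheral", "juxtavascular", "juxtaphrenic")
  else c("<20", "20-50", ">50")
  if (!all(strata %in% known))
    stop("invalid stratum: ", paste(setdiff(strata, known), collapse = ", "))
  dat <- outcomes
  if (!include_false_positives)
    dat <- dat[dat$outcome != "false_positive_detection", , drop = FALSE]
  sf <- factor(dat[[by]], levels = known)
  oc <- factor(dat$outcome, levels = outcome_levels)

  observed_rootcause <- table(stratum = sf, outcome = oc)
  observed_rootcause <- observed_rootcause[, colSums(observed_rootcause) > 0,
                                           drop = FALSE]
  binary <- cbind(correct = tapply(oc == "correct_match", sf, sum, default = 0),
                  incorrect = tapply(oc != "correct_match", sf, sum, default = 0))
  keep <- rowSums(binary) > 0
  binary <- binary[keep, , drop = FALSE]

  denom <- tapply(dat$outcome != "false_positive_detection", sf, sum, default = 0)
  corr <- tapply(dat$outcome == "correct_match", sf, sum, default = 0)
  rates <- data.frame(stratum = known,
                      correct = as.integer(corr),
                      evaluated = as.integer(denom),
                      rate = ifelse(denom > 0, corr / denom, NA_real_),
                      stringsAsFactors = FALSE)

  chi2_binary <- if (nrow(binary) >= 2L && all(colSums(binary) > 0))
    chi2_independence(binary) else NULL
  chi2_rootcause <- if (nrow(binary) >= 2L && ncol(observed_rootcause) >= 2L)
    chi2_independence(observed_rootcause[keep, , drop = FALSE]) else NULL

  residuals <- NULL
  if (!is.null(chi2_rootcause)) {
    r <- chi2_rootcause$pearson_residuals
    residuals <- data.frame(stratum = rep(rownames(r), ncol(r)),
                            outcome = rep(colnames(r), each = nrow(r)),
                            observed = as.vector(chi2_rootcause$observed),
                            expected = as.vector(chi2_rootcause$expected),
                            pearson_residual = as.vector(r),
                            stringsAsFactors = FALSE)
  }
  list(observed_binary = binary,
       observed_rootcause = observed_rootcause,
       rates = rates,
       chi2_binary = chi2_binary,
       chi2_rootcause = chi2_rootcause,
       residuals = residuals)
}
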