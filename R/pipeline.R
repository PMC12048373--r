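#' Run options for the matching pipeline
#'
#' Collects the tunable constants of the pipeline; the defaults are the
#' study's operating point: a 15 mm match threshold, the ten largest baseline
#' lesions between 5 and 30 mm, a 10 mm peripheral pleura margin, and the
#' trimmed-ICP registration settings.
#'
#' @param threshold_mm match-distance cutoff (strict; default 15).
#' @param top_k maximum baseline lesions evaluated per pair (default 10).
#' @param d_min_mm,d_max_mm inclusive diameter window (defaults 5, 30).
#' @param pleura_margin_mm peripheral-localization margin (default 10).
#' @param icp list of options forwarded to [icp_affine_register()].
#' @return Object of class `run_config` (a list).
#' @export
run_config <- function(threshold_mm = 15, top_k = 10L,
                       d_min_mm = 5, d_max_mm = 30,
                       pleura_margin_mm = 10,
                       icp = list(max_iter = 100L, rms_tol_mm = 1e-6,
                                  trim_fraction = 0.1, use_labels = FALSE)) {
  stopifnot(threshold_mm > 0, top_k >= 1, d_min_mm > 0, d_min_mm < d_max_mm)
  structure(as.list(environment()), class = "run_config")
}

#' Register, match and score one baseline/follow-up pair
#'
#' Runs the full per-pair pipeline: ICP affine registration of the landmark
#' sets, target-lesion selection at baseline, mapping of the selected
#' centroids into the follow-up frame, distance-threshold pairing, and (when
#' ground truth is available) per-lesion outcome classification.
#'
#' @param pair `case_pair` (from [generate_study()]), or any list with the
#'   same fields.
#' @param config `run_config`.
#' @return List with `transform`, `diagnostics`, `selected` (baseline lesions
#'   evaluated), `matches` (`match_result`), and `outcomes` (data frame, or
#'   `NULL` when the pair carries no truth links).
#' @export
run_case_pair <- function(pair, config = run_config()) {
  reg <- do.call(icp_affine_register,
                 c(list(moving = pair$baseline_landmarks,
                        fixed = pair$followup_landmarks), config$icp))
  selected <- select_target_lesions(pair$baseline_lesions, k = config$top_k,
                                    d_min_mm = config$d_min_mm,
                                    d_max_mm = config$d_max_mm)
  sel_coreg <- selected
  if (nrow(selected) > 0L) {
    mapped <- apply_affine(reg$transform,
                           as.matrix(selected[, c("x_mm", "y_mm", "z_mm")]))
    sel_coreg[, c("x_mm", "y_mm", "z_mm")] <- mapped
  }
  matches <- pair_nodules(sel_coreg, pair$followup_lesions,
                          threshold_mm = config$threshold_mm)
  outcomes <- NULL
  if (!is.null(pair$truth_links)) {
    outcomes <- classify_outcomes(selected, pair$followup_lesions, matches,
                                  pair$truth_links,
                                  count_bin = if (!is.null(pair$count_bin))
                                    pair$count_bin else NA_character_)
    if (nrow(outcomes) > 0L && !is.null(pair$pair_id))
      outcomes$case_id <- pair$pair_id    # the follow-up pair is the rate unit
  }
  list(transform = reg$transform, diagnostics = reg$diagnostics,
       selected = selected, matches = matches, outcomes = outcomes)
}

#' Evaluate a whole study end to end
#'
#' Applies [run_case_pair()] to every pair and aggregates the per-lesion
#' outcomes into an [compute_rates()] outcome table plus localization and
#' count-bin stratifications.
#'
#' @param pairs list of `case_pair` objects.
#' @param config `run_config`.
#' @return List with `outcomes` (pooled data frame), `table`
#'   (`outcome_table`), `by_localization`, `by_count_bin` (stratified
#'   results from [stratify()]), and `runs` (per-pair pipeline outputs).
#' @export
evaluate_study <- function(pairs, config = run_config()) {
  runs <- lapply(pairs, run_case_pair, config = config)
  outcomes <- do.call(rbind, lapply(runs, `[[`, "outcomes"))
  if (is.null(outcomes) || nrow(outcomes) == 0L)
    stop("no evaluable lesions in the study")
  list(outcomes = outcomes,
       table = compute_rates(outcomes),
       by_localization = stratify(outcomes, "localization"),
       by_count_bin = if (!anyNA(outcomes$count_bin))
         stratify(outcomes, "count_bin") else NULL,
       runs = runs)
}

#' Reference cohort outcome fixture
#'
#' Per-lesion outcome records encoding the headline tabulation of a large
#' clinical follow-up cohort: 1,141 evaluated lesions over 153 follow-up
#' examinations, of which 36 were false-positive detections and 1,105 true
#' nodules (549 parenchymal, 346 peripheral, 165 juxtavascular, 45
#' juxtaphrenic; 504/292/136/32 of these correctly matched, 119 missed, 22
#' incorrectly assigned). The reported marginals fix the correct/incorrect
#' split per localization and the overall missed/incorrect totals; the
#' per-localization split between missed matching and incorrect assignment
#' is not determined by them, so this fixture uses an illustrative
#' allocation consistent with the qualitative finding that missed matching
#' is over-represented in juxtavascular and incorrect assignment in
#' juxtaphrenic nodules. Count-bin labels are `NA` (per-exam counts are not
#' reconstructible). Marginal rates computed from this fixture are exact.
#'
#' @return List with `outcomes` (1,141-row outcome data frame) and
#'   `followup_detected` (lesion ids whose counterpart was present in both
#'   scans: the 964 + 22 = 986 both-scans denominator).
#' @export
reference_cohort <- function() {
  spec <- rbind(
    data.frame(localization = "parenchymal",   outcome = "correct_match",        n = 504),
    data.frame(localization = "parenchymal",   outcome = "missed_matching",      n = 39),
    data.frame(localization = "parenchymal",   outcome = "incorrect_assignment", n = 6),
    data.frame(localization = "peripheral",    outcome = "correct_match",        n = 292),
    data.frame(localization = "peripheral",    outcome = "missed_matching",      n = 46),
    data.frame(localization = "peripheral",    outcome = "incorrect_assignment", n = 8),
    data.frame(localization = "juxtavascular", outcome = "correct_match",        n = 136),
    data.frame(localization = "juxtavascular", outcome = "missed_matching",      n = 27),
    data.frame(localization = "juxtavascular", outcome = "incorrect_assignment", n = 2),
    data.frame(localization = "juxtaphrenic",  outcome = "correct_match",        n = 32),
    data.frame(localization = "juxtaphrenic",  outcome = "missed_matching",      n = 7),
    data.frame(localization = "juxtaphrenic",  outcome = "incorrect_assignment", n = 6),
    data.frame(localization = "peripheral",    outcome = "false_positive_detection", n = 36))
  outcomes <- data.frame(
    case_id = "cohort",
    lesion_id = sprintf("L%04d", seq_len(sum(spec$n))),
    outcome = rep(spec$outcome, spec$n),
    localization = rep(spec$localization, spec$n),
    count_bin = NA_character_,
    stringsAsFactors = FALSE)
  # counterpart present in both scans: every correct match or incorrect
  # assignment (missed lesions were not registered at follow-up)
  outcomes$followup_detected <-
    outcomes$outcome %in% c("correct_match", "incorrect_assignment")
  list(outcomes = outcomes,
       followup_detected = outcomes$lesion_id[outcomes$followup_detected])
}
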