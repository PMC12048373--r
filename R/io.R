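#' Lesion-table schema
#'
#' The required columns of a lesion CSV: one row per detected lesion, with
#' millimetre centroid coordinates in the patient frame and an optional
#' ground-truth link (`true_lesion_id` empty = false positive / unknown).
#' Additional columns are preserved on round trip.
#'
#' @return Character vector of required column names.
#' @export
lesion_table_columns <- function() {
  c("case_id", "exam_id", "lesion_id", "x_mm", "y_mm", "z_mm",
    "diameter_mm", "localization", "texture", "true_lesion_id")
}

#' Read and write lesion tables
#'
#' Comma-separated, UTF-8, header required, `.` decimal. `read_lesion_table`
#' validates the schema: a missing required column raises an error naming it;
#' a malformed number raises a row-level error with the offending line.
#' Unknown columns pass through untouched.
#'
#' @param path file path.
#' @param lesions data frame with at least [lesion_table_columns()].
#' @return `read_lesion_table`: data frame of nodule records.
#' @export
read_lesion_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(lesion_table_columns(), names(df))
  if (length(missing) > 0L)
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("x_mm", "y_mm", "z_mm", "diameter_mm")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("", "NA")))
    if (length(bad) > 0L)
      stop("malformed number in column '", col, "' at data row ", bad[1],
           " (line ", bad[1] + 1L, "): '", df[[col]][bad[1]], "'")
    df[[col]] <- v
  }
  df$true_lesion_id[df$true_lesion_id == ""] <- NA_character_
  df
}

#' @rdname read_lesion_table
#' @export
write_lesion_table <- function(lesions, path) {
  missing <- setdiff(lesion_table_columns(), names(lesions))
  if (length(missing) > 0L)
    stop("schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  utils::write.csv(lesions, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write landmark sets
#'
#' Landmark files are JSON, one object per exam:
#' `{"exam_id": ..., "landmarks": [{"label", "x_mm", "y_mm", "z_mm"}, ...]}`.
#'
#' @param path file path.
#' @param ps `point_set`.
#' @return `read_landmarks`: a `point_set`.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lm <- obj$landmarks
  if (is.null(lm) || NROW(lm) == 0L)
    return(point_set(matrix(numeric(0), 0, 3), exam_id = obj$exam_id))
  labels <- if (!is.null(lm$label) && !all(is.na(lm$label))) lm$label else NULL
  point_set(cbind(lm$x_mm, lm$y_mm, lm$z_mm), labels = labels,
            exam_id = obj$exam_id)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(ps, path) {
  stopifnot(inherits(ps, "point_set"))
  labels <- attr(ps, "labels")
  lm <- data.frame(label = if (is.null(labels)) rep(NA_character_, nrow(ps)) else labels,
                   x_mm = ps[, 1], y_mm = ps[, 2], z_mm = ps[, 3],
                   stringsAsFactors = FALSE)
  jsonlite::write_json(list(exam_id = attr(ps, "exam_id"), landmarks = lm),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Serialize transforms and match results
#'
#' The transform JSON stores the 3x3 linear part row-major plus the
#' translation, with an explicit `"frame": "baseline_to_followup"` field to
#' remove direction ambiguity. Match results mirror the `match_result`
#' structure.
#'
#' @param transform `affine_transform`.
#' @param match `match_result`.
#' @param path file path.
#' @return the read-back object, for the `read_*` forms.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "affine_transform"))
  jsonlite::write_json(list(frame = "baseline_to_followup",
                            linear_row_major = as.vector(t(transform$linear)),
                            translation_mm = transform$translation,
                            is_plausible = transform$is_plausible),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  affine_transform(matrix(obj$linear_row_major, 3, 3, byrow = TRUE),
                   obj$translation_mm)
}

#' @rdname write_transform
#' @export
write_match_result <- function(match, path) {
  stopifnot(inherits(match, "match_result"))
  jsonlite::write_json(list(threshold_mm = match$threshold_mm,
                            pairs = match$pairs,
                            unmatched_baseline = match$unmatched_baseline,
                            unmatched_followup = match$unmatched_followup),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_match_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pairs <- obj$pairs
  if (NROW(pairs) == 0L)
    pairs <- data.frame(baseline_id = character(0), followup_id = character(0),
                        distance_mm = numeric(0), stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 unmatched_baseline = as.character(obj$unmatched_baseline),
                 unmatched_followup = as.character(obj$unmatched_followup),
                 threshold_mm = obj$threshold_mm),
            class = "match_result")
}

#' Write an outcome report
#'
#' Serializes the pooled outcome table, the stratified analyses, and the
#' resolved configuration (provenance) as JSON, plus a tidy CSV of Pearson
#' residuals for association plots.
#'
#' @param evaluation result of [evaluate_study()].
#' @param config the `run_config` used.
#' @param path output JSON path; the residual CSV is written next to it with
#'   suffix `_residuals.csv`.
#' @param seed seed to record for provenance.
#' @return `path`, invisibly.
#' @export
write_outcome_report <- function(evaluation, config, path, seed = NULL) {
  tb <- evaluation$table
  strat_out <- function(s) if (is.null(s)) NULL else list(
    rates = s$rates,
    chi2_binary = if (!is.null(s$chi2_binary))
      list(chi2 = s$chi2_binary$chi2, df = s$chi2_binary$df,
           p_value = s$chi2_binary$p_value) else NULL,
    chi2_rootcause = if (!is.null(s$chi2_rootcause))
      list(chi2 = s$chi2_rootcause$chi2, df = s$chi2_rootcause$df,
           p_value = s$chi2_rootcause$p_value) else NULL)
  report <- list(
    config = unclass(config), seed = seed,
    n_lesions = sum(tb$counts),
    counts = as.list(tb$counts),
    overall_rate = tb$overall_rate,
    conditional_rate = tb$conditional_rate,
    false_positive_fraction = tb$false_positive_fraction,
    missed_fraction = tb$missed_fraction,
    incorrect_fraction = tb$incorrect_fraction,
    per_case_median = tb$per_case_median,
    per_case_iqr = tb$per_case_iqr,
    by_localization = strat_out(evaluation$by_localization),
    by_count_bin = strat_out(evaluation$by_count_bin))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  res <- rbind(
    if (!is.null(evaluation$by_localization$residuals))
      cbind(stratifier = "localization", evaluation$by_localization$residuals),
    if (!is.null(evaluation$by_count_bin$residuals))
      cbind(stratifier = "count_bin", evaluation$by_count_bin$residuals))
  if (!is.null(res))
    utils::write.csv(res, sub("\\.json$", "_residuals.csv", path),
                     row.names = FALSE)
  invisible(path)
}
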