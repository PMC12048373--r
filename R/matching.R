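#' Select the target lesions of a baseline exam
#'
#' Applies the study's lesion-selection rule: among the baseline detections,
#' keep solid lesions whose diameter lies within the size window (inclusive
#' at both ends), then retain the `k` largest by diameter. Diameter ties at
#' the cut are broken by lexicographically smaller `lesion_id`, so selection
#' is deterministic. Exclusion of nodules that truly disappeared at follow-up
#' is a truth-dependent step applied later, by the evaluation module.
#'
#' @param baseline data frame of nodule records (see [lesion_table_columns()]).
#' @param k maximum number of lesions to keep (default 10).
#' @param d_min_mm,d_max_mm inclusive diameter window in mm (defaults 5, 30).
#' @return The selected subset of `baseline`, largest diameter first.
#' @export
select_target_lesions <- function(baseline, k = 10L, d_min_mm = 5, d_max_mm = 30) {
  stopifnot(k >= 1L, d_min_mm > 0, d_min_mm < d_max_mm)
  if (NROW(baseline) == 0L) return(baseline)
  elig <- baseline[baseline$diameter_mm >= d_min_mm &
                     baseline$diameter_mm <= d_max_mm &
                     baseline$texture == "solid", , drop = FALSE]
  if (NROW(elig) == 0L) return(elig)
  ord <- order(-elig$diameter_mm, elig$lesion_id, method = "radix")
  out <- elig[ord[seq_len(min(k, nrow(elig)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair nodules across co-registered exams under a distance threshold
#'
#' Computes all baseline-to-follow-up Euclidean centroid distances in the
#' common (follow-up) frame and admits candidate pairs strictly below
#' `threshold_mm`. One-to-one assignment is enforced greedily in ascending
#' distance order; distance ties are broken by (baseline id, follow-up id)
#' lexicographic order so the result is independent of input row order. In
#' the clinical operating regime, where nodule spacing is large relative to
#' the residual registration error, this greedy pairing coincides with the
#' assignment that maximizes the number of pairs and minimizes total
#' distance.
#'
#' @param baseline_coreg data frame of baseline nodule records whose
#'   centroids have already been mapped through the registration transform.
#' @param followup data frame of follow-up nodule records.
#' @param threshold_mm distance cutoff in mm; a pair is a match only if its
#'   distance is strictly below this (default 15).
#' @return Object of class `match_result`: list with `pairs` (data frame with
#'   columns `baseline_id`, `followup_id`, `distance_mm`),
#'   `unmatched_baseline`, `unmatched_followup` (character vectors of lesion
#'   ids) and `threshold_mm`.
#' @export
pair_nodules <- function(baseline_coreg, followup, threshold_mm = 15) {
  stopifnot(threshold_mm > 0)
  bid <- as.character(if (NROW(baseline_coreg)) baseline_coreg$lesion_id else character(0))
  fid <- as.character(if (NROW(followup)) followup$lesion_id else character(0))
  empty <- data.frame(baseline_id = character(0), followup_id = character(0),
                      distance_mm = numeric(0), stringsAsFactors = FALSE)
  if (length(bid) == 0L || length(fid) == 0L) {
    return(structure(list(pairs = empty,
                          unmatched_baseline = bid,
                          unmatched_followup = fid,
                          threshold_mm = threshold_mm),
                     class = "match_result"))
  }
  B <- as.matrix(baseline_coreg[, c("x_mm", "y_mm", "z_mm")])
  F <- as.matrix(followup[, c("x_mm", "y_mm", "z_mm")])
  tF <- t(F)
  d <- t(vapply(seq_len(nrow(B)),
                function(i) sqrt(colSums((tF - B[i, ])^2)),
                numeric(nrow(F))))
  if (nrow(F) == 1L) d <- matrix(d, ncol = 1L)
  cand <- which(d < threshold_mm, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(structure(list(pairs = empty,
                          unmatched_baseline = bid,
                          unmatched_followup = fid,
                          threshold_mm = threshold_mm),
                     class = "match_result"))
  }
  dist_c <- d[cand]
  ord <- order(dist_c, bid[cand[, 1]], fid[cand[, 2]], method = "radix")
  cand <- cand[ord, , drop = FALSE]
  dist_c <- dist_c[ord]
  used_b <- logical(nrow(B)); used_f <- logical(nrow(F))
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    bi <- cand[i, 1]; fi <- cand[i, 2]
    if (!used_b[bi] && !used_f[fi]) {
      used_b[bi] <- TRUE; used_f[fi] <- TRUE
      sel <- c(sel, i)
    }
  }
  pairs <- data.frame(baseline_id = bid[cand[sel, 1]],
                      followup_id = fid[cand[sel, 2]],
                      distance_mm = dist_c[sel],
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 unmatched_baseline = bid[!used_b],
                 unmatched_followup = fid[!used_f],
                 threshold_mm = threshold_mm),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pairs (< %.1f mm), %d baseline / %d follow-up unmatched\n",
              nrow(x$pairs), x$threshold_mm,
              length(x$unmatched_baseline), length(x$unmatched_followup)))
  invisible(x)
}
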