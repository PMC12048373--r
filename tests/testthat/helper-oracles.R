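# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: brute-force enumeration and closed-form formulas only.

# Optimal one-to-one pairing under a distance threshold: maximize the number
# of pairs, then minimize total distance, by exhaustive recursion over the
# candidate edges. Returns a data frame (baseline index, followup index,
# distance) sorted by baseline index. Feasible for <= ~6 lesions per side
# with sparse candidates.
oracle_assignment <- function(B, F, threshold) {
  nb <- nrow(B); nf <- nrow(F)
  if (nb == 0L || nf == 0L)
    return(data.frame(bi = integer(0), fi = integer(0), d = numeric(0)))
  d <- as.matrix(stats::dist(rbind(B, F)))[seq_len(nb), nb + seq_len(nf), drop = FALSE]
  best <- list(count = -1L, total = Inf, pairs = NULL)
  recurse <- function(bi, used_f, pairs, total) {
    if (bi > nb) {
      cnt <- nrow(pairs)
      if (cnt > best$count || (cnt == best$count && total < best$total - 1e-12))
        best <<- list(count = cnt, total = total, pairs = pairs)
      return(invisible(NULL))
    }
    # leave bi unmatched
    recurse(bi + 1L, used_f, pairs, total)
    for (fi in seq_len(nf)) {
      if (!used_f[fi] && d[bi, fi] < threshold) {
        used_f[fi] <- TRUE
        recurse(bi + 1L, used_f,
                rbind(pairs, data.frame(bi = bi, fi = fi, d = d[bi, fi])),
                total + d[bi, fi])
        used_f[fi] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nf),
          data.frame(bi = integer(0), fi = integer(0), d = numeric(0)), 0)
  p <- best$pairs
  if (is.null(p) || nrow(p) == 0L)
    return(data.frame(bi = integer(0), fi = integer(0), d = numeric(0)))
  p[order(p$bi), , drop = FALSE]
}

# Closed-form Pearson chi-square statistic from a count table.
oracle_chi2 <- function(observed) {
  E <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  sum((observed - E)^2 / E)
}

# Exact two-sided Mann-Whitney p by full enumeration of the
# choose(n+m, n) rank arrangements (no ties).
oracle_mwu_exact <- function(a, b) {
  n <- length(a); m <- length(b)
  ranks <- rank(c(a, b))
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_all <- apply(combos, 2L, function(idx) sum(idx) - n * (n + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = u_obs, p_value = min(1, p))
}

# Random invertible affine within the study's jitter ranges.
random_affine <- function(rot_deg = 10, scale = c(0.95, 1.05), trans_mm = 20) {
  angle <- runif(1, 0, rot_deg) * pi / 180
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  affine_transform(runif(1, scale[1], scale[2]) * R,
                   runif(3, -trans_mm, trans_mm))
}

# Minimal lesion data frame for matching tests.
make_lesions <- function(xyz, ids = NULL, diameter = 10, texture = "solid",
                         localization = "parenchymal", true_ids = NULL,
                         case_id = "caseA", exam_id = "exam1") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(ids)) ids <- sprintf("N%02d", seq_len(n))
  data.frame(case_id = rep(case_id, n), exam_id = rep(exam_id, n),
             lesion_id = ids,
             x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
             diameter_mm = rep_len(diameter, n),
             localization = rep_len(localization, n),
             texture = rep_len(texture, n),
             true_lesion_id = if (is.null(true_ids)) rep(NA_character_, n) else true_ids,
             stringsAsFactors = FALSE)
}
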