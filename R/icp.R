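#' Affine co-registration of landmark point sets by iterative closest point
#'
#' Estimates the affine transform mapping the `moving` exam's landmarks onto
#' the `fixed` exam's, by alternating exact nearest-neighbor correspondence
#' with a least-squares affine fit until the trimmed RMS correspondence
#' distance stabilizes. Designed for anatomical landmark sets (tens of
#' points), where the exam-to-exam deformation is well approximated by a
#' single affine map; no image intensities are used.
#'
#' Initialization translates the moving centroid onto the fixed centroid with
#' an identity linear part. Correspondence is exact nearest neighbor in the
#' fixed set (ties broken by the lower fixed-point index, for determinism);
#' with `trim_fraction` f > 0 the `ceiling(f * n)` worst correspondences are
#' excluded from each fit, which tolerates landmarks missing or spurious in
#' one exam. When `use_labels = TRUE` and both sets carry labels,
#' correspondence is by shared label and the procedure reduces to a single
#' affine fit.
#'
#' @param moving,fixed `point_set`s (or n x 3 matrices) with at least 4
#'   points each.
#' @param max_iter maximum number of ICP iterations.
#' @param rms_tol_mm convergence tolerance on the change in trimmed RMS (mm).
#' @param trim_fraction fraction of worst correspondences discarded from each
#'   fit, in [0, 0.5); 0 disables trimming.
#' @param use_labels use label-based correspondence when both sets are
#'   labeled.
#' @return A list with elements `transform` (`affine_transform`, moving to
#'   fixed frame) and `diagnostics`: a list with `iterations`, `rms_history`
#'   (trimmed RMS per iteration, mm), `converged`, and `trimmed_fraction`.
#' @examples
#' pts <- matrix(runif(120, -80, 80), ncol = 3)
#' fit <- icp_affine_register(pts + 10, pts, trim_fraction = 0)
#' fit$diagnostics$converged
#' @export
icp_affine_register <- function(moving, fixed,
                                max_iter = 100L,
                                rms_tol_mm = 1e-6,
                                trim_fraction = 0.1,
                                use_labels = FALSE) {
  M <- as_point_matrix(moving)
  F <- as_point_matrix(fixed)
  if (nrow(M) < 4L || nrow(F) < 4L)
    stop("insufficient landmarks: at least 4 points per exam are required")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must be in [0, 0.5)")

  if (use_labels) {
    ml <- attr(moving, "labels"); fl <- attr(fixed, "labels")
    if (is.null(ml) || is.null(fl))
      stop("use_labels requires labeled point sets")
    shared <- intersect(ml, fl)
    if (length(shared) < 4L)
      stop("insufficient landmarks: fewer than 4 shared labels")
    pairs <- cbind(match(shared, ml), match(shared, fl))
    tr <- fit_affine(M, F, pairs)
    return(list(transform = tr,
                diagnostics = list(iterations = 1L,
                                   rms_history = attr(tr, "rms_mm"),
                                   converged = TRUE,
                                   trimmed_fraction = 0)))
  }

  n <- nrow(M)
  n_keep <- n - ceiling(trim_fraction * n)
  if (n_keep < 4L)
    stop("insufficient landmarks after trimming")

  tr <- affine_transform(diag(3), colMeans(F) - colMeans(M))
  rms_history <- numeric(0)
  converged <- FALSE
  initial_rms <- NA_real_

  for (iter in seq_len(max_iter)) {
    Mt <- apply_affine(tr, M)
    # exact nearest neighbor; which.min takes the lowest index on ties
    d2 <- outer(rowSums(Mt^2), rep(1, nrow(F))) +
      outer(rep(1, n), rowSums(F^2)) - 2 * Mt %*% t(F)
    nn <- apply(d2, 1L, which.min)
    nn_d2 <- pmax(d2[cbind(seq_len(n), nn)], 0)
    keep <- order(nn_d2)[seq_len(n_keep)]
    if (is.na(initial_rms)) initial_rms <- sqrt(mean(nn_d2[keep]))

    tr_new <- fit_affine(M, F, cbind(keep, nn[keep]))
    rms <- attr(tr_new, "rms_mm")
    rms_history <- c(rms_history, rms)
    tr <- tr_new

    if (initial_rms > 0 && rms > 10 * initial_rms)
      stop("registration failed: RMS diverged")
    if (iter > 1L &&
        abs(rms_history[iter - 1L] - rms) < rms_tol_mm) {
      converged <- TRUE
      break
    }
    if (iter == 1L && rms < rms_tol_mm) {   # already aligned
      converged <- TRUE
      break
    }
  }

  list(transform = tr,
       diagnostics = list(iterations = length(rms_history),
                          rms_history = rms_history,
                          converged = converged,
                          trimmed_fraction = trim_fraction))
}
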