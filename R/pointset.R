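#' Construct a labeled 3-D point set
#'
#' A point set holds the anatomical landmark coordinates (or any other labeled
#' 3-D points) of one exam, in millimetres in a fixed right-handed patient
#' frame. Labels, when given, must be unique so that label-based
#' correspondence is well defined.
#'
#' @param points numeric matrix with 3 columns (x, y, z in mm), or anything
#'   coercible to one; zero rows are allowed.
#' @param labels optional character vector of per-point landmark names, one
#'   per row, all distinct.
#' @param exam_id optional exam identifier carried along for provenance.
#' @return An object of class `point_set`: the coordinate matrix with
#'   `labels` and `exam_id` attributes.
#' @examples
#' ps <- point_set(matrix(rnorm(30), ncol = 3), exam_id = "ex1")
#' nrow(ps)
#' @export
point_set <- function(points, labels = NULL, exam_id = NULL) {
  pts <- as.matrix(points)
  if (length(pts) == 0L) pts <- matrix(numeric(0), ncol = 3)
  if (ncol(pts) != 3L)
    stop("points must have 3 columns (x, y, z in mm)")
  storage.mode(pts) <- "double"
  if (!all(is.finite(pts)))
    stop("invalid coordinates: all coordinates must be finite")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(pts))
      stop("labels must match the number of points")
    if (anyDuplicated(labels))
      stop("labels must be unique")
  }
  structure(pts,
            labels = labels,
            exam_id = exam_id,
            class = c("point_set", "matrix", "array"))
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %d points (mm)%s%s\n", nrow(x),
              if (!is.null(attr(x, "exam_id"))) paste0(", exam ", attr(x, "exam_id")) else "",
              if (!is.null(attr(x, "labels"))) ", labeled" else ""))
  invisible(x)
}

as_point_matrix <- function(x) {
  if (inherits(x, "point_set")) {
    m <- unclass(x)
    attr(m, "labels") <- NULL
    attr(m, "exam_id") <- NULL
    return(m)
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Construct an affine transform
#'
#' Represents the map `p -> linear %*% p + translation` taking baseline
#' coordinates into the follow-up frame. The transform is flagged plausible
#' when its linear part has positive determinant, i.e. it preserves anatomical
#' orientation (no mirroring).
#'
#' @param linear 3x3 numeric matrix (dimensionless).
#' @param translation numeric 3-vector (mm).
#' @return Object of class `affine_transform` with elements `linear`,
#'   `translation` and `is_plausible`.
#' @examples
#' identity_transform()
#' @export
affine_transform <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- matrix(as.numeric(linear), 3, 3)
  translation <- as.numeric(translation)
  if (length(translation) != 3L)
    stop("translation must be a 3-vector")
  if (!all(is.finite(linear)) || !all(is.finite(translation)))
    stop("invalid transform: entries must be finite")
  structure(list(linear = linear,
                 translation = translation,
                 is_plausible = det(linear) > 0),
            class = "affine_transform")
}

#' @rdname affine_transform
#' @export
identity_transform <- function() affine_transform()

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform> det =", format(det(x$linear), digits = 4),
      if (x$is_plausible) "(orientation-preserving)" else "(NOT orientation-preserving)", "\n")
  cat("linear:\n"); print(round(x$linear, 6))
  cat("translation (mm):", format(round(x$translation, 4)), "\n")
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param transform `affine_transform`.
#' @param pts `point_set` or n x 3 matrix.
#' @return Same type as `pts`, with labels and exam id preserved.
#' @export
apply_affine <- function(transform, pts) {
  stopifnot(inherits(transform, "affine_transform"))
  m <- as_point_matrix(pts)
  out <- m %*% t(transform$linear)
  if (nrow(m) > 0L)
    out <- out + matrix(transform$translation, nrow(m), 3, byrow = TRUE)
  if (!all(is.finite(out)))
    stop("invalid transform: non-finite coordinates produced")
  if (inherits(pts, "point_set"))
    return(point_set(out, labels = attr(pts, "labels"),
                     exam_id = attr(pts, "exam_id")))
  out
}

#' Invert an affine transform
#'
#' @param transform `affine_transform` with an invertible linear part.
#' @return The inverse `affine_transform`.
#' @export
invert_affine <- function(transform) {
  stopifnot(inherits(transform, "affine_transform"))
  Ainv <- solve(transform$linear)
  affine_transform(Ainv, -Ainv %*% transform$translation)
}

#' Compose two affine transforms
#'
#' Returns the transform applying `first`, then `second`
#' (`compose_affine(second, first)(p) == second(first(p))`).
#'
#' @param second,first `affine_transform` objects.
#' @return The composed `affine_transform`.
#' @export
compose_affine <- function(second, first) {
  stopifnot(inherits(second, "affine_transform"), inherits(first, "affine_transform"))
  affine_transform(second$linear %*% first$linear,
                   second$linear %*% first$translation + second$translation)
}

#' Least-squares affine fit to paired points
#'
#' Finds the affine transform minimizing the sum of squared distances between
#' transformed source points and their paired destination points. This is the
#' inner solver of the iterative-closest-point registration. The normal
#' problem is solved by QR; if the paired source points are affinely dependent
#' (coplanar or fewer than 4 distinct), the minimum-norm least-squares
#' solution is returned and the result carries attribute
#' `rank_deficient = TRUE`.
#'
#' @param src,dst `point_set`s or n x 3 matrices in mm.
#' @param pairs two-column integer matrix of (source row, destination row)
#'   correspondences; `NULL` means row i pairs with row i.
#' @return `affine_transform`, with attributes `rank_deficient` (logical) and
#'   `rms_mm` (root-mean-square residual of the fit).
#' @examples
#' src <- matrix(rnorm(30, sd = 50), ncol = 3)
#' fit <- fit_affine(src, src + 5)
#' fit$translation
#' @export
fit_affine <- function(src, dst, pairs = NULL) {
  S <- as_point_matrix(src)
  D <- as_point_matrix(dst)
  if (is.null(pairs)) {
    if (nrow(S) != nrow(D))
      stop("src and dst differ in size; supply explicit pairs")
    pairs <- cbind(seq_len(nrow(S)), seq_len(nrow(S)))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs) < 4L)
    stop("insufficient correspondences: at least 4 pairs are required")
  X <- S[pairs[, 1], , drop = FALSE]
  Y <- D[pairs[, 2], , drop = FALSE]
  if (!all(is.finite(X)) || !all(is.finite(Y)))
    stop("invalid coordinates: non-finite input")
  Xh <- cbind(X, 1)                      # n x 4 homogeneous design
  qrx <- qr(Xh)
  if (qrx$rank == 4L) {
    B <- qr.coef(qrx, Y)                 # 4 x 3
    rank_deficient <- FALSE
  } else {
    # minimum-norm solution via the pseudoinverse
    sv <- svd(Xh)
    pos <- sv$d > max(sv$d) * 1e-10
    B <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% Y) / sv$d[pos])
    rank_deficient <- TRUE
  }
  tr <- affine_transform(t(B[1:3, , drop = FALSE]), B[4, ])
  res <- Xh %*% B - Y
  attr(tr, "rank_deficient") <- rank_deficient
  attr(tr, "rms_mm") <- sqrt(mean(rowSums(res^2)))
  tr
}
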