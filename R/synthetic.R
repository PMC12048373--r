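#' Configuration of the synthetic paired-exam simulator
#'
#' Bundles every knob of the synthetic-thorax study generator. Defaults
#' emulate the structure of a clinical follow-up cohort: about 100 cases with
#' roughly half contributing a second follow-up pair (~153 pairs), per-exam
#' nodule counts drawn from a three-regime mixture (<20 / 20-50 / >50), a
#' localization mix of 49.7% parenchymal / 31.3% peripheral / 14.9%
#' juxtavascular / 4.1% juxtaphrenic, and diameters from a log-normal
#' truncated to 5-30 mm whose truncated median is 9.0 mm with IQR
#' 7.1-11.7 mm.
#'
#' @param n_cases number of cases.
#' @param second_followup_prob probability a case contributes a second
#'   follow-up pair (cases with three serial exams).
#' @param nodules_per_case either a single count (fixed), or a list
#'   `list(probs=, ranges=)` giving regime probabilities and inclusive count
#'   ranges; default is the <20 / 20-50 / >50 mixture with weights
#'   0.608/0.203/0.190.
#' @param localization_mix named probabilities over
#'   parenchymal/peripheral/juxtavascular/juxtaphrenic, summing to 1.
#' @param diameter_meanlog,diameter_sdlog log-normal parameters of the
#'   diameter distribution before truncation to `diameter_range`.
#' @param diameter_range inclusive truncation window (mm).
#' @param subsolid_prob probability a true nodule is subsolid or mixed
#'   (excluded by target-lesion selection).
#' @param n_landmarks anatomical landmarks per exam.
#' @param affine_jitter list with `rot_deg` (max rotation), `scale`
#'   (isotropic scale range) and `trans_mm` (max per-axis translation) for
#'   the random exam-to-exam affine.
#' @param diaphragm_shift_mm magnitude of the nonrigid caudal displacement at
#'   the diaphragm surface (respiratory-phase difference between exams).
#' @param shift_decay_mm exponential decay length of that displacement with
#'   distance from the diaphragm.
#' @param residual_jitter_mm iid Gaussian noise (sd, per axis) on follow-up
#'   nodule centroids (detection/segmentation variability).
#' @param landmark_noise_mm iid Gaussian noise (sd, per axis) on follow-up
#'   landmark positions.
#' @param landmark_occlusion probability each landmark is undetected at
#'   follow-up (crowded or obscured anatomy).
#' @param dropout_prob probability a true nodule present at follow-up is not
#'   detected there.
#' @param fp_rate expected number of false-positive detections injected into
#'   each baseline exam (non-nodular structures).
#' @param disappear_prob probability a baseline nodule has truly vanished at
#'   follow-up (treatment response).
#' @param min_separation_mm minimum centre-to-centre spacing enforced between
#'   true nodules of one exam; 0 disables the constraint.
#' @param seed master random seed; per-pair streams are derived from it so
#'   individual pairs are reproducible.
#' @return Object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_cases = 100L,
                             second_followup_prob = 0.53,
                             nodules_per_case = list(
                               probs = c(0.608, 0.203, 0.190),
                               ranges = list(c(1L, 19L), c(20L, 50L), c(51L, 120L))),
                             localization_mix = c(parenchymal = 0.497,
                                                  peripheral = 0.313,
                                                  juxtavascular = 0.149,
                                                  juxtaphrenic = 0.041),
                             diameter_meanlog = 2.1502,
                             diameter_sdlog = 0.4128,
                             diameter_range = c(5, 30),
                             subsolid_prob = 0.05,
                             n_landmarks = 40L,
                             affine_jitter = list(rot_deg = 10, scale = c(0.95, 1.05),
                                                  trans_mm = 20),
                             diaphragm_shift_mm = 5,
                             shift_decay_mm = 40,
                             residual_jitter_mm = 1,
                             landmark_noise_mm = 1,
                             landmark_occlusion = 0.1,
                             dropout_prob = 0.09,
                             fp_rate = 0.25,
                             disappear_prob = 0.02,
                             min_separation_mm = 0,
                             seed = 1L) {
  probs <- c(second_followup_prob, subsolid_prob, landmark_occlusion,
             dropout_prob, disappear_prob)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (abs(sum(localization_mix) - 1) > 1e-8)
    stop("localization_mix must sum to 1")
  if (any(localization_mix < 0) || length(localization_mix) != 4L)
    stop("localization_mix needs 4 non-negative entries")
  mags <- c(diaphragm_shift_mm, shift_decay_mm, residual_jitter_mm,
            landmark_noise_mm, fp_rate, min_separation_mm)
  if (any(mags < 0)) stop("magnitudes must be >= 0")
  if (is.numeric(nodules_per_case) && length(nodules_per_case) == 1L)
    nodules_per_case <- list(probs = 1,
                             ranges = list(rep(as.integer(nodules_per_case), 2L)))
  structure(as.list(environment()), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> %d cases, seed %d, %d landmarks/exam\n",
              x$n_cases, x$seed, x$n_landmarks))
  invisible(x)
}

# run code with a temporary RNG state derived from `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# derived per-pair stream seed, kept within 32-bit integer range
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 1000003) %%
               2147483647)
}

## ---- stylized thorax geometry --------------------------------------------
## Two half-ellipsoid lungs over a Gaussian diaphragm dome, plus a stylized
## vessel tree of line segments from each hilum. Coordinates in mm:
## x lateral, y antero-posterior, z cranio-caudal (+z cranial).

#' Sample a stylized thorax geometry
#'
#' Builds the geometric scaffold used by the simulator: an ellipsoidal lung
#' per side, a diaphragm dome below each lung, and a vessel tree stylized as
#' line segments fanning out from the hilum. Only the distance queries
#' (pleura, diaphragm, nearest vessel) matter for localization semantics.
#'
#' @param n_vessel_segments vessel segments per lung.
#' @return Object of class `thorax_geometry`.
#' @export
sample_thorax_geometry <- function(n_vessel_segments = 8L) {
  lungs <- list(
    list(center = c(-85, 0, 10) + runif(3, -5, 5), semi = c(60, 90, 110) * runif(1, 0.95, 1.05)),
    list(center = c( 85, 0, 10) + runif(3, -5, 5), semi = c(60, 90, 110) * runif(1, 0.95, 1.05)))
  diaphragm <- list(base_z = -95 + runif(1, -5, 5),
                    height = 35 + runif(1, -5, 5),
                    width = 80)
  segs <- do.call(rbind, lapply(lungs, function(lg) {
    hilum <- lg$center + c(-sign(lg$center[1]) * lg$semi[1] * 0.7, 0, 0)
    t(vapply(seq_len(n_vessel_segments), function(i) {
      end <- sample_in_ellipsoid(lg$center, lg$semi * 0.85)
      c(hilum, end)
    }, numeric(6)))
  }))
  structure(list(lungs = lungs, diaphragm = diaphragm, vessels = segs),
            class = "thorax_geometry")
}

# uniform point in an ellipsoid
sample_in_ellipsoid <- function(center, semi) {
  u <- stats::rnorm(3)
  u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
  center + u * semi
}

diaphragm_height <- function(geom, x, y) {
  d <- geom$diaphragm
  h <- vapply(geom$lungs, function(lg) {
    r2 <- (x - lg$center[1])^2 + (y - lg$center[2])^2
    d$height * exp(-r2 / (2 * d$width^2))
  }, numeric(length(x)))
  d$base_z + if (is.matrix(h)) apply(h, 1L, max) else max(h)
}

#' Distance queries on a thorax geometry
#'
#' `dist_to_pleura` approximates the distance from a point to the lung
#' surface (radial approximation to the nearest ellipsoid);
#' `dist_to_diaphragm` is the vertical distance to the diaphragm dome;
#' `dist_to_vessel` the exact distance to the nearest vessel segment.
#'
#' @param geom `thorax_geometry`.
#' @param p numeric 3-vector (mm).
#' @return distance in mm (non-negative).
#' @export
dist_to_pleura <- function(geom, p) {
  min(vapply(geom$lungs, function(lg) {
    v <- p - lg$center
    rho <- sqrt(sum((v / lg$semi)^2))
    if (rho < 1e-9) return(min(lg$semi))
    sqrt(sum(v^2)) * abs(rho - 1) / rho
  }, numeric(1)))
}

#' @rdname dist_to_pleura
#' @export
dist_to_diaphragm <- function(geom, p) {
  abs(p[3] - diaphragm_height(geom, p[1], p[2]))
}

#' @rdname dist_to_pleura
#' @export
dist_to_vessel <- function(geom, p) {
  segs <- geom$vessels
  a <- segs[, 1:3, drop = FALSE]; b <- segs[, 4:6, drop = FALSE]
  ab <- b - a
  ap <- matrix(p, nrow(a), 3, byrow = TRUE) - a
  t <- rowSums(ap * ab) / pmax(rowSums(ab^2), 1e-12)
  t <- pmin(pmax(t, 0), 1)
  closest <- a + ab * t
  sqrt(min(rowSums((matrix(p, nrow(a), 3, byrow = TRUE) - closest)^2)))
}

inside_lung <- function(geom, p) {
  above <- p[3] >= diaphragm_height(geom, p[1], p[2])
  inside <- any(vapply(geom$lungs, function(lg)
    sum(((p - lg$center) / lg$semi)^2) <= 1, logical(1)))
  inside && above
}

#' Classify a nodule's localization from geometry
#'
#' Applies the study's localization taxonomy: peripheral means within
#' `pleura_margin_mm` of the pleura; juxtavascular and juxtaphrenic mean
#' directly adjacent (within `contact_tol_mm`) to a vessel and to the
#' diaphragm, respectively; everything else is parenchymal. Categories are
#' exclusive with precedence juxtaphrenic > juxtavascular > peripheral >
#' parenchymal (diaphragm contact is the rarest and most specific class).
#'
#' @param centroid numeric 3-vector (mm).
#' @param geometry `thorax_geometry`.
#' @param pleura_margin_mm peripheral margin (default 10 mm).
#' @param contact_tol_mm adjacency tolerance operationalizing "directly
#'   adjacent" (default 2 mm).
#' @return one of `"parenchymal"`, `"peripheral"`, `"juxtavascular"`,
#'   `"juxtaphrenic"`.
#' @export
classify_localization <- function(centroid, geometry,
                                  pleura_margin_mm = 10, contact_tol_mm = 2) {
  if (dist_to_diaphragm(geometry, centroid) <= contact_tol_mm) return("juxtaphrenic")
  if (dist_to_vessel(geometry, centroid) <= contact_tol_mm) return("juxtavascular")
  if (dist_to_pleura(geometry, centroid) <= pleura_margin_mm) return("peripheral")
  "parenchymal"
}

# rejection-sample one nodule centroid of the requested localization class
place_nodule <- function(geom, target, existing, min_sep,
                         pleura_margin_mm = 10, contact_tol_mm = 2,
                         max_tries = 400L) {
  for (i in seq_len(max_tries)) {
    lg <- geom$lungs[[sample.int(2L, 1L)]]
    p <- switch(target,
      parenchymal = sample_in_ellipsoid(lg$center, lg$semi * 0.97),
      peripheral = {
        v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
        t_surf <- 1 / sqrt(sum((v / lg$semi)^2))
        lg$center + v * t_surf - v * stats::runif(1, 0.5, pleura_margin_mm * 0.9)
      },
      juxtavascular = {
        segs <- geom$vessels
        s <- segs[sample.int(nrow(segs), 1L), ]
        along <- s[1:3] + (s[4:6] - s[1:3]) * stats::runif(1)
        dirn <- stats::rnorm(3); dirn <- dirn / sqrt(sum(dirn^2))
        along + dirn * stats::runif(1, 0, contact_tol_mm * 0.9)
      },
      juxtaphrenic = {
        q <- sample_in_ellipsoid(lg$center, lg$semi * 0.8)
        q[3] <- diaphragm_height(geom, q[1], q[2]) + stats::runif(1, 0, contact_tol_mm * 0.9)
        q
      },
      stop("invalid stratum: unknown localization '", target, "'"))
    if (!inside_lung(geom, p)) next
    if (classify_localization(p, geom, pleura_margin_mm, contact_tol_mm) != target) next
    if (min_sep > 0 && NROW(existing) > 0 &&
        min(sqrt(rowSums((existing - matrix(p, nrow(existing), 3, byrow = TRUE))^2))) < min_sep)
      next
    return(p)
  }
  stop("placement failed: could not place a ", target,
       " nodule after ", max_tries, " attempts")
}

# truncated log-normal diameters
sample_diameters <- function(n, meanlog, sdlog, range) {
  plo <- stats::plnorm(range[1], meanlog, sdlog)
  phi <- stats::plnorm(range[2], meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

# random affine within the jitter ranges: isotropic scale * rotation + shift
sample_affine_jitter <- function(jit) {
  angle <- stats::runif(1, 0, jit$rot_deg) * pi / 180
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  s <- stats::runif(1, jit$scale[1], jit$scale[2])
  affine_transform(s * R, stats::runif(3, -jit$trans_mm, jit$trans_mm))
}

# landmarks: pleural surface, vessel tree, and interior points
place_landmarks <- function(geom, n) {
  kinds <- sample(c("surface", "vessel", "interior"), n, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2))
  pts <- t(vapply(kinds, function(k) {
    lg <- geom$lungs[[sample.int(2L, 1L)]]
    if (k == "surface") {
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      lg$center + v / sqrt(sum((v / lg$semi)^2))
    } else if (k == "vessel") {
      s <- geom$vessels[sample.int(nrow(geom$vessels), 1L), ]
      s[1:3] + (s[4:6] - s[1:3]) * stats::runif(1)
    } else {
      sample_in_ellipsoid(lg$center, lg$semi * 0.9)
    }
  }, numeric(3)))
  point_set(pts, labels = sprintf("L%03d", seq_len(n)))
}

sample_nodule_count <- function(spec) {
  k <- sample.int(length(spec$probs), 1L, prob = spec$probs)
  r <- spec$ranges[[k]]
  if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1L)
}

count_bin <- function(n) {
  if (is.na(n)) NA_character_
  else if (n < 20) "<20" else if (n <= 50) "20-50" else ">50"
}

## ---- study generation ----------------------------------------------------

generate_case_pair <- function(pair_id, case_id, seed, cfg) {
  with_seed(seed, {
    geom <- sample_thorax_geometry()
    n_nod <- sample_nodule_count(cfg$nodules_per_case)
    locs <- sample(names(cfg$localization_mix), n_nod, replace = TRUE,
                   prob = cfg$localization_mix)
    centroids <- matrix(NA_real_, 0, 3)
    for (i in seq_len(n_nod)) {
      p <- place_nodule(geom, locs[i], centroids, cfg$min_separation_mm)
      centroids <- rbind(centroids, p)
    }
    diam <- sample_diameters(n_nod, cfg$diameter_meanlog, cfg$diameter_sdlog,
                             cfg$diameter_range)
    texture <- ifelse(stats::runif(n_nod) < cfg$subsolid_prob,
                      sample(c("subsolid", "mixed"), n_nod, replace = TRUE),
                      "solid")
    true_ids <- sprintf("%s_T%03d", pair_id, seq_len(n_nod))

    # baseline detections: every true nodule, plus injected false positives
    n_fp <- stats::rpois(1, cfg$fp_rate)
    fp_pts <- if (n_fp > 0)
      t(vapply(seq_len(n_fp), function(i) {
        lg <- geom$lungs[[sample.int(2L, 1L)]]
        v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
        lg$center + v / sqrt(sum((v / lg$semi)^2)) * stats::runif(1, 0.98, 1.08)
      }, numeric(3)))
    else matrix(numeric(0), 0, 3)
    fp_diam <- sample_diameters(n_fp, cfg$diameter_meanlog, cfg$diameter_sdlog,
                                cfg$diameter_range)
    all_pts <- rbind(centroids, fp_pts)
    n_b <- n_nod + n_fp
    baseline <- data.frame(
      case_id = case_id, pair_id = pair_id,
      exam_id = paste0(pair_id, "_BL"),
      lesion_id = sprintf("%s_B%03d", pair_id, seq_len(n_b)),
      x_mm = all_pts[, 1], y_mm = all_pts[, 2], z_mm = all_pts[, 3],
      diameter_mm = c(diam, fp_diam),
      localization = c(locs,
                       vapply(seq_len(n_fp), function(i)
                         classify_localization(fp_pts[i, ], geom), character(1))),
      texture = c(texture, rep("solid", n_fp)),
      true_lesion_id = c(true_ids, rep(NA_character_, n_fp)),
      stringsAsFactors = FALSE)

    # ground-truth motion: global affine + caudal diaphragm displacement
    true_tr <- sample_affine_jitter(cfg$affine_jitter)
    warp <- function(P) {
      Q <- apply_affine(true_tr, P)
      if (cfg$diaphragm_shift_mm > 0) {
        dd <- vapply(seq_len(nrow(P)), function(i)
          dist_to_diaphragm(geom, P[i, ]), numeric(1))
        Q[, 3] <- Q[, 3] - cfg$diaphragm_shift_mm * exp(-dd / cfg$shift_decay_mm)
      }
      Q
    }

    bl_lm <- place_landmarks(geom, cfg$n_landmarks)
    fu_lm_pts <- warp(as_point_matrix(bl_lm))
    if (cfg$landmark_noise_mm > 0)
      fu_lm_pts <- fu_lm_pts + matrix(stats::rnorm(length(fu_lm_pts), 0,
                                                   cfg$landmark_noise_mm),
                                      ncol = 3)
    keep_lm <- stats::runif(cfg$n_landmarks) >= cfg$landmark_occlusion
    if (sum(keep_lm) < 4L) keep_lm[seq_len(4L)] <- TRUE
    fu_lm <- point_set(fu_lm_pts[keep_lm, , drop = FALSE],
                       labels = attr(bl_lm, "labels")[keep_lm])

    # follow-up truth: disappearance, then detection dropout
    disappeared <- stats::runif(n_nod) < cfg$disappear_prob
    detected_fu <- !disappeared & stats::runif(n_nod) >= cfg$dropout_prob
    truth_links <- stats::setNames(ifelse(disappeared, "disappeared", true_ids),
                                   true_ids)
    fu_idx <- which(detected_fu)
    fu_pts <- warp(centroids[fu_idx, , drop = FALSE])
    if (cfg$residual_jitter_mm > 0 && length(fu_idx) > 0)
      fu_pts <- fu_pts + matrix(stats::rnorm(length(fu_pts), 0,
                                             cfg$residual_jitter_mm), ncol = 3)
    n_f <- length(fu_idx)
    followup <- data.frame(
      case_id = rep(case_id, n_f), pair_id = rep(pair_id, n_f),
      exam_id = rep(paste0(pair_id, "_FU"), n_f),
      lesion_id = sprintf("%s_F%03d", pair_id, seq_along(fu_idx)),
      x_mm = fu_pts[, 1], y_mm = fu_pts[, 2], z_mm = fu_pts[, 3],
      diameter_mm = diam[fu_idx],
      localization = locs[fu_idx],
      texture = texture[fu_idx],
      true_lesion_id = true_ids[fu_idx],
      stringsAsFactors = FALSE)

    structure(list(pair_id = pair_id, case_id = case_id,
                   baseline_landmarks = bl_lm,
                   followup_landmarks = fu_lm,
                   baseline_lesions = baseline,
                   followup_lesions = followup,
                   true_transform = true_tr,
                   truth_links = truth_links,
                   geometry = geom,
                   n_nodules_total = n_nod,
                   count_bin = count_bin(n_nod)),
              class = "case_pair")
  })
}

#' Generate a synthetic follow-up study
#'
#' Produces a list of baseline/follow-up exam pairs with known ground truth:
#' stylized thorax geometry, anatomical landmarks, true nodules placed
#' according to the localization mix, a random affine exam-to-exam motion
#' plus a caudal diaphragm displacement that decays away from the diaphragm,
#' landmark occlusion and noise, true disappearance, follow-up detection
#' dropout, and baseline false-positive injection. Deterministic given
#' `config$seed`; each pair draws from its own derived stream so single
#' pairs are reproducible in isolation.
#'
#' @param config `synthetic_config`.
#' @return List of `case_pair` objects; each carries baseline/follow-up
#'   landmark `point_set`s and lesion tables, the true `affine_transform`,
#'   truth links (baseline true id to follow-up true id or `"disappeared"`),
#'   the geometry, and the per-exam nodule count with its bin.
#' @examples
#' study <- generate_study(synthetic_config(n_cases = 2, seed = 7))
#' length(study)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  pairs <- list()
  with_seed(derive_seed(config$seed, 0L), {
    two_fu <- stats::runif(config$n_cases) < config$second_followup_prob
  })
  k <- 0L
  for (i in seq_len(config$n_cases)) {
    case_id <- sprintf("C%03d", i)
    for (f in seq_len(1L + two_fu[i])) {
      k <- k + 1L
      pair_id <- sprintf("%s_P%d", case_id, f)
      pairs[[k]] <- generate_case_pair(pair_id, case_id,
                                       derive_seed(config$seed, k), config)
    }
  }
  pairs
}

#' @export
print.case_pair <- function(x, ...) {
  cat(sprintf("<case_pair> %s: %d true nodules (%s), %d baseline / %d follow-up detections\n",
              x$pair_id, x$n_nodules_total, x$count_bin,
              nrow(x$baseline_lesions), nrow(x$followup_lesions)))
  invisible(x)
}
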