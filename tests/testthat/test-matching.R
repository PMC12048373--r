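test_that("target-lesion selection applies size window, texture and top-k", {
  set.seed(51)
  diam <- seq(4, 40, length.out = 15)
  lesions <- make_lesions(matrix(runif(45, -50, 50), ncol = 3),
                          ids = sprintf("N%02d", 1:15), diameter = diam)
  sel <- select_target_lesions(lesions, k = 10, d_min_mm = 5, d_max_mm = 30)
  expect_true(all(sel$diameter_mm >= 5 & sel$diameter_mm <= 30))
  in_range <- lesions[lesions$diameter_mm >= 5 & lesions$diameter_mm <= 30, ]
  expect_equal(nrow(sel), min(10, nrow(in_range)))
  expect_setequal(sel$lesion_id,
                  in_range$lesion_id[order(-in_range$diameter_mm)][1:nrow(sel)])

  # bounds are inclusive
  edge <- make_lesions(matrix(0, 2, 3), ids = c("A", "B"), diameter = c(5, 30))
  expect_equal(nrow(select_target_lesions(edge)), 2L)

  # subsolid and mixed lesions are excluded
  tex <- make_lesions(matrix(0, 3, 3), ids = c("A", "B", "C"),
                      texture = c("solid", "subsolid", "mixed"))
  expect_equal(select_target_lesions(tex)$lesion_id, "A")

  # fewer than k eligible: all returned
  small <- make_lesions(matrix(0, 3, 3), diameter = 8)
  expect_equal(nrow(select_target_lesions(small, k = 10)), 3L)
  expect_equal(nrow(select_target_lesions(small[0, ], k = 10)), 0L)
})

test_that("selection ties at the k-th diameter break by lesion id (sort oracle)", {
  lesions <- make_lesions(matrix(0, 4, 3), ids = c("N04", "N02", "N03", "N01"),
                          diameter = c(12, 10, 10, 15))
  sel <- select_target_lesions(lesions, k = 3)
  # brute-force oracle: stable sort on (-diameter, id)
  ord <- order(-lesions$diameter_mm, lesions$lesion_id)
  expect_equal(sel$lesion_id, lesions$lesion_id[ord][1:3])
  expect_equal(sel$lesion_id, c("N01", "N04", "N02"))
})

test_that("the 15 mm rule is strict: 14.9 mm matches, 15.0 mm does not", {
  b <- make_lesions(c(0, 0, 0), ids = "B1")
  f149 <- make_lesions(c(14.9, 0, 0), ids = "F1")
  f150 <- make_lesions(c(15.0, 0, 0), ids = "F1")
  m1 <- pair_nodules(b, f149, threshold_mm = 15)
  expect_equal(nrow(m1$pairs), 1L)
  expect_equal(m1$pairs$distance_mm, 14.9)
  m2 <- pair_nodules(b, f150, threshold_mm = 15)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched_baseline, "B1")
  expect_equal(m2$unmatched_followup, "F1")
})

test_that("one-to-one competition resolves to the closer baseline nodule", {
  b <- make_lesions(rbind(c(3, 0, 0), c(8, 0, 0)), ids = c("B1", "B2"))
  f <- make_lesions(c(0, 0, 0), ids = "F1")
  m <- pair_nodules(b, f)
  expect_equal(m$pairs$baseline_id, "B1")
  expect_equal(m$pairs$distance_mm, 3)
  expect_equal(m$unmatched_baseline, "B2")
  # brute-force optimal assignment agrees
  orc <- oracle_assignment(as.matrix(b[, c("x_mm", "y_mm", "z_mm")]),
                           as.matrix(f[, c("x_mm", "y_mm", "z_mm")]), 15)
  expect_equal(orc$bi, 1L)
})

test_that("degenerate inputs give empty match results", {
  f <- make_lesions(matrix(runif(9), 3, 3), ids = c("F1", "F2", "F3"))
  m <- pair_nodules(f[0, ], f)
  expect_equal(nrow(m$pairs), 0L)
  expect_setequal(m$unmatched_followup, c("F1", "F2", "F3"))
  expect_equal(length(m$unmatched_baseline), 0L)
})

test_that("match results satisfy the partition and threshold invariants", {
  set.seed(61)
  for (rep in 1:20) {
    nb <- sample(0:8, 1); nf <- sample(0:8, 1)
    b <- make_lesions(matrix(runif(nb * 3, 0, 60), ncol = 3),
                      ids = sprintf("B%02d", seq_len(nb)))
    f <- make_lesions(matrix(runif(nf * 3, 0, 60), ncol = 3),
                      ids = sprintf("F%02d", seq_len(nf)))
    m <- pair_nodules(b, f, threshold_mm = 15)
    expect_true(all(m$pairs$distance_mm < 15))
    expect_false(anyDuplicated(m$pairs$baseline_id) > 0)
    expect_false(anyDuplicated(m$pairs$followup_id) > 0)
    expect_setequal(c(m$pairs$baseline_id, m$unmatched_baseline), b$lesion_id)
    expect_setequal(c(m$pairs$followup_id, m$unmatched_followup), f$lesion_id)
  }
})

test_that("pairing is invariant under a common rigid motion of both exams", {
  set.seed(71)
  b <- make_lesions(matrix(runif(18, -60, 60), ncol = 3),
                    ids = sprintf("B%d", 1:6))
  f <- make_lesions(as.matrix(b[, c("x_mm", "y_mm", "z_mm")]) +
                      matrix(rnorm(18, sd = 4), ncol = 3),
                    ids = sprintf("F%d", 1:6))
  m0 <- pair_nodules(b, f)
  rigid <- random_affine(rot_deg = 30, scale = c(1, 1), trans_mm = 50)
  b2 <- b; f2 <- f
  b2[, c("x_mm", "y_mm", "z_mm")] <-
    apply_affine(rigid, as.matrix(b[, c("x_mm", "y_mm", "z_mm")]))
  f2[, c("x_mm", "y_mm", "z_mm")] <-
    apply_affine(rigid, as.matrix(f[, c("x_mm", "y_mm", "z_mm")]))
  m1 <- pair_nodules(b2, f2)
  expect_equal(m1$pairs[, c("baseline_id", "followup_id")],
               m0$pairs[, c("baseline_id", "followup_id")])
})

test_that("pairing does not depend on input row order", {
  set.seed(81)
  b <- make_lesions(matrix(runif(18, 0, 50), ncol = 3), ids = sprintf("B%d", 1:6))
  f <- make_lesions(matrix(runif(15, 0, 50), ncol = 3), ids = sprintf("F%d", 1:5))
  m0 <- pair_nodules(b, f)
  m1 <- pair_nodules(b[sample(6), ], f[sample(5), ])
  key <- function(m) {
    p <- m$pairs[order(m$pairs$baseline_id), ]
    rownames(p) <- NULL
    p
  }
  expect_equal(key(m1), key(m0))
})

test_that("greedy pairing equals the exhaustive optimal assignment in the operating regime", {
  set.seed(91)
  for (rep in 1:100) {
    # domain-realistic instance: well-spaced nodules, small residual motion,
    # occasional insertions and deletions
    nb <- sample(1:6, 1)
    B <- matrix(runif(nb * 3, 0, 150), ncol = 3)
    while (nb > 1 && min(dist(B)) < 20) B <- matrix(runif(nb * 3, 0, 150), ncol = 3)
    keep <- runif(nb) > 0.2
    F <- B[keep, , drop = FALSE] + matrix(rnorm(3 * sum(keep), sd = 2), ncol = 3)
    if (runif(1) < 0.3) F <- rbind(F, runif(3, 0, 150))
    nf <- nrow(F)
    if (nf == 0) next
    b <- make_lesions(B, ids = sprintf("B%02d", seq_len(nb)))
    f <- make_lesions(F, ids = sprintf("F%02d", seq_len(nf)))
    m <- pair_nodules(b, f, threshold_mm = 15)
    orc <- oracle_assignment(B, F, 15)
    got <- m$pairs[order(m$pairs$baseline_id), ]
    expect_equal(nrow(got), nrow(orc))
    expect_equal(got$baseline_id, sprintf("B%02d", orc$bi))
    expect_equal(got$followup_id, sprintf("F%02d", orc$fi))
  }
})
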