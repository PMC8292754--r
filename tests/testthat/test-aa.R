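test_that("extended invariants compute the documented feature vector", {
  rt <- spotset(x = c(0, 3, 0), y = c(0, 0, 4), size = rep(1, 3))
  f <- build_invariants_aa(rt, aa_config())$features
  expect_equal(unname(f[1, "r21"]), 5 / 4, tolerance = 1e-9)   # L2/L1
  expect_equal(unname(f[1, "r10"]), 4 / 3, tolerance = 1e-9)   # L1/L0
  expect_equal(ncol(f) - 3, 9)  # 2 ratios + angle + 6 scaled coordinates

  # coordinates are scaled down by a factor of 5
  vi <- as.integer(f[1, 1:3])
  expect_equal(unname(f[1, c("x1", "y1")]), c(rt$x[vi[1]], rt$y[vi[1]]) / 5)

  eq <- spotset(x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2), size = rep(1, 3))
  fe <- build_invariants_aa(eq, aa_config())$features
  expect_equal(unname(fe[1, "r21"]), 1, tolerance = 1e-9)
  expect_equal(unname(fe[1, "r10"]), 1, tolerance = 1e-9)

  expect_error(build_invariants_aa(spotset(0, 0, 1), aa_config()),
               class = "spotmatch_too_few_spots")
})

test_that("RANSAC matcher: identity, known transform, negatives", {
  a <- norm_constellation(30, seed = 1)

  r <- ransac_match_aa(a, a, seed = 1)
  expect_true(r$accepted)
  expect_equal(r$score, 1)
  expect_lt(abs(r$transform$rotation), 1e-6)
  expect_lt(abs(r$transform$scale - 1), 1e-6)

  # copy transformed by rotation 8 deg, scale 1.05 -> parameters recovered
  p <- perturb_constellation(a, rotation = 8, scale = 1.05,
                             translation = c(0.02, -0.01), seed = 2)
  r2 <- ransac_match_aa(a, p$spots, seed = 1)
  expect_true(!is.null(r2$transform))
  expect_lt(abs(r2$transform$rotation - 8), 1)
  expect_lt(abs(r2$transform$scale - 1.05) / 1.05, 0.02)

  # independent random constellations are rejected in almost all trials
  rejected <- 0
  for (i in 1:20) {
    x <- norm_constellation(25, seed = 600 + i)
    y <- norm_constellation(25, seed = 700 + i)
    rr <- ransac_match_aa(x, y, seed = i)
    if (is.null(rr$transform)) rejected <- rejected + 1
  }
  expect_gte(rejected, 19)
})

test_that("RANSAC is seed-reproducible and stable across seeds", {
  a <- norm_constellation(25, seed = 5)
  p <- perturb_recapture(a, seed = 6)
  r1 <- ransac_match_aa(p$spots, a, seed = 3)
  r2 <- ransac_match_aa(p$spots, a, seed = 3)
  expect_identical(r1$score, r2$score)
  expect_identical(r1$transform$matrix, r2$transform$matrix)

  # decisions vary little across RANSAC seeds
  found <- vapply(1:10, function(s)
    !is.null(ransac_match_aa(p$spots, a, seed = s)$transform), logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("mask overlap gate rejects transforms that misalign the body", {
  a <- norm_constellation(25, seed = 8)
  m <- ellipse_norm_mask()
  r <- ransac_match_aa(a, a, maskA = m, maskB = m, seed = 1)
  expect_true(r$accepted)
  expect_gte(r$mask_fscore, 0.99)

  # same constellations, but the stored mask of the target is displaced:
  # the (identity) transform no longer overlays the masks
  m2 <- norm_mask(m$px, m$origin + c(0.9, 0.2), m$step)
  r2 <- ransac_match_aa(a, a, maskA = m, maskB = m2, seed = 1)
  expect_false(r2$accepted)
  expect_lt(r2$mask_fscore, 0.75)
})

test_that("coordinate features improve matched-triangle precision", {
  # the vertex-coordinate features exist to suppress spot alignments that
  # would not align the bodies; with them, the mutual-NN matched triangles
  # contain at least as many true pairs as with the side ratios alone
  for (i in 1:4) {
    a <- norm_constellation(30, seed = 900 + i)
    p <- perturb_constellation(a, rotation = 3, scale = 1.05,
                               jitter_sd = 0.003, seed = 950 + i)
    map <- rep(NA, n_spots(p$spots))
    map[p$correspondence[, "to"]] <- p$correspondence[, "from"]
    ta <- build_invariants_aa(p$spots, aa_config())
    tb <- build_invariants_aa(a, aa_config())
    prec <- function(cols) {
      mm <- spotmatch:::mutual_nn_cpp(ta$features[, cols, drop = FALSE],
                                      tb$features[, cols, drop = FALSE])
      va <- matrix(ta$features[mm[, 1], 1:3], ncol = 3)
      vb <- matrix(tb$features[mm[, 2], 1:3], ncol = 3)
      sum(rowSums(matrix(map[va], ncol = 3) == vb, na.rm = TRUE) == 3)
    }
    expect_gte(prec(4:12), prec(4:5))
  }
})
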