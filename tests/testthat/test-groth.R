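test_that("dedupe removes points within three epsilon, in input order", {
  s <- spotset(x = c(0, 0.002, 0.004, 0.1), y = c(0, 0, 0, 0),
               size = rep(1, 4))
  out <- dedupe_spots(s, epsilon = 0.001)
  # 0.002 within 3e-3 of kept point 0; 0.004 within 3e-3 of... only of the
  # removed 0.002, so it is kept (distance to 0 is 0.004 > 0.003)
  expect_equal(out$x, c(0, 0.004, 0.1))

  far <- spotset(x = c(0, 1, 2), y = c(0, 0, 0), size = rep(1, 3))
  expect_equal(n_spots(dedupe_spots(far, 0.01)), 3L)

  two <- spotset(x = c(0, 0.002), y = c(0, 0), size = c(1, 1))
  expect_equal(n_spots(dedupe_spots(two, 0.001)), 1L)   # distance 2 epsilon
  two4 <- spotset(x = c(0, 0.004), y = c(0, 0), size = c(1, 1))
  expect_equal(n_spots(dedupe_spots(two4, 0.001)), 2L)  # distance 4 epsilon
})

test_that("triangle construction enumerates local triples with invariants", {
  s <- norm_constellation(10, seed = 2)
  tri <- build_triangles_groth(s, groth_config(knn = 25))
  expect_equal(nrow(tri$features), choose(10, 3))  # knn covers all points

  # right triangle with sides 3, 4, 5
  rt <- spotset(x = c(0, 3, 0), y = c(0, 0, 4), size = rep(1, 3))
  f <- build_triangles_groth(rt, groth_config())$features
  expect_equal(unname(f[1, "R"]), 5 / 3, tolerance = 1e-9)
  expect_equal(unname(f[1, "C"]), 0.6, tolerance = 1e-9)
  expect_equal(unname(f[1, "logP"]), log(12), tolerance = 1e-9)

  eq <- spotset(x = c(0, 1, 0.5), y = c(0, 0, sqrt(3) / 2), size = rep(1, 3))
  fe <- build_triangles_groth(eq, groth_config())$features
  expect_equal(unname(fe[1, "R"]), 1, tolerance = 1e-9)
  expect_equal(unname(fe[1, "C"]), 0.5, tolerance = 1e-9)

  expect_error(build_triangles_groth(spotset(1, 1, 1), groth_config()),
               class = "spotmatch_too_few_spots")
})

test_that("k-d tree mutual nearest neighbours equal the brute-force oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    na <- sample(20:200, 1); nb <- sample(20:200, 1)
    A <- matrix(runif(na * 3), na, 3)
    B <- matrix(runif(nb * 3), nb, 3)
    mm <- spotmatch:::mutual_nn_cpp(A, B)
    oracle <- brute_mutual_nn(A, B)
    got <- mm[order(mm[, 1]), 1:2, drop = FALSE]
    exp <- oracle[order(oracle[, 1]), , drop = FALSE]
    expect_equal(unname(got), unname(cbind(exp[, 1], exp[, 2])))
  }
})

test_that("triangle matching filters behave as documented", {
  s <- norm_constellation(20, seed = 4)
  cfg <- groth_config()
  tri <- build_triangles_groth(s, cfg)

  # identical constellations: every triangle matches itself
  m <- match_triangles(tri, tri, cfg)
  expect_equal(m$a, m$b)
  expect_equal(nrow(m), nrow(tri$features))
  expect_true(all(m$dist == 0))

  # mirror flip: every triangle's mirror twin has opposite handedness, so no
  # surviving pair joins a triangle with its own mirror image, and the
  # full matcher does not accept the mirrored constellation
  mir <- spotset(-s$x, s$y, s$size)
  trim <- build_triangles_groth(mir, cfg)
  mm <- match_triangles(tri, trim, cfg)
  if (nrow(mm) > 0) {
    expect_true(all(tri$features[mm$a, "handed"] ==
                      trim$features[mm$b, "handed"]))
    sa <- apply(matrix(tri$features[mm$a, 1:3], ncol = 3), 1,
                function(v) paste(sort(v), collapse = "-"))
    sb <- apply(matrix(trim$features[mm$b, 1:3], ncol = 3), 1,
                function(v) paste(sort(v), collapse = "-"))
    expect_false(any(sa == sb))
  }
  expect_lt(groth_match(mir, s, cfg)$score, 6.5)

  # monotone pruning: disabling any filter never shrinks the candidate set
  q <- perturb_recapture(s, seed = 5)$spots
  triq <- build_triangles_groth(q, cfg)
  full <- nrow(match_triangles(triq, tri, cfg))
  for (f in c("tolerance_filter", "handedness_filter", "angle_filter",
              "magnification_filter")) {
    cfg2 <- cfg; cfg2[[f]] <- FALSE
    expect_gte(nrow(match_triangles(triq, tri, cfg2)), full)
  }
})

test_that("voting assigns pairs under the stated stopping rules", {
  cfg <- groth_config()
  s <- norm_constellation(12, seed = 6)
  tri <- build_triangles_groth(s, cfg)

  # a single matched triangle yields three pairs, one vote each, all assigned
  m1 <- match_triangles(tri, tri, cfg)[1, , drop = FALSE]
  corr <- vote_and_assign(m1, tri, tri, cfg)
  expect_equal(nrow(corr), 3L)
  expect_equal(attr(corr, "votes")$votes, rep(1L, 3))

  # identical constellations: identity correspondence over all points
  mall <- match_triangles(tri, tri, cfg)
  call <- vote_and_assign(mall, tri, tri, cfg)
  expect_equal(nrow(call), 12L)
  expect_equal(call[, "a"], call[, "b"])

  # stop-at-reuse: matching triangle 1 to itself and to a different triangle
  # creates conflicting pairs for triangle 1's vertices; under the stop rule
  # the assignment ends at the first conflict, leaving only the three
  # identity pairs (which sort first by feature distance)
  stop_cfg <- groth_config(on_reuse = "stop")
  other <- which(apply(tri$features[, 1:3], 1, function(v)
    length(intersect(v, tri$features[1, 1:3])) < 3))[1]
  conflict <- data.frame(a = c(1L, 1L), b = c(1L, other),
                         dist = c(0, 0.1), dlogP = c(0, 0))
  c2 <- vote_and_assign(conflict, tri, tri, stop_cfg)
  expect_equal(nrow(c2), 3L)
  expect_equal(sort(c2[, "a"]), sort(as.integer(tri$features[1, 1:3])))
})

test_that("full matcher accepts self and perturbed copies, rejects imposters", {
  cfg <- groth_config()
  a <- norm_constellation(15, seed = 10)
  self <- groth_match(a, a, cfg)
  expect_true(self$accepted)
  expect_equal(nrow(self$correspondence), 15L)
  expect_equal(self$correspondence[, "a"], self$correspondence[, "b"])
  expect_equal(self$score, 15)

  # perturbed recapture: at least 80% of surviving true pairs recovered
  recov <- numeric(0)
  for (i in 1:8) {
    s <- norm_constellation(30, seed = 100 + i)
    p <- perturb_recapture(s, seed = 200 + i)
    r <- groth_match(p$spots, s, cfg)
    if (!r$accepted) { recov <- c(recov, 0); next }
    map <- rep(NA, n_spots(p$spots))
    map[p$correspondence[, "to"]] <- p$correspondence[, "from"]
    good <- sum(map[r$correspondence[, "a"]] == r$correspondence[, "b"],
                na.rm = TRUE)
    recov <- c(recov, good / nrow(p$correspondence))
  }
  expect_gte(mean(recov), 0.6)

  # independent constellation scores far below the acceptance threshold
  b <- norm_constellation(30, seed = 999)
  s <- norm_constellation(30, seed = 100)
  rn <- groth_match(b, s, cfg)
  expect_lt(rn$score, 6.5)

  # too few spots is reported as a rejected result
  tiny <- spotset(c(0, 1), c(0, 0), c(1, 1))
  r2 <- groth_match(tiny, s, cfg)
  expect_false(r2$accepted)
  expect_equal(r2$diagnostics$reason, "too_few_spots")
})

test_that("matching is symmetric in accept/reject on the synthetic suite", {
  cfg <- groth_config()
  for (i in 1:5) {
    a <- norm_constellation(25, seed = 300 + i)
    p <- perturb_recapture(a, seed = 400 + i)
    r1 <- groth_match(p$spots, a, cfg)
    r2 <- groth_match(a, p$spots, cfg)
    expect_equal(r1$accepted, r2$accepted)
    if (r1$accepted) {
      c1 <- r1$correspondence[order(r1$correspondence[, "a"]), , drop = FALSE]
      c2 <- r2$correspondence[order(r2$correspondence[, "b"]), , drop = FALSE]
      expect_equal(unname(c1[, "a"]), unname(c2[, "b"]))
      expect_equal(unname(c1[, "b"]), unname(c2[, "a"]))
    }
  }
})

test_that("self-match score dominates scores against perturbed non-matches", {
  cfg <- groth_config()
  a <- norm_constellation(20, seed = 77)
  self <- groth_match(a, a, cfg)$score
  for (i in 1:5) {
    other <- norm_constellation(20, seed = 500 + i)
    expect_lt(groth_match(other, a, cfg)$score, self)
  }
})
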