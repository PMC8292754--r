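test_that("generate_constellation respects bounds, separation and determinism", {
  expect_equal(n_spots(generate_constellation(0, seed = 1)), 0L)

  s <- generate_constellation(30, frame = c(1000, 400), seed = 1,
                              spot_radius_range = c(5, 10))
  expect_equal(n_spots(s), 30L)
  expect_true(all(s$x >= 0 & s$x <= 1000 & s$y >= 0 & s$y <= 400))
  d <- as.matrix(dist(cbind(s$x, s$y)))
  expect_true(min(d[upper.tri(d)]) >= 20)  # 2 x max radius

  s2 <- generate_constellation(12, seed = 7)
  s3 <- generate_constellation(12, seed = 7)
  expect_identical(s2, s3)

  expect_error(generate_constellation(-1, seed = 1),
               class = "spotmatch_invalid_argument")
})

test_that("perturb_constellation: identity, drop rule and exact rotation", {
  s <- generate_constellation(30, seed = 3)

  idp <- perturb_constellation(s, seed = 5)
  expect_equal(idp$spots$x, s$x)
  expect_equal(idp$spots$y, s$y)
  expect_equal(idp$correspondence[, "from"], 1:30)
  expect_equal(idp$correspondence[, "to"], 1:30)

  dr <- perturb_constellation(s, drop_fraction = 0.5, seed = 5)
  expect_equal(n_spots(dr$spots), 15L)  # floor(30 * 0.5) dropped
  expect_equal(nrow(dr$correspondence), 15L)

  rot <- perturb_constellation(s, rotation = 10, seed = 5)
  ctr <- c(mean(s$x), mean(s$y))
  th <- 10 * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  expected <- t(R %*% (t(cbind(s$x, s$y)) - ctr) + ctr)
  expect_lt(max(abs(cbind(rot$spots$x, rot$spots$y) - expected)), 1e-9)

  expect_error(perturb_constellation(s, drop_fraction = 1.2),
               class = "spotmatch_invalid_argument")
})

test_that("perturbation conserves spots: retained + dropped = original", {
  s <- generate_constellation(23, seed = 9)
  for (frac in c(0, 0.1, 0.37, 1)) {
    p <- perturb_constellation(s, drop_fraction = frac, add_count = 3,
                               seed = 11)
    retained <- nrow(p$correspondence)
    expect_equal(retained + floor(23 * frac), 23)
    expect_equal(n_spots(p$spots), retained + 3L)
  }
})

test_that("render_fish_image produces consistent masks and determinism", {
  r <- small_fish(seed = 2)
  expect_true(all(r$spot_mask <= r$body_mask))  # spots subset of body
  expect_true(all(r$image >= 0 & r$image <= 255))
  expect_equal(n_spots(r$spots), 8L)

  r2 <- small_fish(seed = 2)
  expect_identical(r$image, r2$image)

  r0 <- render_fish_image(fish_spec(frame = c(256, 128), n_spots = 0,
                                    rng_seed = 1))
  expect_false(any(r0$spot_mask))

  expect_error(fish_spec(spot_radius_range = c(300, 400)),
               class = "spotmatch_invalid_argument")
  expect_error(fish_spec(spot_level = 100, body_level = 60),
               class = "spotmatch_invalid_argument")
})

test_that("capture histories follow the survival/capture process", {
  y1 <- simulate_capture_histories(40, 6, phi = 1, p = 1, seed = 1)
  first <- attr(y1, "first")
  for (i in 1:40)
    expect_true(all(y1[i, first[i]:6] == 1))

  y0 <- simulate_capture_histories(40, 6, phi = 0, p = 0.9, seed = 2)
  first <- attr(y0, "first")
  for (i in 1:40)
    expect_true(all(y0[i, -seq_len(first[i])] == 0))

  # P(re-seen at the very next occasion) = phi * p
  y <- simulate_capture_histories(10000, 5, phi = 0.5, p = 0.5, seed = 3)
  first <- attr(y, "first")
  seen_next <- y[cbind(seq_len(nrow(y)), first + 1L)]
  phat <- mean(seen_next)
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(phat - 0.25), 3 * se)
})

test_that("three-occasion history frequencies match exhaustive enumeration", {
  y <- simulate_capture_histories(10000, 3, phi = 0.5, p = 0.5, seed = 4)
  first <- attr(y, "first")
  sub <- y[first == 1, , drop = FALSE]
  n <- nrow(sub)
  pats <- apply(sub, 1, paste, collapse = "")
  for (pat in c("100", "110", "101", "111")) {
    h <- as.integer(strsplit(pat, "")[[1]])
    pexp <- enumerate_cjs_likelihood(h, 0.5, 0.5)
    phat <- mean(pats == pat)
    se <- sqrt(pexp * (1 - pexp) / n)
    expect_lt(abs(phat - pexp), 4 * se)
  }
  expect_equal(enumerate_cjs_likelihood(c(1, 0, 0), 0.5, 0.5), 0.6875)
})

test_that("tag loss fragments histories at the stated rate", {
  y <- simulate_capture_histories(30, 8, phi = 0.9, p = 0.8, seed = 5)
  rec <- capture_records(y)

  r0 <- inject_tag_loss(rec, rate = 0, seed = 1)
  expect_identical(r0$observed_id, r0$id)

  r1 <- inject_tag_loss(rec, rate = 1, seed = 1)
  obs <- histories_from_records(r1, 8, id_col = "observed_id")
  expect_true(all(rowSums(obs) == 1))  # every history a singleton

  # binomial expectation over many recaptures
  yy <- simulate_capture_histories(700, 8, phi = 0.95, p = 0.9, seed = 6)
  rr <- capture_records(yy)
  n_recap <- nrow(rr) - length(unique(rr$id))
  rl <- inject_tag_loss(rr, rate = 0.07, seed = 7)
  expect_lt(abs(sum(rl$lost) - 0.07 * n_recap),
            3 * sqrt(n_recap * 0.07 * 0.93))

  expect_error(inject_tag_loss(rec, rate = 1.5),
               class = "spotmatch_invalid_argument")
})
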