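test_that("spot blur sigma follows the resolution rule", {
  expect_equal(spot_blur_sigma(1882), 19)
  expect_equal(spot_blur_sigma(2322), 21)
  expect_equal(spot_blur_sigma(5184), ((5184 - 1882) / 440) * 2 + 19,
               tolerance = 1e-12)
  expect_equal(spot_blur_sigma(100, min_sigma = 12), 12)  # clamp engages
  expect_error(spot_blur_sigma(0), class = "spotmatch_invalid_argument")

  # affine and strictly increasing above the clamp point
  lens <- seq(2000, 6000, by = 500)
  sig <- vapply(lens, spot_blur_sigma, 0)
  expect_true(all(diff(sig) > 0))
  expect_equal(diff(sig) / 500, rep(2 / 440, length(lens) - 1),
               tolerance = 1e-12)
})

test_that("region filter keeps discs and removes specks and bars", {
  cfg <- baseline_config()
  body_area <- 1e6
  regions <- data.frame(
    label = 1:4,
    # a disc of radius 20 (kept), a 1 px speck, a 40x2 bar, a huge region
    area = c(pi * 20^2, 1, 80, 1e4),
    perimeter = c(2 * pi * 20, 4, 84, 400))
  out <- filter_spot_regions(regions, body_area, cfg)
  expect_equal(out$label, 1L)

  # the bar's circularity is 4*pi*80/84^2 ~ 0.1425 < 0.5
  expect_equal(circularity(80, 84), 4 * pi * 80 / 84^2, tolerance = 1e-12)
  expect_lt(circularity(80, 84), 0.5)

  # idempotent
  expect_identical(filter_spot_regions(out, body_area, cfg), out)
})

test_that("segmentation evaluation handles the degenerate conventions", {
  m <- matrix(FALSE, 5, 5); t <- m
  m[2:3, 2:3] <- TRUE; t[2:3, 2:3] <- TRUE
  expect_equal(unname(evaluate_segmentation(m, t)), c(1, 1, 1))

  empty <- matrix(FALSE, 5, 5)
  expect_equal(unname(evaluate_segmentation(empty, t)), c(0, 0, 0))

  # equal-area masks overlapping half their pixels
  a <- matrix(FALSE, 4, 4); b <- a
  a[1, 1:4] <- TRUE; a[2, 1:4] <- TRUE
  b[2, 1:4] <- TRUE; b[3, 1:4] <- TRUE
  expect_equal(unname(evaluate_segmentation(a, b)), c(0.5, 0.5, 0.5))

  expect_error(evaluate_segmentation(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               class = "spotmatch_invalid_argument")
})

test_that("body mask extraction selects the centred subject", {
  expect_error(
    extract_fish_mask_baseline(matrix(255, 60, 60),
                               baseline_config(image_width = 60)),
    class = "spotmatch_no_subject")

  # two dark blobs; the centred one is selected even though both are dark
  img <- matrix(220, 100, 100)
  xs <- matrix(rep(1:100, each = 100), 100, 100)
  ys <- matrix(rep(1:100, 100), 100, 100)
  img[(xs - 50)^2 + (ys - 50)^2 <= 15^2] <- 30   # centred blob
  img[(xs - 85)^2 + (ys - 85)^2 <= 13^2] <- 30   # corner blob
  cfg <- baseline_config(image_width = 100, sigma1 = 1.5, erosion_radius = 2)
  mask <- extract_fish_mask_baseline(img, cfg)
  w <- which(mask, arr.ind = TRUE)
  expect_lt(max(abs(colMeans(w) - 50)), 2)
})

test_that("baseline recovers body and spots on a synthetic render", {
  r <- render_fish_image(fish_spec(rng_seed = 1))
  cfg <- baseline_config_synthetic(ncol(r$image))
  bm <- extract_fish_mask_baseline(r$image, cfg)
  expect_gt(evaluate_segmentation(bm, r$body_mask)["f1"], 0.9)

  sm <- extract_spots_baseline(r$image, bm, cfg)
  expect_true(all(sm <= bm))  # spot mask subset of body mask
  expect_gt(evaluate_segmentation(sm, r$spot_mask)["f1"], 0.35)

  expect_error(extract_spots_baseline(r$image, r$body_mask & FALSE, cfg),
               class = "spotmatch_empty_mask")

  # a dark blob outside the body never appears in the spot mask
  img2 <- r$image
  img2[1:40, 1:40] <- 20
  sm2 <- extract_spots_baseline(img2, bm, cfg)
  expect_false(any(sm2[1:40, 1:40]))
})

test_that("distractors degrade the baseline body mask (directional)", {
  clean <- numeric(4); noisy <- numeric(4)
  # fish positions spanning centred to strongly off-centre
  offs <- c(0.26, 0.29, 0.45, 0.55)
  for (i in 1:4) {
    rc <- render_fish_image(fish_spec(rng_seed = 40 + i))
    rd <- render_fish_image(fish_spec(
      rng_seed = 40 + i, body_center = c(offs[i], 0.5) * c(1882, 830),
      distractors = c("ruler_stripe", "debris_blob", "shadow_gradient")))
    for (kind in 1:2) {
      r <- if (kind == 1) rc else rd
      cfg <- baseline_config_synthetic(ncol(r$image))
      bm <- tryCatch(extract_fish_mask_baseline(r$image, cfg),
                     error = function(e) r$body_mask & FALSE)
      f <- evaluate_segmentation(bm, r$body_mask)["f1"]
      if (kind == 1) clean[i] <- f else noisy[i] <- f
    }
  }
  expect_lt(mean(noisy), mean(clean))
})
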