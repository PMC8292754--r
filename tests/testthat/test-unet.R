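test_that("padding scales the long side and records an invertible placement", {
  sq <- matrix(runif(64 * 64), 64, 64)
  p <- pad_to_input(sq, 64)
  expect_equal(p$image, sq)  # already square at target size
  expect_equal(p$placement$scale, 1)

  # 1024 x 512 -> content 512 x 256, remainder zeros
  wide <- matrix(1, 1024, 512)
  p2 <- pad_to_input(wide, 512)
  expect_equal(p2$placement$content, c(512, 256))
  expect_equal(sum(p2$image > 0), 512 * 256)
  # all padding pixels are zero
  inside <- matrix(FALSE, 512, 512)
  inside[p2$placement$offset[1] + 1:512 - 0,
         p2$placement$offset[2] + 1:256] <- TRUE
  expect_true(all(p2$image[!inside] == 0))

  back <- placement_to_original(p2$image, p2$placement)
  expect_equal(dim(back), c(1024, 512))

  # coordinate round trip within a pixel
  xy <- cbind(c(10, 400), c(20, 900))
  fwd <- placement_map_coords(p2$placement, xy, to = "input")
  inv <- placement_map_coords(p2$placement, fwd, to = "original")
  expect_lt(max(abs(inv - xy)), 1e-9)
})

test_that("mask-extent cropping rescales the bounding box", {
  img <- matrix(runif(200 * 300), 200, 300)
  mask <- matrix(FALSE, 200, 300)
  mask[51:150, 101:150] <- TRUE  # bbox 100 x 50
  cr <- crop_and_rescale_to_mask(img, mask, 512)
  expect_equal(cr$placement$content, c(512, 256))
  expect_equal(cr$placement$crop, c(50, 100))

  # mask covering the whole frame is equivalent to plain padding
  full <- crop_and_rescale_to_mask(img, matrix(TRUE, 200, 300), 64)
  plain <- pad_to_input(img, 64)
  expect_equal(full$image, plain$image)

  # inverse placement maps content corners back to the bbox within a pixel
  corners_in <- placement_map_coords(cr$placement,
                                     cbind(c(100, 150), c(50, 150)),
                                     to = "input")
  corners_back <- placement_map_coords(cr$placement, corners_in, "original")
  expect_lt(max(abs(corners_back - cbind(c(100, 150), c(50, 150)))), 1e-9)

  expect_error(crop_and_rescale_to_mask(img, mask & FALSE, 64),
               class = "spotmatch_empty_mask")
})

test_that("the network maps inputs to probabilities deterministically", {
  cfg <- unet_smoke_config()
  model <- build_segmentation_network(cfg, seed = 1)
  x <- matrix(runif(64 * 64), 64, 64)
  p1 <- predict_mask(model, x)
  p2 <- predict_mask(model, x)
  expect_identical(p1, p2)  # dropout off at inference
  expect_equal(dim(p1), c(64, 64))
  expect_true(all(is.finite(p1)) && all(p1 >= 0 & p1 <= 1))

  # rebuilt with the same seed -> identical weights
  m2 <- build_segmentation_network(cfg, seed = 1)
  expect_identical(model$enc[[1]]$W, m2$enc[[1]]$W)

  expect_error(unet_config(input_size = 100, depth = 3),
               class = "spotmatch_invalid_argument")
})

test_that("training overfits two images and is seed-reproducible", {
  cfg <- unet_smoke_config()
  pairs <- lapply(1:2, function(i) {
    r <- small_fish(seed = i)
    pi <- pad_to_input(r$image, cfg$input_size)
    pm <- pad_to_input(r$body_mask * 1, cfg$input_size)
    list(image = pi$image, mask = pm$image > 0.5)
  })
  model <- build_segmentation_network(cfg, seed = 1)
  tr <- train_network(model, pairs, cfg, aug = NULL, seed = 3)
  expect_length(tr$loss, cfg$epochs)
  expect_equal(tr$n_draws, cfg$epochs * cfg$samples_per_epoch)
  expect_lt(tr$loss[cfg$epochs], 0.5 * tr$loss[1])

  tr2 <- train_network(model, pairs, cfg, aug = NULL, seed = 3)
  expect_identical(tr$loss, tr2$loss)

  expect_error(train_network(model, list(), cfg),
               class = "spotmatch_invalid_argument")
})

test_that("augmentation preserves shapes and mask binarity", {
  aug <- augmentation_spec()
  r <- small_fish(seed = 4)
  pi <- pad_to_input(r$image, 64)
  pm <- pad_to_input(r$body_mask * 1, 64)
  set.seed(1)
  out <- spotmatch:::augment_pair(pi$image / 255, pm$image > 0.5, aug)
  expect_equal(dim(out$image), c(64, 64))
  expect_true(is.logical(out$mask))
  expect_true(all(out$image >= 0 & out$image <= 1))
})

test_that("mask post-processing fills, joins and selects the central blob", {
  # annulus -> filled disc
  xs <- matrix(rep(1:99, each = 99), 99, 99)
  ys <- matrix(rep(1:99, 99), 99, 99)
  r2 <- (xs - 50)^2 + (ys - 50)^2
  annulus <- r2 <= 30^2 & r2 >= 20^2
  filled <- postprocess_mask(annulus, closing_radius = 2)
  expect_true(all(filled[r2 <= 20^2]))

  # two components 3 px apart, closing radius 5 -> one component
  m <- matrix(FALSE, 40, 40)
  m[10:30, 5:15] <- TRUE
  m[10:30, 19:29] <- TRUE
  joined <- postprocess_mask(m, closing_radius = 5)
  expect_equal(max(EBImage::bwlabel(joined)), 1)

  # central blob kept, corner speck removed
  s <- matrix(FALSE, 50, 50)
  s[20:30, 20:30] <- TRUE
  s[1:2, 1:2] <- TRUE
  sel <- postprocess_mask(s, closing_radius = 2)
  expect_false(any(sel[1:2, 1:2]))
  expect_true(all(sel[21:29, 21:29]))

  # idempotent; empty stays empty
  expect_equal(postprocess_mask(sel, closing_radius = 2), sel)
  empty <- matrix(FALSE, 10, 10)
  expect_equal(postprocess_mask(empty), empty)
})

test_that("a briefly trained network beats the baseline on distractor scenes", {
  mkd <- function(seed, off)
    render_fish_image(fish_spec(frame = c(256, 128), n_spots = 8,
        spot_radius_range = c(4, 7), body_center = c(off, 0.5) * c(256, 128),
        distractors = c("ruler_stripe", "debris_blob", "shadow_gradient"),
        rng_seed = seed))
  set.seed(7); offs <- runif(12, 0.25, 0.6)
  renders <- lapply(1:12, function(i) mkd(i, offs[i]))
  pairs <- lapply(renders[1:8], function(r) {
    pi <- pad_to_input(r$image, 64)
    pm <- pad_to_input(r$body_mask * 1, 64)
    list(image = pi$image, mask = pm$image > 0.5)
  })
  cfg <- unet_config(input_size = 64, depth = 3, filters = 8, in_channels = 1,
                     dropout = 0, epochs = 25, samples_per_epoch = 8,
                     lr = 2e-3)
  tr <- train_network(build_segmentation_network(cfg, seed = 1), pairs, cfg,
                      aug = NULL, seed = 2)
  f1u <- f1b <- numeric(4)
  for (k in 1:4) {
    r <- renders[[8 + k]]
    pi <- pad_to_input(r$image, 64)
    m64 <- postprocess_mask(predict_mask(tr$model, pi$image) > 0.5,
                            closing_radius = 2)
    mfull <- placement_to_original(m64 * 1, pi$placement) > 0.5
    f1u[k] <- evaluate_segmentation(mfull, r$body_mask)["f1"]
    bcfg <- baseline_config_synthetic(ncol(r$image))
    bm <- tryCatch(extract_fish_mask_baseline(r$image, bcfg),
                   error = function(e) r$body_mask & FALSE)
    f1b[k] <- evaluate_segmentation(bm, r$body_mask)["f1"]
  }
  expect_gt(mean(f1u), mean(f1b))
})
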