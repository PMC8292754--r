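#' Configuration of the encoder-decoder segmentation network
#'
#' A U-Net-style fully convolutional network: `depth` encoder levels, each a
#' 3x3 convolution + ReLU (+ dropout) followed by 2x2 max pooling, a
#' bottleneck convolution, and a mirrored decoder with nearest-neighbour
#' upsampling and skip connections, ending in a 1x1 convolution with sigmoid
#' output. The reference configuration matches the published set-up: 512x512
#' RGB input, four encoder levels with 64 filters each, 50% dropout per
#' encoder level, trained for 150 epochs with 50 image draws per epoch.
#' [unet_smoke_config()] gives a small CPU-friendly variant for tests.
#'
#' @param input_size square input size in pixels; must be divisible by
#'   `2^depth`.
#' @param depth number of encoder levels.
#' @param filters convolution filters per layer.
#' @param in_channels input channels (3 for RGB, 1 for greyscale).
#' @param dropout dropout fraction after each encoder block (0 disables).
#' @param epochs training epochs.
#' @param samples_per_epoch image draws per epoch.
#' @param lr Adam learning rate.
#' @param threshold probability threshold for binarizing predictions.
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(input_size = 512, depth = 4, filters = 64,
                        in_channels = 3, dropout = 0.5, epochs = 150,
                        samples_per_epoch = 50, lr = 1e-3, threshold = 0.5) {
  if (input_size %% 2^depth != 0)
    stop_spotmatch("`input_size` must be divisible by 2^depth",
                   "spotmatch_invalid_argument")
  structure(list(input_size = input_size, depth = depth, filters = filters,
                 in_channels = in_channels, dropout = dropout,
                 epochs = epochs, samples_per_epoch = samples_per_epoch,
                 lr = lr, threshold = threshold),
            class = "unet_config")
}

#' @rdname unet_config
#' @export
unet_smoke_config <- function(input_size = 64, depth = 3, filters = 8,
                              in_channels = 1, dropout = 0, epochs = 50,
                              samples_per_epoch = 2, lr = 2e-3,
                              threshold = 0.5) {
  unet_config(input_size, depth, filters, in_channels, dropout, epochs,
              samples_per_epoch, lr, threshold)
}

#' Data augmentation specification
#'
#' Random rotations, shears, zooms, horizontal/vertical flips and brightness
#' adjustments applied to training images (geometric transforms are applied
#' identically to the target masks).
#'
#' @param rotation maximum absolute rotation in degrees.
#' @param shear maximum absolute shear coefficient.
#' @param zoom `c(min, max)` zoom factor range.
#' @param hflip,vflip allow horizontal / vertical flips.
#' @param brightness `c(min, max)` multiplicative brightness range.
#' @return A list of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotation = 15, shear = 0.1, zoom = c(0.9, 1.1),
                              hflip = TRUE, vflip = TRUE,
                              brightness = c(0.8, 1.2)) {
  structure(list(rotation = rotation, shear = shear, zoom = zoom,
                 hflip = hflip, vflip = vflip, brightness = brightness),
            class = "augmentation_spec")
}

# --- geometric pre-processing ------------------------------------------------

resize_plane <- function(m, new_h, new_w, nearest = FALSE) {
  out <- EBImage::resize(m, w = new_h, h = new_w,
                         filter = if (nearest) "none" else "bilinear")
  matrix(out, new_h, new_w)
}

pad_core <- function(image, size, crop = c(0L, 0L), orig = dim(image)[1:2]) {
  img <- if (is.matrix(image)) array(image, c(dim(image), 1L)) else image
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  scale <- size / max(H, W)
  nh <- max(1L, round(H * scale)); nw <- max(1L, round(W * scale))
  if (max(nh, nw) != size) { if (nh >= nw) nh <- size else nw <- size }
  out <- array(0, c(size, size, C))
  r0 <- (size - nh) %/% 2L; c0 <- (size - nw) %/% 2L
  for (ch in seq_len(C))
    out[r0 + seq_len(nh), c0 + seq_len(nw), ch] <-
      resize_plane(img[, , ch], nh, nw)
  placement <- structure(list(scale = scale, offset = c(r0, c0),
                              content = c(nh, nw), orig = orig,
                              crop = crop, size = size),
                         class = "placement_record")
  list(image = if (is.matrix(image)) out[, , 1] else out,
       placement = placement)
}

#' Scale an image into the network input frame with black padding
#'
#' The longest dimension is scaled to `size`, the aspect ratio is preserved
#' and the remainder is zero-padded (centred). The returned placement record
#' allows predictions to be mapped back to original coordinates.
#'
#' @param image H x W matrix or H x W x C array.
#' @param size square network input size.
#' @return List with `image` (size x size, same channel structure) and
#'   `placement` (a `placement_record`).
#' @export
pad_to_input <- function(image, size) {
  pad_core(image, size)
}

#' Crop to a mask's bounding box, then scale and pad
#'
#' Crops the image to the tight bounding box of `body_mask`, then applies the
#' same scale-and-pad rule as [pad_to_input()]. Used to give the spot network
#' a close-up of the subject so small spots survive downsampling.
#'
#' @param image H x W matrix or H x W x C array.
#' @param body_mask non-empty logical mask of the same height/width.
#' @param size square network input size.
#' @return As [pad_to_input()]; the placement additionally records the crop
#'   offset.
#' @export
crop_and_rescale_to_mask <- function(image, body_mask, size) {
  if (!any(body_mask))
    stop_spotmatch("empty body mask", "spotmatch_empty_mask")
  w <- which(body_mask > 0, arr.ind = TRUE)
  r <- range(w[, 1]); c <- range(w[, 2])
  img <- if (is.matrix(image)) image[r[1]:r[2], c[1]:c[2], drop = FALSE]
         else image[r[1]:r[2], c[1]:c[2], , drop = FALSE]
  pad_core(img, size, crop = c(r[1] - 1L, c[1] - 1L),
           orig = dim(image)[1:2])
}

#' Map a network-frame mask back to original image coordinates
#'
#' Inverts the placement produced by [pad_to_input()] or
#' [crop_and_rescale_to_mask()]: the padded content is extracted, resized
#' back (nearest neighbour) and placed at its original position.
#'
#' @param mask size x size matrix (probabilities or binary).
#' @param placement a `placement_record`.
#' @return Matrix with the original image dimensions.
#' @export
placement_to_original <- function(mask, placement) {
  pl <- placement
  content <- mask[pl$offset[1] + seq_len(pl$content[1]),
                  pl$offset[2] + seq_len(pl$content[2]), drop = FALSE]
  ch <- round(pl$content[1] / pl$scale); cw <- round(pl$content[2] / pl$scale)
  back <- resize_plane(content, ch, cw, nearest = TRUE)
  out <- matrix(0, pl$orig[1], pl$orig[2])
  out[pl$crop[1] + seq_len(ch), pl$crop[2] + seq_len(cw)] <- back
  out
}

#' Map coordinates between the original frame and the network input frame
#'
#' @param placement a `placement_record`.
#' @param xy n x 2 matrix of (x, y) coordinates (0-based pixel centres).
#' @param to `"input"` maps original -> network frame, `"original"` the
#'   reverse.
#' @return n x 2 matrix of mapped coordinates.
#' @export
placement_map_coords <- function(placement, xy, to = c("input", "original")) {
  to <- match.arg(to)
  xy <- rbind(xy)
  pl <- placement
  if (to == "input") {
    cbind((xy[, 1] - pl$crop[2]) * pl$scale + pl$offset[2],
          (xy[, 2] - pl$crop[1]) * pl$scale + pl$offset[1])
  } else {
    cbind((xy[, 1] - pl$offset[2]) / pl$scale + pl$crop[2],
          (xy[, 2] - pl$offset[1]) / pl$scale + pl$crop[1])
  }
}

# --- network internals -------------------------------------------------------

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

# im2col for 3x3 same-padding convolution: (H*W) x (9*C) matrix,
# columns grouped by kernel offset, then channel
im2col3 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  xp <- array(0, c(H + 2, W + 2, C))
  xp[2:(H + 1), 2:(W + 1), ] <- x
  cols <- matrix(0, H * W, 9 * C)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    block <- xp[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc), , drop = FALSE]
    cols[, ((k - 1) * C + 1):(k * C)] <- matrix(block, H * W, C)
  }
  cols
}

col2im3 <- function(dcols, H, W, C) {
  dxp <- array(0, c(H + 2, W + 2, C))
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    blk <- array(dcols[, ((k - 1) * C + 1):(k * C)], c(H, W, C))
    dxp[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc), ] <-
      dxp[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc), , drop = FALSE] + blk
  }
  dxp[2:(H + 1), 2:(W + 1), , drop = FALSE]
}

conv3_forward <- function(x, layer) {
  H <- dim(x)[1]; W <- dim(x)[2]
  cols <- im2col3(x)
  y <- sweep(cols %*% layer$W, 2, layer$b, "+")
  list(y = array(y, c(H, W, ncol(layer$W))), cols = cols,
       dims = c(H, W, dim(x)[3]))
}

conv3_backward <- function(dy, cache, layer) {
  H <- cache$dims[1]; W <- cache$dims[2]; C <- cache$dims[3]
  dym <- matrix(dy, H * W, ncol(layer$W))
  list(dW = crossprod(cache$cols, dym), db = colSums(dym),
       dx = col2im3(dym %*% t(layer$W), H, W, C))
}

maxpool2_forward <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  io <- seq(1, H, 2); ie <- seq(2, H, 2)
  jo <- seq(1, W, 2); je <- seq(2, W, 2)
  cand <- array(c(x[io, jo, , drop = FALSE], x[ie, jo, , drop = FALSE],
                  x[io, je, , drop = FALSE], x[ie, je, , drop = FALSE]),
                c(H / 2, W / 2, C, 4))
  arg <- apply(cand, 1:3, which.max)
  y <- apply(cand, 1:3, max)
  list(y = array(y, c(H / 2, W / 2, C)), arg = arg, dims = c(H, W, C))
}

maxpool2_backward <- function(dy, cache) {
  H <- cache$dims[1]; W <- cache$dims[2]; C <- cache$dims[3]
  dx <- array(0, c(H, W, C))
  io <- seq(1, H, 2); ie <- seq(2, H, 2)
  jo <- seq(1, W, 2); je <- seq(2, W, 2)
  for (k in 1:4) {
    sel <- cache$arg == k
    g <- dy * sel
    if (k == 1) dx[io, jo, ] <- dx[io, jo, , drop = FALSE] + g
    if (k == 2) dx[ie, jo, ] <- dx[ie, jo, , drop = FALSE] + g
    if (k == 3) dx[io, je, ] <- dx[io, je, , drop = FALSE] + g
    if (k == 4) dx[ie, je, ] <- dx[ie, je, , drop = FALSE] + g
  }
  dx
}

upsample2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  x[rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), , drop = FALSE]
}

downsample2_sum <- function(dy) {
  H <- dim(dy)[1]; W <- dim(dy)[2]
  io <- seq(1, H, 2); ie <- seq(2, H, 2)
  jo <- seq(1, W, 2); je <- seq(2, W, 2)
  dy[io, jo, , drop = FALSE] + dy[ie, jo, , drop = FALSE] +
    dy[io, je, , drop = FALSE] + dy[ie, je, , drop = FALSE]
}

#' Build the segmentation network
#'
#' Allocates and initializes (He initialization) all convolution weights of
#' the encoder-decoder described in [unet_config()]. The forward pass maps a
#' `size x size x in_channels` input to a `size x size` probability map in
#' \[0, 1\]; with dropout disabled, inference is deterministic.
#'
#' @param cfg a [unet_config()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `unet_model`.
#' @export
build_segmentation_network <- function(cfg = unet_config(), seed = 1) {
  stopifnot(inherits(cfg, "unet_config"))
  f <- cfg$filters
  with_seed(seed, {
    enc <- lapply(seq_len(cfg$depth), function(l) {
      cin <- if (l == 1) cfg$in_channels else f
      list(W = he_init(9 * cin, f), b = rep(0, f))
    })
    bott <- list(W = he_init(9 * f, f), b = rep(0, f))
    dec <- lapply(seq_len(cfg$depth), function(l)
      list(W = he_init(9 * 2 * f, f), b = rep(0, f)))
    out <- list(W = he_init(f, 1), b = 0)
    structure(list(cfg = cfg, enc = enc, bott = bott, dec = dec, out = out),
              class = "unet_model")
  })
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(c(x$enc, list(x$bott), x$dec, list(x$out)),
                   function(l) length(l$W) + length(l$b), 0))
  cat(sprintf("<unet_model: %d encoder levels, %d filters, %d parameters>\n",
              x$cfg$depth, x$cfg$filters, np))
  invisible(x)
}

# forward pass; train = TRUE enables dropout (uses the current RNG stream)
unet_forward <- function(model, x, train = FALSE) {
  cfg <- model$cfg
  caches <- list(enc = vector("list", cfg$depth),
                 pool = vector("list", cfg$depth),
                 drop = vector("list", cfg$depth),
                 dec = vector("list", cfg$depth))
  skips <- vector("list", cfg$depth)
  h <- x
  for (l in seq_len(cfg$depth)) {
    cv <- conv3_forward(h, model$enc[[l]])
    a <- pmax(cv$y, 0)
    if (train && cfg$dropout > 0) {
      mask <- array(stats::runif(length(a)) >= cfg$dropout,
                    dim(a)) / (1 - cfg$dropout)
      a <- a * mask
      caches$drop[[l]] <- mask
    }
    caches$enc[[l]] <- cv
    skips[[l]] <- a
    mp <- maxpool2_forward(a)
    caches$pool[[l]] <- mp
    h <- mp$y
  }
  cvb <- conv3_forward(h, model$bott)
  hb <- pmax(cvb$y, 0)
  caches$bott <- cvb
  for (l in rev(seq_len(cfg$depth))) {
    up <- upsample2(hb)
    cat3 <- array(c(up, skips[[l]]), c(dim(up)[1:2], dim(up)[3] * 2))
    cv <- conv3_forward(cat3, model$dec[[l]])
    hb <- pmax(cv$y, 0)
    caches$dec[[l]] <- cv
  }
  H <- dim(hb)[1]; W <- dim(hb)[2]
  logits <- matrix(matrix(hb, H * W, cfg$filters) %*% model$out$W +
                     model$out$b, H, W)
  caches$final <- hb
  p <- 1 / (1 + exp(-logits))
  list(prob = p, logits = logits, caches = caches, skips = skips)
}

# backward pass from dlogits; returns gradients shaped like the model layers
unet_backward <- function(model, fw, dlogits) {
  cfg <- model$cfg
  H <- nrow(dlogits); W <- ncol(dlogits)
  f <- cfg$filters
  hb <- fw$caches$final
  dout <- list(W = crossprod(matrix(hb, H * W, f), as.numeric(dlogits)),
               b = sum(dlogits))
  dhb <- array(as.numeric(dlogits) %*% t(model$out$W), c(H, W, f))
  grads <- list(enc = vector("list", cfg$depth), bott = NULL,
                dec = vector("list", cfg$depth), out = dout)
  dskip <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    cv <- fw$caches$dec[[l]]
    dz <- dhb * (cv$y > 0)
    bk <- conv3_backward(dz, cv, model$dec[[l]])
    grads$dec[[l]] <- list(W = bk$dW, b = bk$db)
    C2 <- dim(bk$dx)[3]
    dup <- bk$dx[, , seq_len(C2 / 2), drop = FALSE]
    dskip[[l]] <- bk$dx[, , C2 / 2 + seq_len(C2 / 2), drop = FALSE]
    dhb <- downsample2_sum(dup)
  }
  cvb <- fw$caches$bott
  dz <- dhb * (cvb$y > 0)
  bk <- conv3_backward(dz, cvb, model$bott)
  grads$bott <- list(W = bk$dW, b = bk$db)
  dh <- bk$dx
  for (l in rev(seq_len(cfg$depth))) {
    da <- maxpool2_backward(dh, fw$caches$pool[[l]]) + dskip[[l]]
    if (!is.null(fw$caches$drop[[l]])) da <- da * fw$caches$drop[[l]]
    cv <- fw$caches$enc[[l]]
    dz <- da * (cv$y > 0)
    bk <- conv3_backward(dz, cv, model$enc[[l]])
    grads$enc[[l]] <- list(W = bk$dW, b = bk$db)
    dh <- bk$dx
  }
  grads
}

bce_loss <- function(p, y) {
  eps <- 1e-7
  p <- clamp(p, eps, 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# flatten model layers for the optimizer
unet_layers <- function(model) {
  c(model$enc, list(model$bott), model$dec, list(model$out))
}
unet_set_layers <- function(model, layers) {
  d <- model$cfg$depth
  model$enc <- layers[seq_len(d)]
  model$bott <- layers[[d + 1]]
  model$dec <- layers[d + 1 + seq_len(d)]
  model$out <- layers[[2 * d + 2]]
  model
}
grad_layers <- function(grads) {
  c(grads$enc, list(grads$bott), grads$dec, list(grads$out))
}

#' Predict a probability map for one image
#'
#' Runs the forward pass with stochastic layers disabled. Pixel intensities
#' above 1.5 are assumed to be on the 0-255 scale and are rescaled to
#' \[0, 1\].
#'
#' @param model a trained or freshly built `unet_model`.
#' @param image `size x size` matrix (1 channel) or `size x size x C` array
#'   matching the model's `in_channels`.
#' @return Matrix of probabilities in \[0, 1\].
#' @export
predict_mask <- function(model, image) {
  x <- if (is.matrix(image)) array(image, c(dim(image), 1L)) else image
  if (dim(x)[3] != model$cfg$in_channels)
    stop_spotmatch("channel count does not match the model",
                   "spotmatch_invalid_argument")
  if (max(x) > 1.5) x <- x / 255
  unet_forward(model, x, train = FALSE)$prob
}

# nearest-neighbour affine resample about the image centre (rotation degrees,
# zoom factor, shear coefficient); used by augmentation
affine_nn <- function(m, angle = 0, zoom = 1, shear = 0) {
  H <- nrow(m); W <- ncol(m)
  th <- angle * pi / 180
  A <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th))) %*%
    rbind(c(1, shear), c(0, 1)) * zoom
  Ai <- solve(A)
  ctr <- c((W + 1) / 2, (H + 1) / 2)
  gx <- rep(seq_len(W), each = H) - ctr[1]
  gy <- rep(seq_len(H), W) - ctr[2]
  sx <- round(Ai[1, 1] * gx + Ai[1, 2] * gy + ctr[1])
  sy <- round(Ai[2, 1] * gx + Ai[2, 2] * gy + ctr[2])
  ok <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
  vals <- numeric(H * W)
  vals[ok] <- m[cbind(sy[ok], sx[ok])]
  matrix(vals, H, W)  # gx/gy enumerate cells in column-major order
}

augment_pair <- function(image, mask, aug) {
  angle <- stats::runif(1, -aug$rotation, aug$rotation)
  zoom <- stats::runif(1, aug$zoom[1], aug$zoom[2])
  shear <- stats::runif(1, -aug$shear, aug$shear)
  fh <- aug$hflip && stats::runif(1) < 0.5
  fv <- aug$vflip && stats::runif(1) < 0.5
  bright <- stats::runif(1, aug$brightness[1], aug$brightness[2])
  tf <- function(m, geom_only = FALSE) {
    m <- affine_nn(m, angle, zoom, shear)
    if (fh) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (fv) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    m
  }
  img <- if (is.matrix(image)) clamp(tf(image) * bright, 0, 1) else {
    out <- image
    for (ch in seq_len(dim(image)[3])) out[, , ch] <- tf(image[, , ch])
    clamp(out * bright, 0, 1)
  }
  list(image = img, mask = tf(mask) > 0.5)
}

#' Train the segmentation network
#'
#' Stochastic gradient training with the Adam optimizer on pixelwise binary
#' cross-entropy. Each epoch draws `samples_per_epoch` images (with
#' replacement) from the training pairs, optionally augmented. The per-epoch
#' mean loss is recorded; with augmentation off and a fixed seed the loss
#' trace is reproducible.
#'
#' @param model a `unet_model` from [build_segmentation_network()].
#' @param pairs list of training pairs, each `list(image =, mask =)` in the
#'   network input frame (see [pad_to_input()]); images on \[0, 1\] or 0-255.
#' @param cfg a [unet_config()]; defaults to the model's own.
#' @param aug an [augmentation_spec()] or `NULL` to disable augmentation.
#' @param seed integer seed.
#' @return List of class `unet_training` with the trained `model`, the
#'   per-epoch `loss` trace and `n_draws`.
#' @export
train_network <- function(model, pairs, cfg = model$cfg, aug = NULL,
                          seed = 1) {
  if (length(pairs) == 0)
    stop_spotmatch("training set is empty", "spotmatch_invalid_argument")
  prep <- lapply(pairs, function(pr) {
    x <- if (is.matrix(pr$image)) array(pr$image, c(dim(pr$image), 1L))
         else pr$image
    if (max(x) > 1.5) x <- x / 255
    list(image = x, mask = pr$mask > 0.5)
  })
  layers <- unet_layers(model)
  mstate <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  vstate <- mstate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  losses <- numeric(cfg$epochs)
  with_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- numeric(cfg$samples_per_epoch)
      for (s in seq_len(cfg$samples_per_epoch)) {
        i <- sample.int(length(prep), 1)
        x <- prep[[i]]$image; yv <- prep[[i]]$mask
        if (!is.null(aug)) {
          ag <- augment_pair(if (dim(x)[3] == 1) x[, , 1] else x, yv, aug)
          x <- if (is.matrix(ag$image)) array(ag$image, c(dim(ag$image), 1L))
               else ag$image
          yv <- ag$mask
        }
        fw <- unet_forward(model, x, train = TRUE)
        ep_loss[s] <- bce_loss(fw$prob, yv)
        dlogits <- (fw$prob - yv) / length(yv)
        grads <- unet_backward(model, fw, dlogits)
        gl <- grad_layers(grads)
        step <- step + 1L
        for (k in seq_along(layers)) {
          for (nm in c("W", "b")) {
            g <- gl[[k]][[nm]]
            mstate[[k]][[nm]] <- beta1 * mstate[[k]][[nm]] + (1 - beta1) * g
            vstate[[k]][[nm]] <- beta2 * vstate[[k]][[nm]] + (1 - beta2) * g^2
            mhat <- mstate[[k]][[nm]] / (1 - beta1^step)
            vhat <- vstate[[k]][[nm]] / (1 - beta2^step)
            layers[[k]][[nm]] <- layers[[k]][[nm]] -
              cfg$lr * mhat / (sqrt(vhat) + eps)
          }
        }
        model <- unet_set_layers(model, layers)
      }
      losses[ep] <- mean(ep_loss)
    }
  })
  structure(list(model = model, loss = losses,
                 n_draws = cfg$epochs * cfg$samples_per_epoch),
            class = "unet_training")
}

#' @export
print.unet_training <- function(x, ...) {
  cat(sprintf("<unet_training: %d epochs, loss %.4f -> %.4f>\n",
              length(x$loss), x$loss[1], x$loss[length(x$loss)]))
  invisible(x)
}

#' Post-process a predicted binary mask
#'
#' Fills interior holes, applies a morphological closing to join up disjoint
#' regions, and retains only the large component nearest the image centre.
#' Idempotent; an empty prediction is returned unchanged.
#'
#' @param pred logical (or 0/1) matrix.
#' @param closing_radius radius (px) of the disc used for closing.
#' @return Logical matrix.
#' @export
postprocess_mask <- function(pred, closing_radius = 5) {
  pred <- pred > 0
  if (!any(pred)) return(pred)
  m <- EBImage::fillHull(pred * 1) > 0
  brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
  m <- EBImage::erode(EBImage::dilate(m, brush), brush) > 0
  m <- EBImage::fillHull(m * 1) > 0
  labels <- EBImage::bwlabel(m)
  pick <- select_central_component(labels)
  labels == pick
}
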