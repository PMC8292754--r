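#' Generate a random spot constellation
#'
#' Draws `n_spots` spot centres uniformly inside the frame (inset by the
#' maximum spot radius) subject to a minimum pairwise separation, so synthetic
#' spots never merge. By default the separation is twice the maximum spot
#' radius. Sizes are disc areas from radii drawn uniformly in
#' `spot_radius_range`.
#'
#' @param n_spots number of spots (>= 0).
#' @param frame `c(width, height)` in pixels.
#' @param seed integer seed; the call is deterministic given the seed.
#' @param spot_radius_range `c(min, max)` spot radius in pixels.
#' @param min_separation minimum centre-to-centre distance; defaults to twice
#'   the maximum spot radius.
#' @return A [spotset()] in pixel coordinates.
#' @examples
#' s <- generate_constellation(30, frame = c(1000, 400), seed = 1)
#' n_spots(s)
#' @export
generate_constellation <- function(n_spots, frame = c(1882, 830), seed = 1,
                                   spot_radius_range = c(12, 20),
                                   min_separation = 2 * max(spot_radius_range)) {
  if (!is.numeric(n_spots) || length(n_spots) != 1L || n_spots < 0)
    stop_spotmatch("`n_spots` must be a non-negative count",
                   "spotmatch_invalid_argument")
  if (any(frame <= 0)) stop_spotmatch("`frame` must be positive",
                                      "spotmatch_invalid_argument")
  n_spots <- as.integer(n_spots)
  if (n_spots == 0L) return(spotset(frame = frame))
  rmax <- max(spot_radius_range)
  with_seed(seed, {
    xs <- ys <- numeric(0)
    tries <- 0L
    while (length(xs) < n_spots && tries < 20000L) {
      tries <- tries + 1L
      px <- stats::runif(1, rmax, frame[1] - rmax)
      py <- stats::runif(1, rmax, frame[2] - rmax)
      if (length(xs) == 0L ||
          min(sqrt((xs - px)^2 + (ys - py)^2)) >= min_separation) {
        xs <- c(xs, px); ys <- c(ys, py)
      }
    }
    if (length(xs) < n_spots)
      stop_spotmatch("could not place spots at the requested separation",
                     "spotmatch_invalid_argument")
    r <- stats::runif(n_spots, spot_radius_range[1], spot_radius_range[2])
    spotset(xs, ys, pi * r^2, frame = frame)
  })
}

#' Perturb a constellation into a synthetic re-capture
#'
#' Applies a similarity transform (rotation and scale about the constellation
#' centroid, then translation), positional jitter, spot turnover (dropped
#' spots) and new spots, returning the perturbed constellation together with
#' the ground-truth correspondence. This emulates the variation between two
#' photographs of the same individual: pose differences, growth between
#' captures and spot turnover.
#'
#' `floor(n * drop_fraction)` spots are removed uniformly at random; retained
#' spots keep their original relative order and added spots are appended, so
#' the identity perturbation is exactly the identity.
#'
#' @param spots a non-empty [spotset()].
#' @param rotation rotation in degrees (counter-clockwise in the x-right,
#'   y-down convention).
#' @param scale uniform growth factor (> 0); spot sizes scale with its square.
#' @param translation `c(dx, dy)` in the same units as the coordinates.
#' @param jitter_sd standard deviation of isotropic Gaussian jitter.
#' @param drop_fraction fraction of spots that disappear, in \[0, 1\].
#' @param add_count number of new spots without correspondence.
#' @param seed integer seed.
#' @return A list with elements `spots` (the perturbed [spotset()]) and
#'   `correspondence`, a two-column matrix mapping surviving original indices
#'   to new indices.
#' @examples
#' s <- generate_constellation(20, seed = 1)
#' p <- perturb_constellation(s, rotation = 10, jitter_sd = 0, seed = 2)
#' head(p$correspondence)
#' @export
perturb_constellation <- function(spots, rotation = 0, scale = 1,
                                  translation = c(0, 0), jitter_sd = 0,
                                  drop_fraction = 0, add_count = 0, seed = 1) {
  if (!inherits(spots, "spotset") || n_spots(spots) == 0L)
    stop_spotmatch("`spots` must be a non-empty spotset",
                   "spotmatch_invalid_argument")
  check_prob(drop_fraction, "drop_fraction")
  check_positive(scale, "scale")
  n <- n_spots(spots)
  with_seed(seed, {
    keep <- sort(sample.int(n, n - floor(n * drop_fraction)))
    ctr <- c(mean(spots$x), mean(spots$y))
    P <- cbind(spots$x[keep], spots$y[keep])
    P <- sweep(P, 2, ctr) %*% t(rot2(rotation)) * scale
    P <- sweep(P, 2, ctr + translation, "+")
    if (jitter_sd > 0)
      P <- P + matrix(stats::rnorm(length(P), 0, jitter_sd), ncol = 2)
    sizes <- spots$size[keep] * scale^2
    add_count <- as.integer(add_count)
    if (add_count > 0L) {
      # added spots appear within the constellation's bounding box (the
      # original box when every spot was dropped)
      ref <- if (nrow(P) > 0) P else cbind(spots$x, spots$y)
      lo <- apply(ref, 2, min); hi <- apply(ref, 2, max)
      if (any(hi - lo <= 0)) { lo <- lo - 1; hi <- hi + 1 }
      P <- rbind(P, cbind(stats::runif(add_count, lo[1], hi[1]),
                          stats::runif(add_count, lo[2], hi[2])))
      size_ref <- if (length(sizes) > 0) sizes else spots$size * scale^2
      sizes <- c(sizes, rep(stats::median(size_ref), add_count))
    }
    out <- spotset(P[, 1], P[, 2], sizes, frame = spots$frame,
                   normalized = spots$normalized,
                   length_scale = spots$length_scale)
    corr <- cbind(from = keep, to = seq_along(keep))
    list(spots = out, correspondence = corr)
  })
}

#' Synthetic re-capture under the default study conditions
#'
#' Convenience wrapper around [perturb_constellation()] drawing the
#' perturbation parameters of a typical re-capture: rotation uniform within
#' +/- `rotation_max` degrees, growth scale uniform in `scale_range`
#' (fish grow between captures), small positional jitter, and
#' `turnover_fraction` of spots dropped plus the same number added.
#'
#' @param spots a normalized [spotset()].
#' @param seed integer seed.
#' @param rotation_max maximum absolute rotation, degrees.
#' @param scale_range growth factor range.
#' @param jitter_sd jitter standard deviation (fish-length units).
#' @param turnover_fraction fraction of spots dropped and fraction added.
#' @return As [perturb_constellation()].
#' @export
perturb_recapture <- function(spots, seed = 1, rotation_max = 10,
                              scale_range = c(1.0, 1.3), jitter_sd = 0.005,
                              turnover_fraction = 0.1) {
  pars <- with_seed(seed + 777L, list(
    rot = stats::runif(1, -rotation_max, rotation_max),
    sc = stats::runif(1, scale_range[1], scale_range[2]),
    tr = stats::runif(2, -0.02, 0.02)))
  perturb_constellation(spots, rotation = pars$rot, scale = pars$sc,
                        translation = pars$tr, jitter_sd = jitter_sd,
                        drop_fraction = turnover_fraction,
                        add_count = floor(n_spots(spots) * turnover_fraction),
                        seed = seed)
}

#' Specification of a synthetic fish image
#'
#' Describes the rendered scene: an egg-shaped dark body (blunt head end,
#' tapering tail end) with dark, roughly circular spots, on a light
#' background, optionally with distractors resembling field photographs
#' (ruler stripes, debris, a shadow gradient). Intensity invariant:
#' `spot_level < body_level < background_level`.
#'
#' @param frame `c(width, height)` pixels.
#' @param body_center body centre, defaults to the frame centre.
#' @param body_axes `c(a, b)` semi-axes of the body outline in pixels.
#' @param body_rotation body orientation in degrees.
#' @param n_spots number of spots on the flank.
#' @param spot_radius_range `c(min, max)` spot radius in pixels.
#' @param background_level,body_level,spot_level grey levels in \[0, 255\].
#' @param distractors character vector among `"ruler_stripe"`,
#'   `"debris_blob"`, `"shadow_gradient"`.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param rng_seed integer seed.
#' @return An object of class `fish_spec`.
#' @export
fish_spec <- function(frame = c(1882, 830), body_center = frame / 2,
                      body_axes = c(0.33 * frame[1], 0.23 * frame[2]),
                      body_rotation = 0, n_spots = 30,
                      spot_radius_range = c(14, 22),
                      background_level = 210, body_level = 60,
                      spot_level = 20, distractors = character(),
                      noise_sd = 4, rng_seed = 1) {
  if (!(spot_level < body_level && body_level < background_level))
    stop_spotmatch("need spot_level < body_level < background_level",
                   "spotmatch_invalid_argument")
  if (max(spot_radius_range) > min(body_axes))
    stop_spotmatch("spot radius exceeds the minor body axis",
                   "spotmatch_invalid_argument")
  bad <- setdiff(distractors, c("ruler_stripe", "debris_blob", "shadow_gradient"))
  if (length(bad))
    stop_spotmatch(paste("unknown distractor:", paste(bad, collapse = ", ")),
                   "spotmatch_invalid_argument")
  structure(list(frame = frame, body_center = body_center,
                 body_axes = body_axes, body_rotation = body_rotation,
                 n_spots = n_spots, spot_radius_range = spot_radius_range,
                 background_level = background_level, body_level = body_level,
                 spot_level = spot_level, distractors = distractors,
                 noise_sd = noise_sd, rng_seed = rng_seed),
            class = "fish_spec")
}

# body half-height profile: egg-shaped trunk (blunt head end at negative u)
# with a thin caudal tail extending to u = 1.25. The tail makes the mass
# distribution decisively skewed along the major axis, so the alignment's
# 180-degree disambiguation is stable.
egg_profile <- function(u) {
  trunk <- sqrt(pmax(0, 1 - u^2)) * (1 - 0.30 * u)
  tail <- ifelse(u > 0.8 & u <= 1.25, 0.28 * (1 - (u - 0.8) / 0.9), 0)
  pmax(trunk, tail)
}

#' Render a synthetic fish photograph with ground-truth masks
#'
#' Draws the body and spots of `spec` onto a light background, adds the
#' requested distractors and Gaussian noise, and returns the image together
#' with the ground-truth body and spot masks and the spot constellation in
#' pixel coordinates. The spot mask is a subset of the body mask by
#' construction. Deterministic given `spec$rng_seed`.
#'
#' @param spec a [fish_spec()].
#' @return A list with `image` (H x W matrix, grey levels 0-255),
#'   `body_mask`, `spot_mask` (logical H x W matrices), `spots` (a
#'   [spotset()]) and `spec`.
#' @examples
#' r <- render_fish_image(fish_spec(frame = c(400, 180), n_spots = 10,
#'                                  spot_radius_range = c(4, 6)))
#' dim(r$image)
#' @export
render_fish_image <- function(spec) {
  stopifnot(inherits(spec, "fish_spec"))
  W <- as.integer(spec$frame[1]); H <- as.integer(spec$frame[2])
  a <- spec$body_axes[1]; b <- spec$body_axes[2]
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  R <- rot2(spec$body_rotation)  # image offsets -> body frame (row vectors)
  dx <- xs - spec$body_center[1]; dy <- ys - spec$body_center[2]
  u <- (R[1, 1] * dx + R[2, 1] * dy) / a
  v <- R[1, 2] * dx + R[2, 2] * dy
  h <- b * egg_profile(u)
  body <- u > -1 & u < 1.25 & abs(v) < h & h > 0

  with_seed(spec$rng_seed, {
    # spot centres inside the body, in body coordinates, min separation
    # twice the maximum radius so spots stay distinct
    rmax <- max(spec$spot_radius_range)
    su <- sv <- numeric(0)
    tries <- 0L
    while (length(su) < spec$n_spots && tries < 50000L) {
      tries <- tries + 1L
      cu <- stats::runif(1, -0.92, 0.92)
      cv <- stats::runif(1, -1, 1) * (b * egg_profile(cu) - rmax - 1)
      if (b * egg_profile(cu) <= rmax + 1) next
      if (length(su)) {
        d2 <- (su * a - cu * a)^2 + (sv - cv)^2
        if (min(d2) < (2 * rmax)^2) next
      }
      su <- c(su, cu); sv <- c(sv, cv)
    }
    if (length(su) < spec$n_spots)
      stop_spotmatch("could not place the requested number of spots",
                     "spotmatch_invalid_argument")
    sr <- if (spec$n_spots > 0)
      stats::runif(spec$n_spots, spec$spot_radius_range[1],
                   spec$spot_radius_range[2]) else numeric(0)

    spot <- matrix(FALSE, H, W)
    Rf <- rot2(spec$body_rotation)
    px <- py <- numeric(length(su))
    for (i in seq_along(su)) {
      ctr <- c(su[i] * a, sv[i]) %*% t(Rf)
      px[i] <- ctr[1] + spec$body_center[1]
      py[i] <- ctr[2] + spec$body_center[2]
      spot <- spot | ((xs - px[i])^2 + (ys - py[i])^2 <= sr[i]^2)
    }
    spot <- spot & body

    img <- matrix(spec$background_level, H, W)
    if ("shadow_gradient" %in% spec$distractors)
      img <- img * (0.6 + 0.4 * xs / W)
    if ("ruler_stripe" %in% spec$distractors) {
      # solid dark ruler bar with bright ticks along the bottom edge
      band <- ys > 0.9 * H
      img[band] <- 45
      tick <- band & (xs %% max(2, round(0.0425 * W))) < 0.0064 * W
      img[tick] <- 170
    }
    if ("debris_blob" %in% spec$distractors) {
      for (k in 1:6) {
        bx <- stats::runif(1, 0, W); by <- stats::runif(1, 0, H * 0.85)
        br <- stats::runif(1, 0.011, 0.024) * W
        blob <- (xs - bx)^2 + (ys - by)^2 <= br^2
        img[blob & !body] <- 30
      }
    }
    img[body] <- spec$body_level
    img[spot] <- spec$spot_level
    img <- clamp(img + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W),
                 0, 255)

    list(image = img, body_mask = body, spot_mask = spot,
         spots = spotset(px, py, pi * sr^2, frame = c(W, H)), spec = spec)
  })
}

#' Simulate capture histories under the Cormack-Jolly-Seber model
#'
#' Forward simulation of the survival/capture model: an individual alive at
#' occasion t-1 survives to t with probability `phi`; an individual alive at
#' t (after its first capture) is captured with probability `p`. Each row has
#' a 1 at its first-capture occasion; first captures are spread uniformly over
#' occasions 1..T-1.
#'
#' @param n_individuals number of individuals.
#' @param n_occasions number of capture occasions T (>= 2).
#' @param phi per-interval survival probability.
#' @param p capture probability.
#' @param seed integer seed.
#' @return An `n x T` binary matrix with row names `ind1..indn`, with
#'   attributes `first` (first-capture occasion per row) and `alive` (the
#'   simulated latent alive states, hidden ground truth).
#' @examples
#' y <- simulate_capture_histories(50, 5, phi = 0.8, p = 0.5, seed = 1)
#' dim(y)
#' @export
simulate_capture_histories <- function(n_individuals, n_occasions, phi, p,
                                       seed = 1) {
  check_prob(phi, "phi"); check_prob(p, "p")
  if (n_occasions < 2) stop_spotmatch("need at least two occasions",
                                      "spotmatch_invalid_argument")
  n <- as.integer(n_individuals); T <- as.integer(n_occasions)
  with_seed(seed, {
    first <- sample.int(T - 1L, n, replace = TRUE)
    alive <- matrix(FALSE, n, T)
    y <- matrix(0L, n, T)
    for (i in seq_len(n)) {
      f <- first[i]
      alive[i, f] <- TRUE
      y[i, f] <- 1L
      for (t in seq_len(T)[-seq_len(f)]) {
        alive[i, t] <- alive[i, t - 1] && stats::runif(1) < phi
        y[i, t] <- as.integer(alive[i, t] && stats::runif(1) < p)
      }
    }
    rownames(y) <- paste0("ind", seq_len(n))
    attr(y, "first") <- first
    attr(y, "alive") <- alive
    y
  })
}

#' Capture events of a history matrix
#'
#' @param y binary capture-history matrix with row names.
#' @return A data frame of capture events `(id, occasion)`, ordered by
#'   occasion then id.
#' @export
capture_records <- function(y) {
  w <- which(y == 1L, arr.ind = TRUE)
  out <- data.frame(id = rownames(y)[w[, 1]], occasion = as.integer(w[, 2]),
                    stringsAsFactors = FALSE)
  out[order(out$occasion, out$id), , drop = FALSE]
}

#' Fragment capture records by simulated tag loss
#'
#' At each recapture event (every capture after an individual's first), with
#' probability `rate` the tag is absent and the fish is re-tagged: the
#' observed id switches to a fresh, never-seen id from that event onwards.
#' First captures always keep their id (the tag is implanted then). True ids
#' are retained as hidden ground truth.
#'
#' @param records data frame of capture events `(id, occasion)` as returned
#'   by [capture_records()].
#' @param rate per-recapture probability of tag loss, in \[0, 1\].
#' @param seed integer seed.
#' @return The records with columns `observed_id` and `lost` added.
#' @examples
#' y <- simulate_capture_histories(20, 6, 0.8, 0.6, seed = 1)
#' r <- inject_tag_loss(capture_records(y), rate = 0.1, seed = 2)
#' head(r)
#' @export
inject_tag_loss <- function(records, rate, seed = 1) {
  check_prob(rate, "rate")
  records <- records[order(records$occasion, records$id), , drop = FALSE]
  with_seed(seed, {
    observed <- character(nrow(records))
    lost <- logical(nrow(records))
    current <- list()   # true id -> current observed id
    fresh <- 0L
    for (k in seq_len(nrow(records))) {
      id <- records$id[k]
      if (is.null(current[[id]])) {
        current[[id]] <- id
      } else if (rate > 0 && stats::runif(1) < rate) {
        fresh <- fresh + 1L
        current[[id]] <- sprintf("retag%04d", fresh)
        lost[k] <- TRUE
      }
      observed[k] <- current[[id]]
    }
    records$observed_id <- observed
    records$lost <- lost
    records
  })
}

#' Build a capture-history matrix from capture records
#'
#' @param records data frame with an id column and an `occasion` column.
#' @param n_occasions total number of occasions T.
#' @param id_col name of the id column (e.g. `"id"` or `"observed_id"`).
#' @return Binary matrix with one row per distinct id (in order of first
#'   appearance).
#' @export
histories_from_records <- function(records, n_occasions, id_col = "id") {
  ids <- unique(records[[id_col]])
  y <- matrix(0L, length(ids), n_occasions, dimnames = list(ids, NULL))
  y[cbind(match(records[[id_col]], ids), records$occasion)] <- 1L
  y
}
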