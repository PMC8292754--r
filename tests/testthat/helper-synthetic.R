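# Shared fixtures, all generated in code.

# a constellation in normalized (fish-length) units, as produced by pca_align
norm_constellation <- function(n, seed) {
  generate_constellation(n, frame = c(1, 0.33), seed = seed,
                         spot_radius_range = c(0.008, 0.012))
}

# a small, quick-to-render fish scene
small_fish <- function(seed = 1, ...) {
  render_fish_image(fish_spec(frame = c(256, 128), n_spots = 8,
                              spot_radius_range = c(4, 7), rng_seed = seed,
                              ...))
}

# an elliptical normalized mask raster (stand-in body for matcher tests)
ellipse_norm_mask <- function(step = 1 / 64, aspect = 0.3) {
  gx <- seq(-0.05, 1.05, by = step)
  gy <- seq(-0.05, aspect + 0.05, by = step)
  px <- outer(gy, gx, function(y, x)
    ((x - 0.5) / 0.5)^2 + ((y - aspect / 2) / (aspect / 2))^2 <= 1)
  norm_mask(px, origin = c(gx[1], gy[1]), step = step)
}

# brute-force mutual nearest neighbours (oracle for the k-d tree search)
brute_mutual_nn <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  nnAB <- apply(d2, 1, which.min)
  nnBA <- apply(d2, 2, which.min)
  keep <- which(nnBA[nnAB] == seq_len(nrow(A)))
  cbind(a = keep, b = nnAB[keep])
}

# exhaustive CJS likelihood: sum over all latent alive/dead trajectories
enumerate_cjs_likelihood <- function(history, phi, p) {
  T <- length(history)
  f <- which(history == 1)[1]
  if (f == T) return(1)
  steps <- T - f
  total <- 0
  for (code in 0:(2^steps - 1)) {
    alive <- as.logical(bitwAnd(code, 2^(0:(steps - 1))) > 0)
    prob <- 1
    prev_alive <- TRUE
    ok <- TRUE
    for (s in seq_len(steps)) {
      t <- f + s
      a <- alive[s]
      if (a && !prev_alive) { ok <- FALSE; break }  # no resurrection
      prob <- prob * if (prev_alive) (if (a) phi else 1 - phi) else 1
      y <- history[t]
      if (y == 1 && !a) { ok <- FALSE; break }
      prob <- prob * if (a) (if (y == 1) p else 1 - p) else 1
      prev_alive <- a
    }
    if (ok) total <- total + prob
  }
  total
}
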