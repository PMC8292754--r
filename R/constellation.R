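#' Convert a spot mask into a constellation
#'
#' One spot per connected component: position is the component centroid
#' (x right, y down, 0-based pixel centres), size is the pixel count (area).
#'
#' @param spot_mask logical (or 0/1) H x W matrix.
#' @return A [spotset()] in pixel coordinates (empty for an empty mask).
#' @examples
#' m <- matrix(FALSE, 30, 40); m[21:25, 11:15] <- TRUE
#' as.data.frame(spots_from_mask(m))  # centroid (12, 22), size 25
#' @export
spots_from_mask <- function(spot_mask) {
  labels <- EBImage::bwlabel(spot_mask > 0)
  n <- max(labels)
  H <- nrow(spot_mask); W <- ncol(spot_mask)
  if (n == 0) return(spotset(frame = c(W, H)))
  w <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[w]
  cx <- tapply(w[, 2] - 1, lab, mean)   # 0-based x = column - 1
  cy <- tapply(w[, 1] - 1, lab, mean)
  area <- tabulate(lab, nbins = n)
  spotset(as.numeric(cx), as.numeric(cy), area[as.integer(names(cx))],
          frame = c(W, H))
}

#' Normalized binary masks
#'
#' A `norm_mask` is a binary raster expressed in fish-length units: `step`
#' units per cell, with `origin` holding the coordinates of the centre of
#' cell `[1, 1]` (rows advance y, columns advance x).
#'
#' @param px logical matrix.
#' @param origin numeric `c(x0, y0)`.
#' @param step cell size in fish-length units.
#' @return An object of class `norm_mask`.
#' @export
norm_mask <- function(px, origin, step) {
  structure(list(px = px, origin = as.numeric(origin), step = as.numeric(step)),
            class = "norm_mask")
}

#' @export
print.norm_mask <- function(x, ...) {
  cat(sprintf("<norm_mask: %d x %d cells, step %.4f>\n",
              nrow(x$px), ncol(x$px), x$step))
  invisible(x)
}

# coordinates (fish-length units) of the TRUE cells of a norm_mask
norm_mask_coords <- function(nm) {
  w <- which(nm$px, arr.ind = TRUE)
  cbind(x = nm$origin[1] + (w[, 2] - 1) * nm$step,
        y = nm$origin[2] + (w[, 1] - 1) * nm$step)
}

# Alignment of a point cloud (mask pixel coordinates): rotation putting the
# first principal axis horizontal, 180-degree ambiguity resolved by requiring
# a negative third central moment along the major axis, then scaling by the
# extent along the major axis. Returns the transform parameters.
align_point_cloud <- function(P) {
  if (nrow(unique(P)) < 2)
    stop_spotmatch("mask has fewer than two distinct pixels",
                   "spotmatch_degenerate_mask")
  mu <- colMeans(P)
  cv <- stats::cov(P)
  eig <- eigen(cv, symmetric = TRUE)
  e1 <- eig$vectors[, 1]
  alpha <- atan2(e1[2], e1[1]) * 180 / pi
  U <- sweep(P, 2, mu) %*% rot2(alpha)  # rotate by -alpha (row vectors)
  if (mean(U[, 1]^3) > 0) {
    alpha <- alpha + 180
    U <- -U
  }
  alpha <- ((alpha + 180) %% 360) - 180
  L <- max(U[, 1]) - min(U[, 1])
  if (L <= 0)
    stop_spotmatch("mask extent is degenerate", "spotmatch_degenerate_mask")
  list(rotation = -alpha, centre = mu, mins = c(min(U[, 1]), min(U[, 2])),
       length_scale = L)
}

# apply an alignment (as returned by align_point_cloud) to row coordinates
apply_alignment <- function(align, P) {
  U <- sweep(P, 2, align$centre) %*% rot2(-align$rotation)
  sweep(U, 2, align$mins) / align$length_scale
}

#' Align and normalize a constellation by the body principal axes
#'
#' Rotates the body mask (and the spots with it) so its first principal axis
#' is horizontal and the second vertical, resolves the 180-degree ambiguity
#' by a fixed skewness convention (the third central moment of mask pixels
#' along the major axis is negative after alignment), and scales all
#' coordinates by the mask extent along the major axis (the fish length) so
#' x values span \[0, 1\]. Both axes use the same scale, preserving aspect.
#' Spot sizes are divided by the squared length scale.
#'
#' @param spots a [spotset()] in the pixel frame of `body_mask`.
#' @param body_mask logical H x W body mask with at least two distinct
#'   pixels.
#' @param raster_step cell size (fish-length units) of the normalized mask
#'   raster.
#' @return A list with `spots` (normalized [spotset()]), `mask` (a
#'   [norm_mask()]) and `alignment` (rotation applied in degrees, origin
#'   shift and `length_scale` in px per fish-length unit).
#' @export
pca_align <- function(spots, body_mask, raster_step = 1 / 128) {
  w <- which(body_mask > 0, arr.ind = TRUE)
  if (nrow(w) < 2)
    stop_spotmatch("mask has fewer than two distinct pixels",
                   "spotmatch_degenerate_mask")
  P <- cbind(w[, 2] - 1, w[, 1] - 1)  # (x, y), 0-based
  align <- align_point_cloud(P)

  U <- apply_alignment(align, P)
  ymax <- max(U[, 2])

  sp_out <- spots
  if (n_spots(spots) > 0) {
    S <- apply_alignment(align, cbind(spots$x, spots$y))
    sp_out <- spotset(S[, 1], S[, 2], spots$size / align$length_scale^2,
                      frame = spots$frame, normalized = TRUE,
                      length_scale = align$length_scale)
  } else {
    sp_out <- spotset(frame = spots$frame, normalized = TRUE,
                      length_scale = align$length_scale)
  }

  # rasterize the aligned mask on a regular grid in normalized units by
  # inverse-mapping cell centres into the pixel frame
  pad <- 0.05
  gx <- seq(-pad, 1 + pad, by = raster_step)
  gy <- seq(-pad, ymax + pad, by = raster_step)
  G <- cbind(rep(gx, each = length(gy)), rep(gy, length(gx)))
  Upix <- sweep(G * align$length_scale, 2, align$mins, "+")
  Ppix <- sweep(Upix %*% rot2(align$rotation), 2, align$centre, "+")
  cc <- round(Ppix[, 1]) + 1L
  rr <- round(Ppix[, 2]) + 1L
  ok <- cc >= 1L & cc <= ncol(body_mask) & rr >= 1L & rr <= nrow(body_mask)
  vals <- logical(nrow(G))
  vals[ok] <- body_mask[cbind(rr[ok], cc[ok])] > 0
  px <- matrix(vals, nrow = length(gy), ncol = length(gx))

  list(spots = sp_out,
       mask = norm_mask(px, origin = c(gx[1], gy[1]), step = raster_step),
       alignment = align)
}
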