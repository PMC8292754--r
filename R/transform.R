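#' Similarity transforms
#'
#' A similarity transform maps a point p to `scale * R(rotation) p +
#' translation`, where `R` is the standard rotation matrix (angle in degrees,
#' counter-clockwise for column vectors in the x-right/y-down convention used
#' throughout the package).
#'
#' @param rotation rotation angle in degrees.
#' @param scale uniform scale factor (> 0).
#' @param translation numeric `c(tx, ty)`.
#' @return An object of class `similarity_transform` with an equivalent
#'   3 x 3 homogeneous `matrix` element.
#' @examples
#' t <- similarity_transform(10, 1.1, c(0.05, -0.02))
#' transform_points(t, cbind(0.5, 0.5))
#' @export
similarity_transform <- function(rotation = 0, scale = 1,
                                 translation = c(0, 0)) {
  check_positive(scale, "scale")
  th <- rotation * pi / 180
  m <- rbind(c(scale * cos(th), -scale * sin(th), translation[1]),
             c(scale * sin(th),  scale * cos(th), translation[2]),
             c(0, 0, 1))
  structure(list(rotation = rotation, scale = scale,
                 translation = as.numeric(translation), matrix = m),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("<similarity: rotation %.3f deg, scale %.4f, translation (%.4f, %.4f)>\n",
              x$rotation, x$scale, x$translation[1], x$translation[2]))
  invisible(x)
}

#' Apply a similarity transform to points
#' @param t a [similarity_transform()].
#' @param xy n x 2 matrix of coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
transform_points <- function(t, xy) {
  xy <- rbind(xy)[, 1:2, drop = FALSE]
  out <- cbind(xy, 1) %*% t(t$matrix)
  out[, 1:2, drop = FALSE]
}

#' Invert a similarity transform
#' @param t a [similarity_transform()].
#' @return The inverse [similarity_transform()].
#' @export
transform_invert <- function(t) {
  s <- 1 / t$scale
  th <- -t$rotation * pi / 180
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  tr <- -s * as.numeric(R %*% t$translation)
  similarity_transform(-t$rotation, s, tr)
}

#' Least-squares similarity transform from point correspondences
#'
#' Finds the rotation + uniform scale + translation minimizing the summed
#' squared distance between transformed source points and target points
#' (closed form via complex regression). Exact when the correspondences are
#' truly related by a similarity transform.
#'
#' @param src,dst n x 2 coordinate matrices (n >= 2).
#' @return A [similarity_transform()].
#' @export
estimate_similarity_transform <- function(src, dst) {
  src <- rbind(src); dst <- rbind(dst)
  if (nrow(src) < 2 || nrow(src) != nrow(dst))
    stop_spotmatch("need matching source/target points (>= 2)",
                   "spotmatch_invalid_argument")
  # degenerate configurations: coincident or (for minimal triples) collinear
  ctr <- sweep(src, 2, colMeans(src))
  sv <- svd(ctr)$d
  if (sv[1] < 1e-12 || (nrow(src) >= 3 && sv[2] / sv[1] < 1e-9))
    stop_spotmatch("source points are collinear or coincident",
                   "spotmatch_degenerate_configuration")
  f <- fit_similarity_cpp(as.matrix(src), as.matrix(dst))
  if (f[5] == 0)
    stop_spotmatch("source points are degenerate",
                   "spotmatch_degenerate_configuration")
  similarity_transform(f[1] * 180 / pi, f[2], c(f[3], f[4]))
}

#' Transformation disturbance
#'
#' Penalty discouraging implausibly large alignments between two
#' constellations whose masks are already roughly aligned:
#' `|rotation|/60 + |scale - 1|/2 + (|tx| + |ty|)/2` with rotation in
#' degrees and the translation's Manhattan norm in fish-length units.
#' Zero iff the transform is the identity.
#'
#' @param t a [similarity_transform()].
#' @return Non-negative disturbance value.
#' @examples
#' transform_disturbance(similarity_transform(60, 1, c(0, 0)))  # 1
#' @export
transform_disturbance <- function(t) {
  abs(t$rotation) / 60 + abs(t$scale - 1) / 2 +
    sum(abs(t$translation)) / 2
}

#' Reprojection error of point correspondences under a transform
#'
#' First-order geometric (Sampson-style) error of a correspondence; for the
#' similarity-transform model this is the Euclidean reprojection distance
#' `||t(source) - target||`.
#'
#' @param t a [similarity_transform()].
#' @param source,target n x 2 coordinate matrices (or length-2 vectors).
#' @return Numeric vector of per-pair errors.
#' @export
pair_error <- function(t, source, target) {
  s <- rbind(source); d <- rbind(target)
  e <- transform_points(t, s) - d[, 1:2, drop = FALSE]
  unname(sqrt(rowSums(e^2)))
}

#' Worst vertex error of a matched triangle
#' @param t a [similarity_transform()].
#' @param src3,dst3 3 x 2 vertex coordinate matrices.
#' @return The maximum of the three vertex [pair_error()]s.
#' @export
triangle_error <- function(t, src3, dst3) max(pair_error(t, src3, dst3))

#' Overlap F-score of two normalized masks under a transform
#'
#' Applies `t` to mask `a` and overlays it on mask `b`, returning the Dice /
#' F-score `2|A&B| / (|A| + |B|)` computed on `b`'s grid (extended by a 25%
#' margin so translated content is not clipped). Empty masks give 0.
#'
#' @param t a [similarity_transform()] mapping `a` coordinates into `b`
#'   coordinates.
#' @param a,b [norm_mask()] objects.
#' @return F-score in \[0, 1\].
#' @export
mask_fscore <- function(t, a, b) {
  if (!any(a$px) || !any(b$px)) return(0)
  nr <- nrow(b$px); nc <- ncol(b$px)
  mr <- ceiling(0.25 * nr); mc <- ceiling(0.25 * nc)
  rows <- seq(1 - mr, nr + mr); cols <- seq(1 - mc, nc + mc)
  gx <- b$origin[1] + (rep(cols, each = length(rows)) - 1) * b$step
  gy <- b$origin[2] + (rep(rows, length(cols)) - 1) * b$step
  inv <- transform_invert(t)
  A <- transform_points(inv, cbind(gx, gy))
  ar <- round((A[, 2] - a$origin[2]) / a$step) + 1
  ac <- round((A[, 1] - a$origin[1]) / a$step) + 1
  okA <- ar >= 1 & ar <= nrow(a$px) & ac >= 1 & ac <= ncol(a$px)
  TA <- logical(length(gx))
  TA[okA] <- a$px[cbind(ar[okA], ac[okA])]
  br <- rep(rows, length(cols)); bc <- rep(cols, each = length(rows))
  okB <- br >= 1 & br <= nr & bc >= 1 & bc <= nc
  TB <- logical(length(gx))
  TB[okB] <- b$px[cbind(br[okB], bc[okB])]
  denom <- sum(TA) + sum(TB)
  if (denom == 0) return(0)
  2 * sum(TA & TB) / denom
}
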