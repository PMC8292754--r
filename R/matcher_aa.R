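#' Configuration of the RANSAC similarity-transform matcher
#'
#' @param knn triangles are built from each point's `knn` nearest
#'   neighbours.
#' @param inlier_error_threshold maximum reprojection error (fish-length
#'   units) for a vertex pair / triangle to count as an inlier.
#' @param consensus_fraction inlier fraction required to stop the search
#'   (see `consensus_on`).
#' @param consensus_on whether consensus is measured on `"points"` (default:
#'   the fraction of source spots and of target spots lying in an inlier
#'   candidate pair; the smaller of the two must reach
#'   `consensus_fraction`) or on `"triangles"` (fraction of matched triangles
#'   whose worst vertex error is an inlier). Point consensus follows the
#'   matcher this design derives from and is far more robust when many
#'   matched triangles are spurious.
#' @param max_disturbance maximum [transform_disturbance()] for early
#'   termination; qualifying transforms above it are retained only as
#'   fallback candidates (smallest disturbance wins).
#' @param max_iterations RANSAC iteration cap.
#' @param mask_fscore_min matches whose transformed-mask overlap F-score
#'   falls below this gate are rejected regardless of score.
#' @param accept_score_min score threshold used when this matcher must make
#'   an open-set decision on its own (e.g. inside the ensemble); calibrated
#'   on synthetic data.
#' @return A list of class `aa_config`.
#' @export
aa_config <- function(knn = 15, inlier_error_threshold = 0.02,
                      consensus_fraction = 0.85, max_disturbance = 1.0,
                      max_iterations = 500, mask_fscore_min = 0.75,
                      accept_score_min = 0.25,
                      consensus_on = c("points", "triangles")) {
  structure(list(knn = knn,
                 inlier_error_threshold = inlier_error_threshold,
                 consensus_fraction = consensus_fraction,
                 max_disturbance = max_disturbance,
                 max_iterations = max_iterations,
                 mask_fscore_min = mask_fscore_min,
                 accept_score_min = accept_score_min,
                 consensus_on = match.arg(consensus_on)),
            class = "aa_config")
}

aa_feature_cols <- c("v1", "v2", "v3", "r21", "r10", "angle",
                     "x1", "y1", "x2", "y2", "x3", "y3")

#' Build triangles with extended side-ratio invariants
#'
#' Triangles are formed locally from each spot's `knn` nearest neighbours.
#' With side lengths `L2 >= L1 >= L0`, the feature vector per triangle is
#' `(L2/L1, L1/L0, centroid angle, vertex coordinates / 5)` — nine
#' components. The coordinate features (scaled down by a factor of 5 to
#' match the magnitude of the ratio features) encourage matches between
#' triangles in the same body region, since the constellations are already
#' roughly aligned by normalization.
#'
#' @param spots a [spotset()] with at least 3 spots.
#' @param cfg an [aa_config()].
#' @return Object of class `aa_triangles`.
#' @export
build_invariants_aa <- function(spots, cfg = aa_config()) {
  if (n_spots(spots) < 3)
    stop_spotmatch("need at least 3 spots to form triangles",
                   "spotmatch_too_few_spots")
  triples <- local_triples_cpp(spots$x, spots$y, as.integer(cfg$knn))
  feats <- aa_features_cpp(spots$x, spots$y, triples)
  colnames(feats) <- aa_feature_cols
  structure(list(features = feats, x = spots$x, y = spots$y),
            class = "aa_triangles")
}

#' @export
print.aa_triangles <- function(x, ...) {
  cat(sprintf("<aa_triangles: %d triangles over %d spots>\n",
              nrow(x$features), length(x$x)))
  invisible(x)
}

#' Match two constellations with the RANSAC similarity matcher
#'
#' Triangles are matched by mutual nearest neighbours in the nine-dimensional
#' invariant space, then RANSAC repeatedly draws a matched triangle, fits the
#' similarity transform from its three vertex pairs and measures the inlier
#' consensus among the candidate correspondences at reprojection error
#' `inlier_error_threshold` (over points by default, see [aa_config()]).
#' A transform reaching `consensus_fraction`
#' inliers terminates the search early when its [transform_disturbance()] is
#' within `max_disturbance`; otherwise the qualifying transform with the
#' smallest disturbance is kept. The selected transform is refitted by least
#' squares on all inlier vertex pairs. The score is the fraction of target
#' spots that are inliers times the fraction of source spots that are
#' inliers; when masks are supplied, a match whose transformed-mask overlap
#' F-score is below `mask_fscore_min` is rejected regardless of score.
#'
#' @param spotsA,spotsB normalized [spotset()]s (source and target).
#' @param maskA,maskB optional [norm_mask()]s aligned with the spots.
#' @param cfg an [aa_config()].
#' @param seed integer seed for the RANSAC draws.
#' @param tri_a,tri_b optional cached [build_invariants_aa()] results.
#' @return A [match_result()] with the estimated transform; the
#'   correspondence holds the inlier point pairs (injective, best error
#'   first).
#' @export
ransac_match_aa <- function(spotsA, spotsB, maskA = NULL, maskB = NULL,
                            cfg = aa_config(), seed = 1,
                            tri_a = NULL, tri_b = NULL) {
  if (n_spots(spotsA) < 3 || n_spots(spotsB) < 3)
    return(rejected_result("too_few_spots"))
  if (is.null(tri_a)) tri_a <- build_invariants_aa(spotsA, cfg)
  if (is.null(tri_b)) tri_b <- build_invariants_aa(spotsB, cfg)
  fa <- tri_a$features; fb <- tri_b$features
  if (nrow(fa) == 0 || nrow(fb) == 0) return(rejected_result("no_triangles"))
  mm <- mutual_nn_cpp(fa[, 4:12, drop = FALSE], fb[, 4:12, drop = FALSE])
  if (nrow(mm) == 0) return(rejected_result("no_matched_triangles"))
  triA <- fa[mm[, 1], 1:3, drop = FALSE]
  triB <- fb[mm[, 2], 1:3, drop = FALSE]
  storage.mode(triA) <- "integer"; storage.mode(triB) <- "integer"
  pairs <- unique(cbind(a = as.integer(triA), b = as.integer(triB)))

  rs <- ransac_aa_cpp(spotsA$x, spotsA$y, spotsB$x, spotsB$y, triA, triB,
                      pairs, cfg$inlier_error_threshold,
                      cfg$consensus_fraction, cfg$max_disturbance,
                      as.integer(cfg$max_iterations), as.integer(seed),
                      identical(cfg$consensus_on, "points"))
  if (!isTRUE(rs$found))
    return(rejected_result("no_consensus"))
  tf <- similarity_transform(rs$rotation, rs$scale, c(rs$tx, rs$ty))

  # point-level inliers over the unique vertex pairs of the matched triangles
  err <- pair_error(tf, cbind(spotsA$x[pairs[, "a"]], spotsA$y[pairs[, "a"]]),
                    cbind(spotsB$x[pairs[, "b"]], spotsB$y[pairs[, "b"]]))
  inl <- pairs[err <= cfg$inlier_error_threshold, , drop = FALSE]
  err_in <- err[err <= cfg$inlier_error_threshold]
  # injective correspondence, best error first
  ord <- order(err_in)
  usedA <- logical(n_spots(spotsA)); usedB <- logical(n_spots(spotsB))
  sel <- logical(nrow(inl))
  for (k in ord) {
    ai <- inl[k, "a"]; bi <- inl[k, "b"]
    if (!usedA[ai] && !usedB[bi]) {
      usedA[ai] <- TRUE; usedB[bi] <- TRUE; sel[k] <- TRUE
    }
  }
  corr <- inl[sel, , drop = FALSE]
  score <- (length(unique(inl[, "b"])) / n_spots(spotsB)) *
    (length(unique(inl[, "a"])) / n_spots(spotsA))

  fsc <- NA_real_
  accepted <- TRUE
  if (!is.null(maskA) && !is.null(maskB)) {
    fsc <- mask_fscore(tf, maskA, maskB)
    if (fsc < cfg$mask_fscore_min) accepted <- FALSE
  }
  match_result(corr, score = score, accepted = accepted, transform = tf,
               mask_fscore = fsc,
               diagnostics = list(n_matched_triangles = nrow(mm),
                                  capped = isTRUE(rs$capped),
                                  iterations = rs$iterations,
                                  disturbance = rs$disturbance,
                                  triangle_inlier_fraction = mean(rs$inlier)))
}
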