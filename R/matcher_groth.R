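#' Configuration of the Groth-style triangle-voting matcher
#'
#' Triangle invariants (side ratio, cosine, log perimeter, handedness,
#' centroid angle) are matched between two constellations by mutual nearest
#' neighbours in feature space, filtered, and converted into point
#' correspondences by voting. The classical restrictions on maximum side
#' ratio and cosine are deliberately dropped (spot patterns are often highly
#' linear); instead triangles are built locally from each point's `knn`
#' nearest neighbours.
#'
#' @param epsilon positional tolerance in fish-length units: the expected
#'   uncertainty of a spot centroid between two captures of the same fish.
#'   It drives both the de-duplication radius (3 epsilon) and the
#'   first-order invariant tolerances, so it should be set to (or slightly
#'   above) the positional noise scale of the data.
#' @param knn number of nearest neighbours used in triangle construction.
#' @param max_angle_diff maximum centroid-angle difference (degrees) between
#'   matched triangles.
#' @param angle_weight weight of the centroid angle (in radians) in the
#'   nearest-neighbour feature space. The angle of every triangle shifts
#'   coherently with the residual rotation between two captures, so it is
#'   down-weighted relative to the rotation-invariant ratio and cosine
#'   features; the full angle still acts through `max_angle_diff`.
#' @param magnification_sd matched pairs must have their log-perimeter
#'   difference within this many standard deviations of the pair-set mean.
#' @param vote_drop_factor assignment stops when the vote count drops by this
#'   factor (see `vote_drop_from`).
#' @param vote_drop_from reference for the vote-drop stop: `"previous"`
#'   (default) stops at a cliff — the next pair has less than `1 /
#'   vote_drop_factor` of the previous pair's votes — which separates the
#'   well-supported block from the spurious tail; `"first"` measures the
#'   drop against the top pair.
#' @param on_reuse what to do when the next pair re-uses an already assigned
#'   point: `"stop"` (default) terminates the assignment; `"skip"` rejects
#'   that pair and continues down the list. Stopping keeps the assignment
#'   conservative, which is what gives the matcher its sharp score rise on
#'   genuine matches.
#' @param score_threshold open-set acceptance threshold on the match score.
#' @param tolerance_filter,handedness_filter,angle_filter,magnification_filter
#'   logical switches for the individual candidate filters (all `TRUE` in
#'   normal operation; each filter only ever removes candidates).
#' @return A list of class `groth_config`.
#' @export
groth_config <- function(epsilon = 0.0075, knn = 25, max_angle_diff = 10,
                         angle_weight = 0.25,
                         magnification_sd = 1.5, vote_drop_factor = 2,
                         vote_drop_from = c("previous", "first"),
                         on_reuse = c("stop", "skip"),
                         score_threshold = 6.5,
                         tolerance_filter = TRUE, handedness_filter = TRUE,
                         angle_filter = TRUE, magnification_filter = TRUE) {
  structure(list(epsilon = epsilon, knn = knn,
                 max_angle_diff = max_angle_diff,
                 angle_weight = angle_weight,
                 magnification_sd = magnification_sd,
                 vote_drop_factor = vote_drop_factor,
                 vote_drop_from = match.arg(vote_drop_from),
                 on_reuse = match.arg(on_reuse),
                 score_threshold = score_threshold,
                 tolerance_filter = tolerance_filter,
                 handedness_filter = handedness_filter,
                 angle_filter = angle_filter,
                 magnification_filter = magnification_filter),
            class = "groth_config")
}

#' Remove near-duplicate spots
#'
#' Greedily removes, in input order, any spot lying within `3 * epsilon` of
#' an already-kept spot. Guards the triangle invariants against
#' near-coincident points.
#'
#' @param spots a [spotset()].
#' @param epsilon positional tolerance (> 0).
#' @return A [spotset()]; the indices of the kept spots are in attribute
#'   `"kept"`.
#' @export
dedupe_spots <- function(spots, epsilon) {
  check_positive(epsilon, "epsilon")
  n <- n_spots(spots)
  if (n <= 1) {
    out <- spots
    attr(out, "kept") <- seq_len(n)
    return(out)
  }
  keep <- 1L
  for (i in seq_len(n)[-1]) {
    d <- sqrt((spots$x[keep] - spots$x[i])^2 + (spots$y[keep] - spots$y[i])^2)
    if (min(d) > 3 * epsilon) keep <- c(keep, i)
  }
  out <- subset_spots(spots, keep)
  attr(out, "kept") <- keep
  out
}

groth_feature_cols <- c("v1", "v2", "v3", "R", "C", "logP", "handed",
                        "angle", "tolR2", "tolC2")

#' Build Groth triangles with invariant features
#'
#' Forms all distinct triangles joining each spot with pairs among its `knn`
#' nearest neighbours and computes, per triangle: vertex order (v1 at the
#' junction of the shortest and longest side), side ratio `R` =
#' longest/shortest, cosine `C` of the angle between those sides, log
#' perimeter, handedness of the shortest-to-longest traversal, the angle
#' between the first vertex, the triangle centroid and the horizontal, and
#' first-order tolerances of `R` and `C` propagated from `epsilon`. No side
#' ratio or cosine pruning is applied.
#'
#' @param spots a [spotset()] with at least 3 spots.
#' @param cfg a [groth_config()].
#' @return Object of class `groth_triangles`: a feature matrix (one row per
#'   triangle) plus the generating spot coordinates.
#' @export
build_triangles_groth <- function(spots, cfg = groth_config()) {
  if (n_spots(spots) < 3)
    stop_spotmatch("need at least 3 spots to form triangles",
                   "spotmatch_too_few_spots")
  triples <- local_triples_cpp(spots$x, spots$y, as.integer(cfg$knn))
  feats <- groth_features_cpp(spots$x, spots$y, triples, cfg$epsilon)
  colnames(feats) <- groth_feature_cols
  structure(list(features = feats, x = spots$x, y = spots$y),
            class = "groth_triangles")
}

#' @export
print.groth_triangles <- function(x, ...) {
  cat(sprintf("<groth_triangles: %d triangles over %d spots>\n",
              nrow(x$features), length(x$x)))
  invisible(x)
}

# smallest absolute angular difference in degrees, with wraparound
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Match triangles between two constellations
#'
#' Candidate pairs are mutual nearest neighbours in the (R, C, centroid
#' angle) feature space (angle in radians so the scales are commensurate),
#' searched with dual k-d trees. Candidates are then filtered: invariant
#' differences within the summed first-order tolerances, same handedness,
#' centroid-angle difference at most `max_angle_diff`, and log-perimeter
#' difference (the log magnification) within `magnification_sd` standard
#' deviations of the candidate-set mean.
#'
#' @param A,B `groth_triangles` from [build_triangles_groth()].
#' @param cfg a [groth_config()].
#' @return Data frame with columns `a`, `b` (triangle row indices), `dist`
#'   (squared feature distance) and `dlogP`.
#' @export
match_triangles <- function(A, B, cfg = groth_config()) {
  fa <- A$features; fb <- B$features
  if (nrow(fa) == 0 || nrow(fb) == 0)
    return(data.frame(a = integer(), b = integer(), dist = numeric(),
                      dlogP = numeric()))
  w <- if (is.null(cfg$angle_weight)) 1 else cfg$angle_weight
  FA <- cbind(fa[, "R"], fa[, "C"], fa[, "angle"] * pi / 180 * w)
  FB <- cbind(fb[, "R"], fb[, "C"], fb[, "angle"] * pi / 180 * w)
  mm <- mutual_nn_cpp(FA, FB)
  if (nrow(mm) == 0)
    return(data.frame(a = integer(), b = integer(), dist = numeric(),
                      dlogP = numeric()))
  a <- as.integer(mm[, 1]); b <- as.integer(mm[, 2]); dist <- mm[, 3]
  keep <- rep(TRUE, length(a))
  if (isTRUE(cfg$tolerance_filter)) {
    keep <- keep &
      (fa[a, "R"] - fb[b, "R"])^2 < fa[a, "tolR2"] + fb[b, "tolR2"] &
      (fa[a, "C"] - fb[b, "C"])^2 < fa[a, "tolC2"] + fb[b, "tolC2"]
  }
  if (isTRUE(cfg$handedness_filter))
    keep <- keep & fa[a, "handed"] == fb[b, "handed"]
  if (isTRUE(cfg$angle_filter))
    keep <- keep & angle_diff(fa[a, "angle"], fb[b, "angle"]) <= cfg$max_angle_diff
  a <- a[keep]; b <- b[keep]; dist <- dist[keep]
  dlogP <- fa[a, "logP"] - fb[b, "logP"]
  if (isTRUE(cfg$magnification_filter) && length(a) > 1) {
    mu <- mean(dlogP); sdv <- stats::sd(dlogP)
    if (is.finite(sdv) && sdv > 0) {
      keep2 <- abs(dlogP - mu) <= cfg$magnification_sd * sdv
      a <- a[keep2]; b <- b[keep2]; dist <- dist[keep2]; dlogP <- dlogP[keep2]
    }
  }
  data.frame(a = a, b = b, dist = dist, dlogP = dlogP)
}

#' Convert matched triangles into a point correspondence by voting
#'
#' Every matched triangle casts one vote for each of its three vertex pairs
#' (vertices aligned by the invariant ordering). Candidate pairs are sorted
#' by descending votes (ties: smaller summed feature distance, then
#' lexicographic indices) and assigned successively until the vote count
#' drops below `votes[1] / vote_drop_factor`, a pair re-uses an already
#' assigned point, or votes are exhausted.
#'
#' @param matches data frame from [match_triangles()].
#' @param A,B the `groth_triangles` the matches refer to.
#' @param cfg a [groth_config()].
#' @return Integer matrix with columns `a`, `b` (spot indices); attributes
#'   `votes` (the full vote table) and `votes_assigned`.
#' @export
vote_and_assign <- function(matches, A, B, cfg = groth_config()) {
  empty <- matrix(integer(), 0, 2, dimnames = list(NULL, c("a", "b")))
  if (nrow(matches) == 0) {
    attr(empty, "votes") <- data.frame(a = integer(), b = integer(),
                                       votes = integer())
    attr(empty, "votes_assigned") <- 0L
    return(empty)
  }
  va <- A$features[matches$a, c("v1", "v2", "v3"), drop = FALSE]
  vb <- B$features[matches$b, c("v1", "v2", "v3"), drop = FALSE]
  pa <- as.integer(va); pb <- as.integer(vb)
  dd <- rep(matches$dist, 3)
  nb <- max(pb)
  key <- (pa - 1) * nb + pb
  uk <- sort(unique(key))
  idx <- match(key, uk)
  votes <- tabulate(idx, nbins = length(uk))
  dsum <- as.numeric(rowsum(dd, idx))
  ua <- as.integer((uk - 1) %/% nb + 1)
  ub <- as.integer((uk - 1) %% nb + 1)
  ord <- order(-votes, dsum, ua, ub)
  ua <- ua[ord]; ub <- ub[ord]; votes <- votes[ord]
  ref_first <- identical(cfg$vote_drop_from, "first")
  skip_reuse <- !identical(cfg$on_reuse, "stop")
  usedA <- logical(max(pa)); usedB <- logical(nb)
  outA <- integer(0); outB <- integer(0)
  prev <- votes[1]
  for (k in seq_along(ua)) {
    if (votes[k] <= 0) break
    ref <- if (ref_first) votes[1] else prev
    if (votes[k] < ref / cfg$vote_drop_factor) break
    if (usedA[ua[k]] || usedB[ub[k]]) {
      if (skip_reuse) next else break
    }
    usedA[ua[k]] <- TRUE; usedB[ub[k]] <- TRUE
    outA <- c(outA, ua[k]); outB <- c(outB, ub[k])
    prev <- votes[k]
  }
  out <- cbind(a = outA, b = outB)
  attr(out, "votes") <- data.frame(a = ua, b = ub, votes = as.integer(votes))
  attr(out, "votes_assigned") <- sum(votes[seq_along(outA)])
  out
}

#' Match result container
#' @param correspondence two-column matrix of spot index pairs.
#' @param score match score (0 when rejected).
#' @param accepted logical.
#' @param transform optional [similarity_transform()].
#' @param mask_fscore optional mask overlap F-score.
#' @param diagnostics list of matcher internals.
#' @return Object of class `match_result`.
#' @export
match_result <- function(correspondence, score, accepted, transform = NULL,
                         mask_fscore = NA_real_, diagnostics = list()) {
  structure(list(correspondence = correspondence, score = score,
                 accepted = accepted, transform = transform,
                 mask_fscore = mask_fscore, diagnostics = diagnostics),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %s, score %.3f, %d matched pairs%s>\n",
              if (x$accepted) "accepted" else "rejected", x$score,
              nrow(x$correspondence),
              if (!is.na(x$mask_fscore))
                sprintf(", mask F %.3f", x$mask_fscore) else ""))
  invisible(x)
}

rejected_result <- function(reason) {
  match_result(matrix(integer(), 0, 2, dimnames = list(NULL, c("a", "b"))),
               score = 0, accepted = FALSE,
               diagnostics = list(reason = reason))
}

groth_round <- function(spotsA, spotsB, cfg, tri_a = NULL, tri_b = NULL) {
  if (is.null(tri_a)) tri_a <- build_triangles_groth(spotsA, cfg)
  if (is.null(tri_b)) tri_b <- build_triangles_groth(spotsB, cfg)
  m <- match_triangles(tri_a, tri_b, cfg)
  vote_and_assign(m, tri_a, tri_b, cfg)
}

# the verification round re-examines an already vetted subset: individual
# contested pairs there reflect vote-order ties, not a bad match, so the
# re-run skips them instead of aborting
verification_cfg <- function(cfg) {
  cfg$on_reuse <- "skip"
  cfg
}

#' Match two constellations with the Groth voting matcher
#'
#' Runs the full pipeline (de-duplication, triangle construction, mutual
#' nearest-neighbour matching, filters, voting) and then repeats it using
#' only the points from the matched pairs, to weed out spurious assignments.
#' If the second round returns as many matches as the first, the first-round
#' matches are accepted; fewer matches mean the constellations are deemed
#' impossible to match (score 0).
#'
#' The score is `n_assigned * (fraction of first-round votes captured by the
#' assigned pairs)`: it rises steeply with the number of well-supported
#' pairs, and the default open-set threshold of 6.5 roughly requires seven
#' well-supported pairs.
#'
#' @param spotsA,spotsB normalized [spotset()]s.
#' @param cfg a [groth_config()].
#' @param tri_a,tri_b optional pre-built [build_triangles_groth()] results
#'   for the de-duplicated spot sets (a cache for repeated comparisons).
#' @return A [match_result()]; `correspondence` holds indices into the
#'   original (pre-deduplication) spot sets.
#' @export
groth_match <- function(spotsA, spotsB, cfg = groth_config(),
                        tri_a = NULL, tri_b = NULL) {
  da <- dedupe_spots(spotsA, cfg$epsilon)
  db <- dedupe_spots(spotsB, cfg$epsilon)
  if (n_spots(da) < 3 || n_spots(db) < 3)
    return(rejected_result("too_few_spots"))
  corr1 <- groth_round(da, db, cfg, tri_a, tri_b)
  if (nrow(corr1) == 0) return(rejected_result("no_votes"))
  votes <- attr(corr1, "votes")
  total_votes <- sum(votes$votes)
  captured <- attr(corr1, "votes_assigned")

  if (nrow(corr1) >= 3) {
    subA <- subset_spots(da, corr1[, "a"])
    subB <- subset_spots(db, corr1[, "b"])
    corr2 <- groth_round(subA, subB, verification_cfg(cfg))
  } else corr2 <- corr1

  if (nrow(corr2) < nrow(corr1))
    return(match_result(matrix(integer(), 0, 2,
                               dimnames = list(NULL, c("a", "b"))),
                        score = 0, accepted = FALSE,
                        diagnostics = list(reason = "round2_fewer",
                                           n_round1 = nrow(corr1),
                                           n_round2 = nrow(corr2))))
  keptA <- attr(da, "kept"); keptB <- attr(db, "kept")
  corr <- cbind(a = keptA[corr1[, "a"]], b = keptB[corr1[, "b"]])
  score <- nrow(corr) * (captured / total_votes)
  match_result(corr, score = score, accepted = TRUE,
               diagnostics = list(n_round1 = nrow(corr1),
                                  n_round2 = nrow(corr2),
                                  votes_total = total_votes,
                                  votes_captured = captured))
}
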