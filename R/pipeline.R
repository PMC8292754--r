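#' A constellation record
#'
#' One photographed capture event: the normalized constellation, optionally
#' the normalized body mask, the capture date, the observed tag id (if any)
#' and the fork length.
#'
#' @param id unique record identifier.
#' @param date capture date (anything ordered by `>`, e.g. `Date` or
#'   numeric occasion index).
#' @param spots normalized [spotset()].
#' @param mask optional [norm_mask()].
#' @param tag_id observed tag id or `NA`.
#' @param fork_length fork length in mm or `NA`.
#' @return Object of class `constellation_record`.
#' @export
constellation_record <- function(id, date, spots, mask = NULL,
                                 tag_id = NA_character_,
                                 fork_length = NA_real_) {
  if (missing(date) || is.null(date) || length(date) != 1L || is.na(date))
    stop_spotmatch("record date is required", "spotmatch_invalid_argument")
  structure(list(id = as.character(id), date = date, spots = spots,
                 mask = mask, tag_id = tag_id, fork_length = fork_length,
                 cache = new.env(parent = emptyenv())),
            class = "constellation_record")
}

#' A chronological constellation database
#'
#' Collections of records keyed by strictly increasing capture dates.
#' Queries are compared only against records from earlier collections,
#' mirroring the field protocol where earlier captures of a fish always
#' precede it in the database.
#'
#' @return An empty database of class `constellation_db`.
#' @export
constellation_db <- function() {
  structure(list(dates = list(), collections = list()),
            class = "constellation_db")
}

#' @export
print.constellation_db <- function(x, ...) {
  cat(sprintf("<constellation_db: %d collections, %d records>\n",
              length(x$collections),
              sum(vapply(x$collections, length, integer(1)))))
  invisible(x)
}

#' Add a collection of records to the database
#'
#' @param db a [constellation_db()].
#' @param records list of [constellation_record()]s captured at `date`.
#' @param date collection date; must be strictly after the latest stored
#'   date.
#' @return The updated database.
#' @export
add_collection <- function(db, records, date) {
  if (length(db$dates) > 0 && !(date > db$dates[[length(db$dates)]]))
    stop_spotmatch("collection date must be strictly after the latest stored date",
                   "spotmatch_chronology_violation")
  db$dates <- c(db$dates, list(date))
  db$collections <- c(db$collections, list(records))
  db
}

#' Records stored before a given date
#' @param db a [constellation_db()].
#' @param date cutoff; only records from strictly earlier collections are
#'   returned (all records when `NULL`).
#' @return Flat list of records.
#' @export
db_records_before <- function(db, date = NULL) {
  keep <- if (is.null(date)) seq_along(db$collections)
          else which(vapply(db$dates, function(d) date > d, logical(1)))
  do.call(c, c(list(list()), db$collections[keep]))
}

# cached matcher precomputations attached to a record (reference semantics)
record_triangles <- function(rec, matcher, cfg) {
  key <- paste0(matcher, "_tri")
  if (is.null(rec$cache[[key]])) {
    rec$cache[[key]] <- tryCatch(
      switch(matcher,
             groth = build_triangles_groth(dedupe_spots(rec$spots, cfg$epsilon), cfg),
             aa = build_invariants_aa(rec$spots, cfg)),
      spotmatch_too_few_spots = function(e) NULL, error = function(e) NULL)
  }
  rec$cache[[key]]
}

#' Rank database records against a query
#'
#' Scores every record stored before the query's date with the requested
#' matcher and sorts descending; comparisons that cannot be scored (too few
#' spots, no consensus, round-two failure) are kept as unscored sentinels
#' ordered after all scored records. Ties are broken by record id.
#'
#' @param query a [constellation_record()].
#' @param db a [constellation_db()].
#' @param matcher `"groth"` or `"aa"`.
#' @param cfg matcher configuration ([groth_config()] or [aa_config()]).
#' @param seed integer seed (used by the RANSAC matcher).
#' @return Data frame of class `ranked_matches` with columns `record_id`,
#'   `score` (NA for sentinels), `accepted` and `mask_fscore`.
#' @export
rank_matches <- function(query, db, matcher = c("groth", "aa"), cfg = NULL,
                         seed = 1) {
  matcher <- match.arg(matcher)
  if (is.null(cfg)) cfg <- if (matcher == "groth") groth_config() else aa_config()
  records <- db_records_before(db, query$date)
  out <- data.frame(record_id = character(), score = numeric(),
                    accepted = logical(), mask_fscore = numeric(),
                    stringsAsFactors = FALSE)
  if (length(records) == 0) {
    class(out) <- c("ranked_matches", class(out))
    return(out)
  }
  qtri <- record_triangles(query, matcher, cfg)
  res <- lapply(records, function(rec) {
    rtri <- record_triangles(rec, matcher, cfg)
    if (matcher == "groth") {
      r <- groth_match(query$spots, rec$spots, cfg, tri_a = qtri, tri_b = rtri)
      c(score = if (r$accepted) r$score else NA_real_,
        accepted = r$accepted, fsc = NA_real_)
    } else {
      r <- ransac_match_aa(query$spots, rec$spots, query$mask, rec$mask,
                           cfg, seed = seed, tri_a = qtri, tri_b = rtri)
      c(score = if (!is.null(r$transform)) r$score else NA_real_,
        accepted = r$accepted, fsc = r$mask_fscore)
    }
  })
  m <- do.call(rbind, res)
  out <- data.frame(record_id = vapply(records, `[[`, "", "id"),
                    score = m[, "score"], accepted = m[, "accepted"] > 0,
                    mask_fscore = m[, "fsc"], stringsAsFactors = FALSE)
  ord <- order(is.na(out$score), -ifelse(is.na(out$score), -Inf, out$score),
               out$record_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ranked_matches", class(out))
  out
}

#' Open-set decision from a ranking
#'
#' @param ranked a `ranked_matches` data frame.
#' @param threshold score threshold; the top-ranked scored record is
#'   returned when its score reaches the threshold.
#' @param require_accepted additionally require the matcher's own accept
#'   flag (used for the RANSAC matcher's mask gate).
#' @return The matched record id, or `NA_character_` for no-match.
#' @export
decide_open_set <- function(ranked, threshold, require_accepted = FALSE) {
  scored <- ranked[!is.na(ranked$score), , drop = FALSE]
  if (require_accepted) scored <- scored[scored$accepted, , drop = FALSE]
  if (nrow(scored) == 0) return(NA_character_)
  if (scored$score[1] >= threshold) scored$record_id[1] else NA_character_
}

#' Combine the two matchers' open-set decisions
#'
#' Simple OR rule: a match is declared when either matcher accepts. When
#' both accept different records the Groth decision wins (its false-positive
#' rate is the better of the two); the conflict is recorded in an attribute
#' for audit.
#'
#' @param groth,aa decisions (record id or `NA`) from [decide_open_set()].
#' @return Record id or `NA`; attribute `"conflict"` is `TRUE` when the two
#'   matchers accepted different records.
#' @export
ensemble_decision <- function(groth, aa) {
  conflict <- !is.na(groth) && !is.na(aa) && groth != aa
  out <- if (!is.na(groth)) groth else aa
  attr(out, "conflict") <- conflict
  out
}

#' Open-set evaluation counts
#'
#' @param decisions vector of decided record ids (`NA` = no-match).
#' @param truth vector of true prior record ids (`NA` = the query is novel).
#' @return List of class `evaluation_counts` with `tp`, `fp`, `tn`, `fn`
#'   and `accuracy = (tp + tn) / total`.
#' @export
evaluate_open_set <- function(decisions, truth) {
  if (length(decisions) != length(truth))
    stop_spotmatch("decisions and truth differ in length",
                   "spotmatch_invalid_argument")
  dec <- as.character(decisions); tru <- as.character(truth)
  tp <- sum(!is.na(dec) & !is.na(tru) & dec == tru)
  fp <- sum(!is.na(dec) & (is.na(tru) | dec != tru))
  tn <- sum(is.na(dec) & is.na(tru))
  fn <- sum(is.na(dec) & !is.na(tru))
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / length(dec)),
            class = "evaluation_counts")
}

#' @export
print.evaluation_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d  open-set accuracy %.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$accuracy))
  invisible(x)
}

#' Closed-set rank-k accuracy
#'
#' Among queries known to have a true prior record, the fraction whose true
#' record appears within the top k ranked candidates, for k in {1, 2, 5}.
#'
#' @param rankings list of `ranked_matches`, one per query.
#' @param truth vector of true record ids (`NA` entries are skipped).
#' @return Named numeric vector `c(rank1, rank2, rank5)`.
#' @export
evaluate_closed_set <- function(rankings, truth) {
  keep <- !is.na(truth)
  rankings <- rankings[keep]; truth <- truth[keep]
  if (length(truth) == 0) return(c(rank1 = NA_real_, rank2 = NA_real_,
                                   rank5 = NA_real_))
  pos <- mapply(function(r, t) {
    scored <- r[!is.na(r$score), , drop = FALSE]
    i <- match(t, scored$record_id)
    if (is.na(i)) Inf else i
  }, rankings, truth)
  c(rank1 = mean(pos <= 1), rank2 = mean(pos <= 2), rank5 = mean(pos <= 5))
}

# --- capture-history correction ---------------------------------------------

# union-find over character ids
uf_new <- function(ids) {
  parent <- stats::setNames(ids, ids)
  list(parent = parent)
}
uf_find <- function(uf, x) {
  while (uf$parent[[x]] != x) x <- uf$parent[[x]]
  x
}
uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a); rb <- uf_find(uf, b)
  if (ra != rb) uf$parent[[rb]] <- ra
  uf
}

#' Merge fragmented capture histories using accepted re-identifications
#'
#' Accepted photo matches link observed tag ids that belong to the same
#' individual. Linked ids are merged with a union-find; the history of a
#' consolidated individual is the element-wise OR of its fragments. Two
#' fragments of the same individual captured at the same occasion indicate a
#' contradictory link chain and raise a conflict error.
#'
#' @param links data frame with columns `from`, `to`: pairs of observed ids
#'   decided to be the same individual.
#' @param records data frame of capture events with columns `observed_id`
#'   and `occasion`.
#' @param n_occasions total number of occasions.
#' @return Binary capture-history matrix, one row per consolidated
#'   individual, named by the fragment with the earliest first capture.
#' @export
correct_capture_histories <- function(links, records, n_occasions) {
  ids <- unique(records$observed_id)
  uf <- uf_new(ids)
  if (nrow(links) > 0)
    for (k in seq_len(nrow(links)))
      uf <- uf_union(uf, as.character(links$to[k]), as.character(links$from[k]))
  root <- vapply(records$observed_id, function(i) uf_find(uf, i), "")
  # conflict: one consolidated individual, two capture events, same occasion,
  # from different observed fragments
  key <- paste(root, records$occasion)
  if (any(tapply(records$observed_id, key, function(v) length(unique(v))) > 1))
    stop_spotmatch("linked fragments captured in the same collection",
                   "spotmatch_conflict")
  first_occ <- tapply(records$occasion, records$observed_id, min)
  label <- tapply(ids, vapply(ids, function(i) uf_find(uf, i), ""),
                  function(v) v[which.min(first_occ[v])])
  histories_from_records(
    data.frame(id = unname(label[root]), occasion = records$occasion),
    n_occasions)
}

#' Re-identify fragmented individuals in a capture-record stream
#'
#' Processes capture events in chronological order. The first event of each
#' observed tag id is treated as a potentially new individual and its
#' constellation is queried against the most recent prior record of every
#' consolidated individual; a decision at or above `threshold` links the two
#' ids. Candidates already captured at the query's occasion are excluded (an
#' individual cannot be handled twice in one collection).
#'
#' @param records data frame with columns `observed_id` and `occasion`.
#' @param constellations list of normalized [spotset()]s, one per record row.
#' @param masks optional list of [norm_mask()]s (needed by the `aa` matcher's
#'   gate).
#' @param matcher `"groth"` (default, fully automated) or `"aa"`.
#' @param cfg matcher configuration.
#' @param threshold open-set score threshold.
#' @param seed integer seed.
#' @return List with `links` (data frame `from`, `to`) and `decisions` (one
#'   row per queried fragment).
#' @export
link_fragments <- function(records, constellations, masks = NULL,
                           matcher = "groth", cfg = NULL, threshold = 6.5,
                           seed = 1) {
  if (is.null(cfg)) cfg <- if (matcher == "groth") groth_config() else aa_config()
  ord <- order(records$occasion)
  records <- records[ord, , drop = FALSE]
  constellations <- constellations[ord]
  if (!is.null(masks)) masks <- masks[ord]

  members <- integer(0)    # observed id -> individual index (names = ids)
  ind_root <- character(0) # first observed id per individual
  ind_rec <- list()        # latest record per individual
  ind_occ <- integer(0)    # occasion of that record
  links <- data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE)
  decisions <- data.frame(observed_id = character(), occasion = integer(),
                          match = character(), score = numeric(),
                          stringsAsFactors = FALSE)
  for (k in seq_len(nrow(records))) {
    oid <- records$observed_id[k]
    occ <- as.integer(records$occasion[k])
    rec <- constellation_record(id = sprintf("rec%05d", k), date = occ,
                                spots = constellations[[k]],
                                mask = if (!is.null(masks)) masks[[k]] else NULL,
                                tag_id = oid)
    if (oid %in% names(members)) {
      i <- members[[oid]]
      ind_rec[[i]] <- rec; ind_occ[i] <- occ
      next
    }
    cand <- which(ind_occ < occ)
    best_i <- NA_integer_; best_score <- NA_real_
    if (length(cand) > 0) {
      qtri <- record_triangles(rec, matcher, cfg)
      scores <- rep(NA_real_, length(cand))
      for (j in seq_along(cand)) {
        tgt <- ind_rec[[cand[j]]]
        ttri <- record_triangles(tgt, matcher, cfg)
        if (matcher == "groth") {
          r <- groth_match(rec$spots, tgt$spots, cfg, tri_a = qtri,
                           tri_b = ttri)
          if (r$accepted) scores[j] <- r$score
        } else {
          r <- ransac_match_aa(rec$spots, tgt$spots, rec$mask, tgt$mask,
                               cfg, seed = seed, tri_a = qtri, tri_b = ttri)
          if (!is.null(r$transform) && r$accepted) scores[j] <- r$score
        }
      }
      if (any(!is.na(scores))) {
        jbest <- which.max(ifelse(is.na(scores), -Inf, scores))
        if (scores[jbest] >= threshold) {
          best_i <- cand[jbest]
          best_score <- scores[jbest]
        }
      }
    }
    decisions <- rbind(decisions,
                       data.frame(observed_id = oid, occasion = occ,
                                  match = if (is.na(best_i)) NA_character_
                                          else ind_root[best_i],
                                  score = best_score,
                                  stringsAsFactors = FALSE))
    if (!is.na(best_i)) {
      links <- rbind(links, data.frame(from = oid, to = ind_root[best_i],
                                       stringsAsFactors = FALSE))
      members[[oid]] <- best_i
      ind_rec[[best_i]] <- rec; ind_occ[best_i] <- occ
    } else {
      ind_root <- c(ind_root, oid)
      ind_rec <- c(ind_rec, list(rec))
      ind_occ <- c(ind_occ, occ)
      members[[oid]] <- length(ind_root)
    }
  }
  list(links = links, decisions = decisions)
}
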