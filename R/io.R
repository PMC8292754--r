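#' Read and write spot constellations
#'
#' CSV files carry the raw table with header `x,y,size`; JSON files
#' additionally carry the normalization metadata (frame, normalized flag,
#' length scale) and round-trip a [spotset()] losslessly.
#'
#' @param spots a [spotset()].
#' @param path file path; the format is chosen by extension (`.csv` or
#'   `.json`).
#' @return `write_spotset` returns `path` invisibly; `read_spotset` returns a
#'   [spotset()].
#' @export
write_spotset <- function(spots, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(spots = as.data.frame(spots), frame = spots$frame,
           normalized = spots$normalized, length_scale = spots$length_scale),
      path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    utils::write.csv(as.data.frame(spots), path, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_spotset
#' @export
read_spotset <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(j$spots)
    if (nrow(df) == 0) df <- data.frame(x = numeric(), y = numeric(),
                                        size = numeric())
    return(spotset(df$x, df$y, df$size, frame = unlist(j$frame),
                   normalized = isTRUE(j$normalized),
                   length_scale = if (is.null(j$length_scale)) NA_real_
                                  else j$length_scale))
  }
  lines <- readLines(path)
  if (length(lines) == 0)
    stop_spotmatch("empty file (missing header)", "spotmatch_parse")
  header <- gsub('"', "", strsplit(trimws(lines[1]), ",")[[1]])
  need <- c("x", "y", "size")
  if (!all(need %in% header))
    stop_spotmatch("header must contain columns x, y, size",
                   "spotmatch_parse")
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  if (length(body) == 0) return(spotset())
  rows <- lapply(seq_along(body), function(i) {
    f <- strsplit(body[i], ",")[[1]]
    v <- suppressWarnings(as.numeric(f[match(need, header)]))
    if (length(f) < length(header) || any(is.na(v)))
      stop_spotmatch(sprintf("malformed row %d: '%s'", i + 1L, body[i]),
                     "spotmatch_parse")
    v
  })
  m <- do.call(rbind, rows)
  spotset(m[, 1], m[, 2], m[, 3])
}

#' Read and write capture-history matrices
#'
#' CSV with an `id` column followed by one 0/1 column per occasion. Reading
#' validates that every row has at least one capture.
#'
#' @param y binary capture-history matrix with row names.
#' @param path CSV file path.
#' @return `read_capture_histories` returns the validated matrix.
#' @export
write_capture_histories <- function(y, path) {
  df <- data.frame(id = rownames(y), as.data.frame(unclass(y)))
  names(df) <- c("id", paste0("t", seq_len(ncol(y))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_capture_histories
#' @export
read_capture_histories <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df))
    stop_spotmatch("missing id column", "spotmatch_parse")
  y <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  if (!all(y %in% c(0, 1)))
    stop_spotmatch("capture histories must be 0/1", "spotmatch_parse")
  storage.mode(y) <- "integer"
  rownames(y) <- df$id
  colnames(y) <- NULL
  bad <- rownames(y)[rowSums(y) == 0]
  if (length(bad))
    stop_spotmatch(paste("history with no captures for id:",
                         paste(bad, collapse = ", ")),
                   "spotmatch_validation")
  y
}

#' Read and write binary masks as PNG
#'
#' Masks are stored as single-channel 0/255 PNG images.
#'
#' @param mask logical matrix.
#' @param path PNG file path.
#' @return `read_mask_png` returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1.0, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m > 0.5
}

#' Read and write greyscale images as PNG
#' @param image H x W matrix with grey levels 0-255.
#' @param path PNG file path.
#' @return `read_image_png` returns an H x W matrix on the 0-255 scale.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clamp(image / 255, 0, 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- rowMeans(m, dims = 2L)
  m * 255
}

#' Write a match result as JSON
#' @param result a [match_result()].
#' @param path JSON file path.
#' @export
write_match_result <- function(result, path) {
  out <- list(accepted = result$accepted, score = result$score,
              mask_fscore = result$mask_fscore,
              correspondence = as.data.frame(result$correspondence),
              diagnostics = result$diagnostics)
  if (!is.null(result$transform))
    out$transform <- list(rotation = result$transform$rotation,
                          scale = result$transform$scale,
                          translation = result$transform$translation,
                          matrix = result$transform$matrix)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Run the full re-identification pipeline on a directory of collections
#'
#' The input directory holds one sub-directory per collection, named by an
#' increasing sortable date key (e.g. `2014-06`), each containing greyscale
#' PNG photographs and optionally a `tags.csv` (`file,tag_id`). For every
#' image the pipeline extracts the body and spot masks with the baseline
#' segmenter, converts spots to a normalized constellation, and matches it
#' chronologically against earlier collections; accepted matches merge
#' observed ids, and the corrected capture histories are fitted with the
#' survival model when at least three collections are present.
#'
#' @param config list (or path to a YAML/JSON file) with entries
#'   `collections_dir`, `out_dir`, optional `matcher` ("groth"), `threshold`
#'   (6.5), `seed` (1), `fit_survival` (TRUE), `n_samples` (2000) and
#'   `baseline` ("synthetic" for renders, "field" for full-resolution
#'   photograph defaults).
#' @return List with `records`, `links`, `decisions`, `histories` and
#'   optionally `survival`, invisibly; artefacts are written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (tolower(tools::file_ext(config)) %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop_spotmatch("yaml package required for YAML configs",
                       "spotmatch_invalid_argument")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(list(matcher = "groth", threshold = 6.5, seed = 1,
                                fit_survival = TRUE, n_samples = 2000),
                           config)
  if (is.null(cfg$collections_dir) || is.null(cfg$out_dir))
    stop_spotmatch("config needs collections_dir and out_dir",
                   "spotmatch_invalid_argument")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  dirs <- sort(list.dirs(cfg$collections_dir, recursive = FALSE))
  if (length(dirs) == 0)
    stop_spotmatch("no collection directories found",
                   "spotmatch_invalid_argument")

  records <- data.frame(observed_id = character(), occasion = integer(),
                        file = character(), stringsAsFactors = FALSE)
  constellations <- list()
  for (k in seq_along(dirs)) {
    files <- sort(list.files(dirs[k], pattern = "\\.png$", full.names = TRUE))
    tags <- file.path(dirs[k], "tags.csv")
    tagmap <- if (file.exists(tags))
      utils::read.csv(tags, stringsAsFactors = FALSE) else NULL
    for (f in files) {
      img <- read_image_png(f)
      bcfg <- if (identical(cfg$baseline, "field"))
        baseline_config(image_width = ncol(img))
      else baseline_config_synthetic(ncol(img))
      mask <- tryCatch(extract_fish_mask_baseline(img, bcfg),
                       spotmatch_no_subject = function(e) NULL)
      if (is.null(mask)) {
        warning(sprintf("no subject found in %s; skipped", f))
        next
      }
      spm <- extract_spots_baseline(img, mask, bcfg)
      al <- pca_align(spots_from_mask(spm), mask)
      tid <- if (!is.null(tagmap)) {
        i <- match(basename(f), tagmap$file)
        if (!is.na(i)) tagmap$tag_id[i] else basename(f)
      } else basename(f)
      records <- rbind(records,
                       data.frame(observed_id = as.character(tid),
                                  occasion = k, file = f,
                                  stringsAsFactors = FALSE))
      constellations <- c(constellations, list(al$spots))
      write_spotset(al$spots,
                    file.path(cfg$out_dir,
                              sprintf("spots_%02d_%s.csv", k,
                                      tools::file_path_sans_ext(basename(f)))))
    }
  }
  if (nrow(records) == 0)
    stop_spotmatch("no usable photographs", "spotmatch_invalid_argument")

  mcfg <- if (cfg$matcher == "groth") groth_config() else aa_config()
  lk <- link_fragments(records, constellations, matcher = cfg$matcher,
                       cfg = mcfg, threshold = cfg$threshold, seed = cfg$seed)
  hist <- correct_capture_histories(lk$links, records, length(dirs))
  utils::write.csv(lk$decisions, file.path(cfg$out_dir, "decisions.csv"),
                   row.names = FALSE)
  write_capture_histories(hist, file.path(cfg$out_dir, "histories.csv"))

  out <- list(records = records, links = lk$links, decisions = lk$decisions,
              histories = hist)
  if (isTRUE(cfg$fit_survival) && length(dirs) >= 3 && nrow(hist) >= 2) {
    fit <- fit_cjs(hist, n_samples = max(1000, cfg$n_samples),
                   seed = cfg$seed, chains = 2)
    jsonlite::write_json(summary(fit), file.path(cfg$out_dir, "survival.json"),
                         auto_unbox = TRUE, digits = NA)
    out$survival <- fit
  }
  invisible(out)
}
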