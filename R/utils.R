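# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# All stochastic operations in the package take an explicit seed and go
# through this so no global RNG state leaks between calls.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_spotmatch <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "spotmatch_error", "error")))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_spotmatch(sprintf("`%s` must be a probability in [0, 1]", name),
                   "spotmatch_invalid_argument")
  x
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop_spotmatch(sprintf("`%s` must be a positive number", name),
                   "spotmatch_invalid_argument")
  x
}

# greyscale view of an image: H x W matrix in [0, 255]
to_grey <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3L)
    return(rowMeans(image, dims = 2L))
  stop_spotmatch("`image` must be an H x W matrix or H x W x C array",
                 "spotmatch_invalid_argument")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 2-D rotation matrix, angle in degrees, applied to row-vector coordinates
rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}
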