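# Internal helpers shared across modules.

#' Derive a component seed from a global seed
#'
#' Counter-based fan-out: each component draws its seed from the global seed
#' and a fixed integer index, so adding a component never perturbs the random
#' streams of existing ones. Result always fits in a 32-bit signed integer.
#'
#' @param seed Global integer seed.
#' @param idx Non-negative integer counter identifying the component.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
fan_seed <- function(seed, idx) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(idx))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.double(seed)) %% m)
  for (k in c(as.double(idx) %% m, 12345)) {
    s <- (s * 48271 + k + 1) %% m
  }
  as.integer(s %% (m - 2) + 1)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Hash a configuration object
#'
#' 32-bit FNV-1a hash over the deparsed object, used to stamp report rows so
#' that any row can be traced back to the exact configuration that produced it.
#'
#' @param x Any R object (typically a named list of settings).
#' @return Hex string of 8 characters.
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b)) + 2^30 # keep in range
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

is_gray_image <- function(img) {
  is.matrix(img) && is.numeric(img) && all(is.finite(img)) &&
    min(img) >= -1e-9 && max(img) <= 1 + 1e-9
}

assert_gray_image <- function(img, min_size = 1L) {
  if (!is.matrix(img) || !is.numeric(img))
    stop_param("expected a numeric matrix of intensities in [0,1]")
  if (nrow(img) < min_size || ncol(img) < min_size)
    stop_param("image too small: %dx%d (need at least %d pixels per side)",
               nrow(img), ncol(img), min_size)
  if (any(!is.finite(img)) || min(img) < -1e-9 || max(img) > 1 + 1e-9)
    stop_param("image intensities must be finite and within [0,1]")
  invisible(img)
}
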