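#' Synthetic sample textures
#'
#' Renders one of three texture families emulating typical microscope samples:
#' `regular_grid` (high-contrast periodic two-level pattern, as on
#' micro/nano-structured surfaces), `bar_target` (grouped parallel bars of
#' varying pitch, as on resolution test targets) and `speckle` (band-limited
#' random granularity, as on laser-processed metal substrates). Intensities are
#' rescaled so that the Michelson contrast `(max - min) / (max + min)` equals
#' the requested `contrast` exactly, around a mid-grey of 0.5.
#'
#' @param family One of `"regular_grid"`, `"bar_target"`, `"speckle"`.
#' @param size Image side length in pixels (square output), at least 8.
#' @param contrast Target Michelson contrast in `(0, 1]`.
#' @param seed Integer seed; identical arguments give bit-identical images.
#' @return A `size x size` numeric matrix with intensities in `[0, 1]`.
#' @examples
#' tex <- make_texture("speckle", 64, 0.5, seed = 1)
#' range(tex)
#' @export
texture_families <- function() c("regular_grid", "bar_target", "speckle")

#' @rdname texture_families
#' @export
make_texture <- function(family = texture_families(), size, contrast, seed = 1L) {
  family <- match.arg(family)
  if (!is.numeric(size) || length(size) != 1L || size < 8)
    stop_param("degenerate input: size must be >= 8 pixels, got %s", format(size))
  size <- as.integer(size)
  if (!is.numeric(contrast) || contrast <= 0 || contrast > 1)
    stop_param("contrast must lie in (0, 1], got %s", format(contrast))

  base <- with_seed(seed, switch(family,
    regular_grid = .tex_regular_grid(size),
    bar_target   = .tex_bar_target(size),
    speckle      = .tex_speckle(size)
  ))
  # map the [0,1] base pattern to [0.5(1-c), 0.5(1+c)]: exact Michelson contrast
  lo <- 0.5 * (1 - contrast)
  hi <- 0.5 * (1 + contrast)
  lo + (hi - lo) * base
}

# Checkerboard of random period/phase: periodic, exactly two-level. The cell
# period is kept coarse (>= size/8) so the pattern retains low-frequency
# content: under heavy Gaussian defocus a purely high-frequency pattern's
# residual oscillation would fall below double-precision resolution against
# the mid-grey level, flattening the sharpness curve tail.
.tex_regular_grid <- function(size) {
  period <- sample(max(4L, size %/% 8L):max(5L, size %/% 5L), 1L)
  phx <- sample.int(period, 1L) - 1L
  phy <- sample.int(period, 1L) - 1L
  i <- ((seq_len(size) - 1L + phx) %/% period)
  j <- ((seq_len(size) - 1L + phy) %/% period)
  (outer(i, j, `+`) %% 2L) * 1.0
}

# grouped parallel bars, pitch varying coarse-to-fine across groups
.tex_bar_target <- function(size) {
  n_groups <- 5L
  edges <- round(seq(0L, size, length.out = n_groups + 1L))
  pitches <- pmax(2L, round(size / (6 * seq_len(n_groups))))
  phase <- sample.int(64L, 1L)
  row_profile <- numeric(size)
  for (g in seq_len(n_groups)) {
    idx <- (edges[g] + 1L):edges[g + 1L]
    row_profile[idx] <- ((idx + phase) %/% pitches[g]) %% 2L
  }
  m <- matrix(row_profile, nrow = size, ncol = size, byrow = sample(c(TRUE, FALSE), 1L))
  m * 1.0
}

# band-limited granularity: white noise smoothed to a grain scale ~ size/32
.tex_speckle <- function(size) {
  noise <- matrix(stats::rnorm(size * size), size, size)
  sm <- as.matrix(EBImage::gblur(noise, sigma = max(1, size / 64),
                                 radius = .gblur_radius(max(1, size / 64), size)))
  (sm - min(sm)) / (max(sm) - min(sm))
}
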