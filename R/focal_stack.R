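# Focal stack simulation: voltage-indexed through-focus frame sequences.

# Gaussian kernel radius for EBImage::gblur, capped so the kernel fits the image.
.gblur_radius <- function(sigma, size) {
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  cap <- as.integer(size) - 1L
  if (cap %% 2L == 0L) cap <- cap - 1L
  max(3L, min(r, cap))
}

# Isotropic Gaussian defocus applied in the Fourier domain (periodic
# boundary). The Gaussian transfer function exp(-2 pi^2 sigma^2 |f|^2) is
# strictly decreasing in sigma at every non-zero spatial frequency, so any
# gradient-energy style sharpness of a blurred frame is strictly decreasing
# in sigma — this is what guarantees strictly unimodal sharpness curves on
# noiseless stacks, with no kernel-truncation artifacts at heavy defocus.
.blur <- function(img, sigma) {
  if (sigma <= 1e-12) return(img)
  h <- nrow(img); w <- ncol(img)
  fr <- c(0:(h %/% 2), -((h - h %/% 2 - 1):1)) / h
  fc <- c(0:(w %/% 2), -((w - w %/% 2 - 1):1)) / w
  H <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, `+`))
  out <- Re(stats::fft(stats::fft(img) * H, inverse = TRUE)) / (h * w)
  clamp(out, 0, 1)
}

#' Render a synthetic through-focus focal stack
#'
#' Simulates the acquisition of a complete focusing sweep
#' (defocused-focused-defocused) of a voltage-driven lens: frame `i` is the
#' sample texture convolved with an isotropic Gaussian point-spread function of
#' width `sigma(i) = psf_sigma0 + psf_slope * |i - focus_index|` pixels, plus
#' additive Gaussian sensor noise, clipped to `[0, 1]`. The voltage grid is
#' uniform: `voltage_grid[i] = v_start + (i - 1) * v_step`.
#'
#' Frame indices are 1-based throughout the package; on-disk artifacts written
#' by [write_stack()] use 0-based frame numbering.
#'
#' @param texture Numeric matrix in `[0,1]` (see [make_texture()]).
#' @param n_frames Number of frames (at least 3); default 100.
#' @param focus_index 1-based index of the ground-truth sharpest frame.
#' @param v_start Absolute voltage of the first frame (V). The algorithms only
#'   depend on the 0.1 V resolution; the origin defaults to 35 V.
#' @param v_step Voltage increment between frames (V), default 0.1.
#' @param psf_sigma0 Gaussian blur sigma at best focus (pixels).
#' @param psf_slope Blur growth per frame of defocus (pixels/frame), > 0.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity).
#' @param seed Integer seed controlling the noise; deterministic.
#' @param texture_family,sample_id Metadata labels carried by the stack.
#' @return An object of class `focal_stack`: list with `frames` (list of
#'   matrices), `voltage_grid`, `focus_index`, `texture_family`, `sample_id`
#'   and the simulation parameters.
#' @export
render_stack <- function(texture, n_frames = 100L, focus_index,
                         v_start = 35, v_step = 0.1,
                         psf_sigma0 = 0.5, psf_slope = 0.3,
                         noise_sd = 0.01, seed = 1L,
                         texture_family = "unknown", sample_id = NULL) {
  assert_gray_image(texture, min_size = 8L)
  if (!is.numeric(n_frames) || n_frames < 3)
    stop_param("n_frames must be at least 3, got %s", format(n_frames))
  n_frames <- as.integer(n_frames)
  if (!is.numeric(focus_index) || focus_index < 1 || focus_index > n_frames)
    stop_param("focus_index %s out of range 1..%d", format(focus_index), n_frames)
  focus_index <- as.integer(focus_index)
  if (v_step <= 0) stop_param("v_step must be positive")
  if (psf_slope <= 0) stop_param("psf_slope must be positive")

  frames <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    sigma <- psf_sigma0 + psf_slope * abs(i - focus_index)
    f <- .blur(texture, sigma)
    if (noise_sd > 0)
      f <- f + matrix(stats::rnorm(length(f), sd = noise_sd), nrow(f), ncol(f))
    clamp(f, 0, 1)
  }))
  structure(list(
    frames = frames,
    voltage_grid = v_start + (seq_len(n_frames) - 1) * v_step,
    focus_index = focus_index,
    texture_family = texture_family,
    sample_id = if (is.null(sample_id)) sprintf("stack_seed%d", as.integer(seed)) else sample_id,
    params = list(psf_sigma0 = psf_sigma0, psf_slope = psf_slope,
                  noise_sd = noise_sd, seed = as.integer(seed))
  ), class = "focal_stack")
}

#' @export
print.focal_stack <- function(x, ...) {
  cat(sprintf("<focal_stack> %s: %d frames %dx%d, %.2f-%.2f V (step %.3g V), focus at frame %d (%.2f V), family %s\n",
              x$sample_id, length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$voltage_grid[1], x$voltage_grid[length(x$voltage_grid)],
              x$voltage_grid[2] - x$voltage_grid[1],
              x$focus_index, x$voltage_grid[x$focus_index], x$texture_family))
  invisible(x)
}

n_frames <- function(stack) length(stack$frames)

v_step_of <- function(stack) {
  vg <- stack$voltage_grid
  if (length(vg) < 2) return(NA_real_)
  vg[2] - vg[1]
}

#' Augment a focal stack
#'
#' Applies the same photometric/geometric operation to every frame of the
#' stack, preserving the frame count, voltage grid and ground-truth focus
#' index. Available operations: `hflip`, `vflip` (mirror), `crop` (random crop
#' retaining at least half of each dimension, resized back to the original
#' resolution) and `gamma` (intensity exponent drawn from `gamma_range`).
#'
#' @param stack A `focal_stack`.
#' @param ops Character vector of operation names, applied in order.
#' @param seed Integer seed; parameters of random ops are drawn once per op.
#' @param gamma_range Range for the gamma exponent (use `c(1, 1)` for identity).
#' @param crop_min_frac Minimum retained fraction per dimension for `crop`,
#'   clamped to at least 0.5.
#' @return A new `focal_stack`.
#' @export
augment_stack <- function(stack, ops, seed = 1L,
                          gamma_range = c(0.7, 1.4), crop_min_frac = 0.7) {
  stopifnot(inherits(stack, "focal_stack"))
  known <- c("hflip", "vflip", "crop", "gamma")
  bad <- setdiff(ops, known)
  if (length(bad))
    stop_param("unknown augmentation op(s): %s", paste(bad, collapse = ", "))
  crop_min_frac <- max(0.5, crop_min_frac)
  frames <- stack$frames
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  with_seed(seed, {
    for (op in ops) {
      frames <- switch(op,
        hflip = lapply(frames, function(f) f[, ncol(f):1, drop = FALSE]),
        vflip = lapply(frames, function(f) f[nrow(f):1, , drop = FALSE]),
        gamma = {
          g <- stats::runif(1, gamma_range[1], gamma_range[2])
          lapply(frames, function(f) f^g)
        },
        crop = {
          fh <- stats::runif(1, crop_min_frac, 1)
          fw <- stats::runif(1, crop_min_frac, 1)
          ch <- max(8L, as.integer(round(fh * h)))
          cw <- max(8L, as.integer(round(fw * w)))
          r0 <- sample.int(h - ch + 1L, 1L)
          c0 <- sample.int(w - cw + 1L, 1L)
          lapply(frames, function(f) {
            cropped <- f[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
            clamp(as.matrix(EBImage::resize(EBImage::as.Image(cropped), w = h, h = w)), 0, 1)
          })
        })
    }
  })
  out <- stack
  out$frames <- frames
  out$sample_id <- paste0(stack$sample_id, "+", paste(ops, collapse = "+"))
  out
}

#' Build a list of synthetic focal stacks for training/evaluation
#'
#' Assembles the parallel list of state datasets sampled during training.
#' Stacks are distributed across the requested texture families as evenly as
#' possible (round-robin), each rendered from a disjoint derived seed, with the
#' ground-truth focus index drawn uniformly from the central 80% of the frame
#' range so every stack contains both defocus flanks. Default per-family
#' contrasts follow the emulated sample types: high (0.9) for `regular_grid`,
#' medium (0.5) for `bar_target` and `speckle`.
#'
#' @param n_stacks Number of stacks (>= 1).
#' @param families Character vector of texture families (non-empty).
#' @param n_frames Frames per stack, default 100.
#' @param size Frame side length in pixels, default 224.
#' @param seed Global seed; stack `i` uses `fan_seed(seed, i)`.
#' @param contrast Optional single contrast overriding the per-family defaults.
#' @param augment Fraction of stacks (0 to 1) to which a random augmentation is
#'   applied after rendering; default 0 (off).
#' @inheritParams render_stack
#' @return An object of class `state_dataset_list`: list with `stacks` and
#'   `family_counts`.
#' @export
build_dataset_list <- function(n_stacks, families, n_frames = 100L, size = 224L,
                               seed = 1L, contrast = NULL,
                               v_start = 35, v_step = 0.1,
                               psf_sigma0 = 0.5, psf_slope = 0.3,
                               noise_sd = 0.01, augment = 0) {
  if (!is.numeric(n_stacks) || n_stacks < 1)
    stop_param("n_stacks must be >= 1")
  if (length(families) == 0)
    stop_param("families must be a non-empty character vector")
  bad <- setdiff(families, texture_families())
  if (length(bad)) stop_param("unknown texture families: %s", paste(bad, collapse = ", "))
  n_stacks <- as.integer(n_stacks)
  default_contrast <- c(regular_grid = 0.9, bar_target = 0.5, speckle = 0.5)

  lo <- max(2L, as.integer(ceiling(0.1 * n_frames)))
  hi <- min(as.integer(n_frames) - 1L, as.integer(floor(0.9 * n_frames)))

  stacks <- lapply(seq_len(n_stacks), function(i) {
    fam <- families[((i - 1L) %% length(families)) + 1L]
    s <- fan_seed(seed, i)
    ctr <- if (is.null(contrast)) default_contrast[[fam]] else contrast
    focus <- with_seed(fan_seed(seed, i + n_stacks), sample(lo:hi, 1L))
    tex <- make_texture(fam, size, ctr, seed = s)
    st <- render_stack(tex, n_frames = n_frames, focus_index = focus,
                       v_start = v_start, v_step = v_step,
                       psf_sigma0 = psf_sigma0, psf_slope = psf_slope,
                       noise_sd = noise_sd, seed = fan_seed(seed, i + 2L * n_stacks),
                       texture_family = fam,
                       sample_id = sprintf("%s_%03d", fam, i))
    if (augment > 0 && with_seed(fan_seed(seed, i + 3L * n_stacks), stats::runif(1)) < augment) {
      op <- with_seed(fan_seed(seed, i + 4L * n_stacks),
                      sample(c("hflip", "vflip", "gamma"), 1L))
      st <- augment_stack(st, op, seed = fan_seed(seed, i + 5L * n_stacks))
    }
    st
  })
  fams <- vapply(stacks, function(s) s$texture_family, character(1))
  structure(list(stacks = stacks,
                 family_counts = table(factor(fams, levels = sort(unique(fams))))),
            class = "state_dataset_list")
}

#' Expand a dataset list with augmented copies
#'
#' Appends augmented variants (horizontal/vertical mirror, gamma) of every
#' stack, multiplying the list size by `length(variants) + 1`. Voltage grids
#' and focus indices are preserved; this emulates building many state
#' datasets per sample from few acquisitions via data augmentation.
#'
#' @param dataset_list A `state_dataset_list`.
#' @param variants List of character vectors of [augment_stack()] ops.
#' @param seed Seed for the stochastic ops (gamma exponent draw).
#' @return A larger `state_dataset_list`.
#' @export
augment_dataset_list <- function(dataset_list,
                                 variants = list("hflip", "vflip",
                                                 "gamma", c("hflip", "gamma")),
                                 seed = 1L) {
  stopifnot(inherits(dataset_list, "state_dataset_list"))
  stacks <- dataset_list$stacks
  out <- stacks
  for (vi in seq_along(variants)) {
    out <- c(out, lapply(seq_along(stacks), function(i)
      augment_stack(stacks[[i]], variants[[vi]],
                    seed = fan_seed(seed, vi * 1000L + i))))
  }
  fams <- vapply(out, function(s) s$texture_family, character(1))
  structure(list(stacks = out,
                 family_counts = table(factor(fams, levels = sort(unique(fams))))),
            class = "state_dataset_list")
}

#' @export
print.state_dataset_list <- function(x, ...) {
  cat(sprintf("<state_dataset_list> %d stacks (%s)\n", length(x$stacks),
              paste(sprintf("%s: %d", names(x$family_counts), x$family_counts),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.state_dataset_list <- function(x) length(x$stacks)

#' Write / read a focal stack on disk
#'
#' Frames are stored as 8-bit grayscale PNG files named
#' `frame_{index:03d}_v{voltage:.2f}.png` (0-based indices) together with a
#' JSON sidecar `stack.json` holding the voltage grid, the (0-based) focus
#' index, texture family, sample id and simulation parameters.
#' `read_stack(write_stack(s))` reproduces frame order, voltages and focus
#' index exactly, and pixels to within 8-bit quantization (1/255).
#'
#' @param stack A `focal_stack`.
#' @param dir_path Directory to create/read.
#' @return `write_stack` returns `dir_path` invisibly; `read_stack` returns a
#'   `focal_stack`.
#' @export
write_stack <- function(stack, dir_path) {
  stopifnot(inherits(stack, "focal_stack"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  n <- n_frames(stack)
  files <- sprintf("frame_%03d_v%.2f.png", seq_len(n) - 1L, stack$voltage_grid)
  for (i in seq_len(n))
    png::writePNG(stack$frames[[i]], file.path(dir_path, files[i]))
  sidecar <- list(
    format = "focusrl_stack_v1",
    n_frames = n,
    index_base = 0L,
    voltage_grid = stack$voltage_grid,
    focus_index = stack$focus_index - 1L, # 0-based on disk
    texture_family = stack$texture_family,
    sample_id = stack$sample_id,
    params = stack$params,
    files = files
  )
  jsonlite::write_json(sidecar, file.path(dir_path, "stack.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir_path)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir_path) {
  sidecar_path <- file.path(dir_path, "stack.json")
  if (!file.exists(sidecar_path))
    stop_param("malformed stack directory: missing sidecar %s", sidecar_path)
  sc <- tryCatch(jsonlite::read_json(sidecar_path, simplifyVector = TRUE),
                 error = function(e) stop_param("malformed sidecar: %s", conditionMessage(e)))
  need <- c("n_frames", "voltage_grid", "focus_index", "files")
  if (!all(need %in% names(sc)))
    stop_param("malformed sidecar: missing field(s) %s",
               paste(setdiff(need, names(sc)), collapse = ", "))
  n <- as.integer(sc$n_frames)
  ord <- order(sc$voltage_grid) # read in voltage order regardless of listing order
  frames <- vector("list", n)
  for (k in seq_len(n)) {
    i <- ord[k]
    f <- file.path(dir_path, sc$files[i])
    if (!file.exists(f))
      stop_param("missing frame file for index %d: %s", i - 1L, sc$files[i])
    frames[[k]] <- png::readPNG(f)
  }
  structure(list(
    frames = frames,
    voltage_grid = as.numeric(sc$voltage_grid)[ord],
    # focus_index in the sidecar refers to listing order; remap to voltage order
    focus_index = match(as.integer(sc$focus_index) + 1L, ord),
    texture_family = if (is.null(sc$texture_family)) "unknown" else sc$texture_family,
    sample_id = if (is.null(sc$sample_id)) basename(dir_path) else sc$sample_id,
    params = sc$params
  ), class = "focal_stack")
}
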