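# Sharpness (clarity) evaluation functions and per-stack curve normalization.

#' Energy (squared-gradient) focus measure
#'
#' Sum over pixels of the squared first differences in both image directions,
#' with out-of-range neighbours omitted:
#' `sum((I[x+1,y]-I[x,y])^2) + sum((I[x,y+1]-I[x,y])^2)`. This squared-gradient
#' "Energy" measure peaks at best focus and is zero for a constant image.
#'
#' @param img Numeric matrix of intensities in `[0, 1]`.
#' @return Non-negative scalar.
#' @export
energy_gradient <- function(img) {
  assert_gray_image(img)
  dx <- img[, -1L, drop = FALSE] - img[, -ncol(img), drop = FALSE]
  dy <- img[-1L, , drop = FALSE] - img[-nrow(img), , drop = FALSE]
  sum(dx * dx) + sum(dy * dy)
}

#' Evaluate a named focus measure
#'
#' Standard set of sharpness functions: `energy` (squared gradient, see
#' [energy_gradient()]), `tenengrad` (Sobel gradient energy), `laplacian`
#' (squared 4-neighbour Laplacian), `variance` (intensity variance) and
#' `brenner` (squared differences at offset 2). All are non-negative, zero on a
#' constant image, flip-invariant, and rank an image above any blurred copy of
#' itself.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param name Measure name.
#' @return Non-negative scalar.
#' @export
measure <- function(img, name = c("energy", "tenengrad", "laplacian",
                                  "variance", "brenner")) {
  if (length(name) != 1L || !name %in% c("energy", "tenengrad", "laplacian",
                                         "variance", "brenner"))
    stop_param("unknown focus measure: %s", paste(name, collapse = ","))
  assert_gray_image(img)
  switch(name,
    energy = energy_gradient(img),
    variance = {
      m <- mean(img)
      mean((img - m)^2)
    },
    brenner = {
      n <- ncol(img); m <- nrow(img)
      dx <- if (n > 2) img[, 3:n, drop = FALSE] - img[, 1:(n - 2), drop = FALSE] else 0
      dy <- if (m > 2) img[3:m, , drop = FALSE] - img[1:(m - 2), , drop = FALSE] else 0
      sum(dx * dx) + sum(dy * dy)
    },
    tenengrad = {
      m <- nrow(img); n <- ncol(img)
      if (m < 3 || n < 3) return(0)
      ri <- 2:(m - 1); ci <- 2:(n - 1)
      # Sobel responses on the interior
      gx <- (img[ri - 1, ci + 1] + 2 * img[ri, ci + 1] + img[ri + 1, ci + 1]) -
            (img[ri - 1, ci - 1] + 2 * img[ri, ci - 1] + img[ri + 1, ci - 1])
      gy <- (img[ri + 1, ci - 1] + 2 * img[ri + 1, ci] + img[ri + 1, ci + 1]) -
            (img[ri - 1, ci - 1] + 2 * img[ri - 1, ci] + img[ri - 1, ci + 1])
      sum(gx * gx + gy * gy)
    },
    laplacian = {
      m <- nrow(img); n <- ncol(img)
      if (m < 3 || n < 3) return(0)
      ri <- 2:(m - 1); ci <- 2:(n - 1)
      lap <- 4 * img[ri, ci] - img[ri - 1, ci] - img[ri + 1, ci] -
             img[ri, ci - 1] - img[ri, ci + 1]
      sum(lap * lap)
    })
}

#' Sharpness curve of a focal stack
#'
#' Evaluates a focus measure on every frame of the stack.
#'
#' @param stack A `focal_stack`.
#' @param name Focus measure name (see [measure()]).
#' @return An object of class `sharpness_curve`: list with `values` (one per
#'   frame) and `measure_name`.
#' @export
sharpness_curve <- function(stack, name = "energy") {
  stopifnot(inherits(stack, "focal_stack"))
  vals <- vapply(stack$frames, measure, numeric(1), name = name)
  structure(list(values = vals, measure_name = name), class = "sharpness_curve")
}

#' Min-max normalize a sharpness curve
#'
#' Maps values to `(v - min) / (max - min)` in `[0, 1]` so that evaluation
#' values are comparable across frames of the same stack taken under varying
#' voltages. The argmax is preserved; the maximum becomes exactly 1 and the
#' minimum exactly 0.
#'
#' @param curve A `sharpness_curve` or bare numeric vector.
#' @return Same type as the input, normalized.
#' @export
normalize_curve <- function(curve) {
  vals <- if (inherits(curve, "sharpness_curve")) curve$values else curve
  if (!is.numeric(vals) || length(vals) < 1 || any(!is.finite(vals)))
    stop_param("curve values must be finite numerics")
  rng <- range(vals)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2])))
    stop_param("degenerate curve: max equals min, cannot normalize")
  out <- (vals - rng[1]) / (rng[2] - rng[1])
  if (inherits(curve, "sharpness_curve")) {
    curve$values <- out
    curve
  } else out
}
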