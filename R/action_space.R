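# Discrete voltage-adjustment action sets.
#
# An action is a signed integer control factor tau multiplying the voltage
# resolution v (one focal-stack frame per unit factor, v = 0.1 V by default):
# a = tau * v. Factor 0 is the stop action. Two constructions are provided:
#   logarithmic: {0, +-b^j : j = 0..(n_A-3)/2}
#   multiple:    {0, +-1} U {+-k*b : k = 1..(n_A-3)/2}
# For b = 2 and n_A = 7 the two coincide: (-4,-2,-1,0,1,2,4).

#' Build a discrete voltage action set
#'
#' @param b Integer base, at least 2, controlling the factor spacing.
#' @param n_A Odd action-space size, at least 3 (forward, backward, stop).
#' @param method `"logarithmic"` (powers of `b`) or `"multiple"` (integer
#'   multiples of `b` above the unit step).
#' @param v_step Voltage resolution per unit control factor (V), default 0.1.
#' @return Object of class `action_set`: list with sorted `control_factors`
#'   (including 0 and +-1, symmetric about 0), `base_b`, `method`, `v_step`.
#' @examples
#' build_action_set(5, 7, "logarithmic")$control_factors # -25 -5 -1 0 1 5 25
#' build_action_set(3, 7, "multiple")$control_factors    # -6 -3 -1 0 1 3 6
#' @export
build_action_set <- function(b, n_A, method = c("logarithmic", "multiple"),
                             v_step = 0.1) {
  method <- match.arg(method)
  if (!is.numeric(b) || length(b) != 1L || b < 2 || b != round(b))
    stop_param("base b must be an integer >= 2, got %s", format(b))
  if (!is.numeric(n_A) || length(n_A) != 1L || n_A < 3 || n_A %% 2 != 1)
    stop_param("n_A must be an odd integer >= 3, got %s", format(n_A))
  if (v_step <= 0) stop_param("v_step must be positive")
  b <- as.integer(b); n_A <- as.integer(n_A)
  k <- (n_A - 3L) %/% 2L
  pos <- if (method == "logarithmic") {
    b^(0:k)
  } else {
    c(1L, if (k >= 1L) seq_len(k) * b)
  }
  factors <- sort(unique(c(-pos, 0L, pos)))
  stopifnot(length(factors) == n_A)
  structure(list(control_factors = as.integer(factors), base_b = b,
                 method = method, v_step = v_step),
            class = "action_set")
}

#' @export
print.action_set <- function(x, ...) {
  cat(sprintf("<action_set> %s base %d, n_A=%d, v=%.3g V: (%s)\n",
              x$method, x$base_b, length(x$control_factors), x$v_step,
              paste(x$control_factors, collapse = ",")))
  invisible(x)
}

#' @export
format.action_set <- function(x, ...) {
  paste0("(", paste(x$control_factors, collapse = ","), ")")
}

#' Check that an action space fits a state range
#'
#' An action set is admissible for a sweep of `n_S` frames when its largest
#' control factor does not overshoot half the state range:
#' `b^((n_A - 3)/2) <= n_S / 2`.
#'
#' @param b Base. @param n_A Odd action-space size. @param n_S Frame count.
#' @return Logical.
#' @examples
#' check_action_space(5, 7, 100) # TRUE: 25 <= 50
#' check_action_space(5, 9, 100) # FALSE: 125 > 50
#' @export
check_action_space <- function(b, n_A, n_S) {
  stopifnot(b >= 2, n_A >= 3, n_S >= 1)
  b^((n_A - 3) / 2) <= n_S / 2
}

#' Apply a control factor to a frame index
#'
#' Moves the current frame index by `factor` frames, clipping at the sweep
#' boundaries (the physical lens saturates at its voltage limits; boundary
#' moves never error).
#'
#' @param index Current 1-based frame index.
#' @param factor Signed integer control factor.
#' @param n_frames Number of frames in the sweep.
#' @return New 1-based frame index in `[1, n_frames]`.
#' @export
apply_action <- function(index, factor, n_frames) {
  if (!is.numeric(index) || index < 1 || index > n_frames)
    stop_param("index %s out of range 1..%d", format(index), n_frames)
  as.integer(clamp(index + factor, 1L, as.integer(n_frames)))
}

#' Minimal move counts for an action set (breadth-first search)
#'
#' Exact minimum number of non-stop moves needed to reach `target` from every
#' start index, under boundary clipping. Used as an oracle lower bound on any
#' policy's step count (one stop action must be added to terminate).
#'
#' @param action_set An `action_set`.
#' @param n_frames Frame count.
#' @param target Target 1-based index.
#' @return Integer vector of length `n_frames`; moves from each start index.
#' @export
bfs_min_moves <- function(action_set, n_frames, target) {
  stopifnot(inherits(action_set, "action_set"),
            target >= 1, target <= n_frames)
  moves <- setdiff(action_set$control_factors, 0L)
  dist <- rep(NA_integer_, n_frames)
  dist[target] <- 0L
  frontier <- as.integer(target)
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- integer(0)
    for (i in frontier) {
      # predecessors j with clamp(j + m) == i
      for (m in moves) {
        js <- i - m
        if (js >= 1 && js <= n_frames && is.na(dist[js])) {
          dist[js] <- d; nxt <- c(nxt, js)
        }
        # clipped transitions into the boundaries
        if (i == 1L && m < 0) {
          js <- seq_len(min(n_frames, 1L - m - 1L))
          js <- js[is.na(dist[js]) & js + m < 1L]
          if (length(js)) { dist[js] <- d; nxt <- c(nxt, js) }
        }
        if (i == n_frames && m > 0) {
          js <- seq.int(max(1L, n_frames - m + 1L), n_frames)
          js <- js[is.na(dist[js]) & js + m > n_frames]
          if (length(js)) { dist[js] <- d; nxt <- c(nxt, js) }
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist
}
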