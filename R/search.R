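# Classical autofocus baselines: exhaustive sweep, golden-section and
# Fibonacci search over the (unimodal) sharpness curve of a focal stack.
#
# "Probes" counts distinct sharpness evaluations, i.e. image captures at a
# lens setting; probed values are cached so no index is ever evaluated twice.
# Both bracketing searches shrink the interval to at most tol_indices frames
# and then evaluate the few remaining interior points, so on a strictly
# unimodal curve they return the exact global argmax.

.searcher <- function(stack, measure_name) {
  cache <- new.env(parent = emptyenv())
  trace <- integer(0)
  probe <- function(i) {
    key <- as.character(i)
    if (is.null(cache[[key]])) {
      cache[[key]] <- measure(stack$frames[[i]], measure_name)
      trace <<- c(trace, as.integer(i))
    }
    cache[[key]]
  }
  result <- function() {
    vals <- vapply(trace, function(i) cache[[as.character(i)]], numeric(1))
    best <- trace[which.max(vals)]
    structure(list(best_index = best, probes = length(trace), trace = trace,
                   best_voltage = stack$voltage_grid[best]),
              class = "search_result")
  }
  list(probe = probe, result = result)
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> best index %d (%.2f V) after %d probes\n",
              x$best_index, x$best_voltage, x$probes))
  invisible(x)
}

#' Exhaustive sweep search
#'
#' Probes every frame and returns the global argmax of the focus measure; the
#' brute-force oracle the bracketing searches are checked against.
#'
#' @param stack A `focal_stack`.
#' @param measure Focus measure name (see [measure()]).
#' @return A `search_result`: `best_index`, `probes`, `trace`.
#' @export
sweep_search <- function(stack, measure = "energy") {
  stopifnot(inherits(stack, "focal_stack"))
  if (length(stack$frames) == 0) stop_param("empty stack")
  s <- .searcher(stack, measure)
  for (i in seq_along(stack$frames)) s$probe(i)
  s$result()
}

#' Golden-section search over a focal stack
#'
#' Derivative-free bracketing search for the sharpness maximum of a unimodal
#' curve (guaranteed for noiseless synthetic stacks). Interior probe positions
#' follow the golden ratio; the bracket is shrunk until its width is at most
#' `tol_indices` frames, after which all remaining interior frames are probed
#' and the best probed index returned. Probes are cached (never re-probed).
#'
#' With `N` frames the probe count is bounded by
#' `2 + ceil(log((N-1)/tol) / log(phi)) + (tol + 1)` where `phi ~ 1.618`
#' (two initial probes, one new probe per iteration, final cleanup).
#'
#' @param stack A `focal_stack`.
#' @param measure Focus measure name.
#' @param tol_indices Bracket width (frames) at which iteration stops;
#'   default 2 frames = 0.2 V at the default resolution, matching the success
#'   tolerance.
#' @return A `search_result`.
#' @export
golden_section_search <- function(stack, measure = "energy", tol_indices = 2L) {
  stopifnot(inherits(stack, "focal_stack"))
  n <- length(stack$frames)
  if (n == 0) stop_param("empty stack")
  s <- .searcher(stack, measure)
  if (n <= tol_indices + 1L) {
    for (i in seq_len(n)) s$probe(i)
    return(s$result())
  }
  invphi <- (sqrt(5) - 1) / 2
  lo <- 1L; hi <- n
  x1 <- clamp(lo + as.integer(round((1 - invphi) * (hi - lo))), lo + 1L, hi - 1L)
  x2 <- clamp(lo + as.integer(round(invphi * (hi - lo))), x1, hi - 1L)
  if (x2 == x1) x2 <- x1 + 1L
  f1 <- s$probe(x1); f2 <- s$probe(x2)
  while (hi - lo > tol_indices) {
    if (f1 < f2) {
      lo <- x1
      x1 <- x2; f1 <- f2
      x2 <- lo + as.integer(round(invphi * (hi - lo)))
      if (x2 <= x1) x2 <- x1 + 1L
      if (x2 >= hi) break
      f2 <- s$probe(x2)
    } else {
      hi <- x2
      x2 <- x1; f2 <- f1
      x1 <- lo + as.integer(round((1 - invphi) * (hi - lo)))
      if (x1 >= x2) x1 <- x2 - 1L
      if (x1 <= lo) break
      f1 <- s$probe(x1)
    }
  }
  for (i in lo:hi) s$probe(i)
  s$result()
}

#' Fibonacci search over a focal stack
#'
#' Like [golden_section_search()] but the interval is reduced on the Fibonacci
#' ratio schedule, which is probe-optimal for a fixed evaluation budget on a
#' lattice. For `N` frames the probe count is at most the smallest `k` with
#' `F(k) >= N` (`F(1) = F(2) = 1`); e.g. 12 probes for `N = 100`.
#'
#' @inheritParams golden_section_search
#' @return A `search_result`.
#' @export
fibonacci_search <- function(stack, measure = "energy", tol_indices = 2L) {
  stopifnot(inherits(stack, "focal_stack"))
  n <- length(stack$frames)
  if (n == 0) stop_param("empty stack")
  s <- .searcher(stack, measure)
  if (n <= max(3L, tol_indices + 1L)) {
    for (i in seq_len(n)) s$probe(i)
    return(s$result())
  }
  fib <- c(1, 1)
  while (fib[length(fib)] < n + 1L) fib <- c(fib, sum(utils::tail(fib, 2)))
  k <- length(fib)
  # Work on the conceptual lattice 1..F(k)-1: positions beyond n are virtual
  # (-Inf, never probed), which keeps the Fibonacci interval structure intact
  # at the right edge instead of wasting probes on clamped positions.
  pv <- function(i) if (i > n) -Inf else s$probe(i)
  lo <- 0L; hi <- as.integer(fib[k])
  x1 <- lo + as.integer(fib[k - 2L])
  x2 <- lo + as.integer(fib[k - 1L])
  f1 <- pv(x1); f2 <- pv(x2)
  k <- k - 1L
  while (min(hi, n + 1L) - lo - 1L > tol_indices && k > 2L) {
    if (f1 < f2) {
      lo <- x1
      x1 <- x2; f1 <- f2
      x2 <- lo + as.integer(fib[k - 1L])
      k <- k - 1L
      if (x2 >= hi) break
      f2 <- pv(x2)
    } else {
      hi <- x2
      x2 <- x1; f2 <- f1
      x1 <- lo + as.integer(fib[k - 2L])
      k <- k - 1L
      if (x1 <= lo) break
      f1 <- pv(x1)
    }
  }
  for (i in max(1L, lo):min(n, hi)) s$probe(i)
  s$result()
}
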