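# Hybrid shaped reward for the autofocus task.
#
# Per step the agent receives a sum of four gated components:
#   sharpness: -alpha * (1 - Fc_norm)   (orientation "corrected"; the literal
#              printed form -alpha * Fc_norm is kept behind orientation =
#              "literal" for comparison — see the methods vignette)
#   time step: -beta * ln(n / beta)     positive for n < beta, zero at n = beta
#   stop:      +mu when the agent stops correctly near focus (Done flag)
#   extra:     +delta at the stack's ground-truth sharpest frame,
#              -delta at a least-sharp frame (normalized sharpness <= 0.05)

#' Reward parameters and component gates
#'
#' Defaults follow the tuned values `alpha = 100`, `beta = 30`, `mu = 200`,
#' `delta = 100`, chosen so the maximum magnitude of each component is on the
#' same order. The four logical gates switch components on/off for ablations
#' (see [variant_gates()]).
#'
#' @param alpha Sharpness scale (> 0).
#' @param beta Step-penalty coefficient (> 0); the time component changes sign
#'   at `n = beta` steps.
#' @param mu Stop-reward coefficient (> 0).
#' @param delta Extreme-image bonus magnitude (> 0).
#' @param sharpness_on,time_on,stop_on,extra_on Component gates.
#' @param orientation `"corrected"` (sharpest frame incurs zero penalty) or
#'   `"literal"` (the printed form, which penalizes high sharpness).
#' @param extra_scope `"every_step"` grants the extreme-image bonus whenever
#'   the agent is at an extreme frame; `"stop_only"` grants it only on the
#'   stop step. Under the corrected orientation `"every_step"` makes the
#'   clearest-image bonus collectable indefinitely by loitering at focus,
#'   which defeats autonomous stopping; see the methods vignette.
#' @return Object of class `reward_params`.
#' @export
reward_params <- function(alpha = 100, beta = 30, mu = 200, delta = 100,
                          sharpness_on = TRUE, time_on = TRUE,
                          stop_on = TRUE, extra_on = TRUE,
                          orientation = c("corrected", "literal"),
                          extra_scope = c("every_step", "stop_only")) {
  orientation <- match.arg(orientation)
  extra_scope <- match.arg(extra_scope)
  for (nm in c("alpha", "beta", "mu", "delta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop_param("%s must be a positive scalar", nm)
  }
  structure(list(alpha = alpha, beta = beta, mu = mu, delta = delta,
                 sharpness_on = isTRUE(sharpness_on), time_on = isTRUE(time_on),
                 stop_on = isTRUE(stop_on), extra_on = isTRUE(extra_on),
                 orientation = orientation, extra_scope = extra_scope),
            class = "reward_params")
}

#' Compute the per-step reward
#'
#' @param fc_norm Normalized sharpness of the current frame, in `[0, 1]`
#'   (per-stack min-max normalization, see [normalize_curve()]).
#' @param n Step count within the episode (>= 1; the first action's reward
#'   uses `n = 1`).
#' @param stop_correct Logical Done flag: the agent stopped within the success
#'   tolerance of the optimal focus.
#' @param extreme One of `"neither"`, `"sharpest"` (current frame is the
#'   stack's ground-truth sharpest) or `"least_sharp"`.
#' @param params A [reward_params()] object.
#' @return Scalar reward.
#' @examples
#' p <- reward_params()
#' compute_reward(1, 30, FALSE, "sharpest", p)            # +100
#' compute_reward(0.5, 60, TRUE, "neither", p)            # -50 - 30*log(2) + 200
#' @export
compute_reward <- function(fc_norm, n, stop_correct, extreme = "neither",
                           params = reward_params()) {
  stopifnot(inherits(params, "reward_params"))
  if (!is.numeric(fc_norm) || fc_norm < -1e-12 || fc_norm > 1 + 1e-12)
    stop_param("fc_norm must lie in [0,1], got %s", format(fc_norm))
  if (!is.numeric(n) || n < 1)
    stop_param("step count n must be >= 1, got %s", format(n))
  if (!extreme %in% c("neither", "sharpest", "least_sharp"))
    stop_param("unknown extreme label: %s", extreme)
  fc_norm <- clamp(fc_norm, 0, 1)
  r <- 0
  if (params$sharpness_on)
    r <- r + if (params$orientation == "corrected") -params$alpha * (1 - fc_norm)
             else -params$alpha * fc_norm
  if (params$time_on)
    r <- r - params$beta * log(n / params$beta)
  if (params$stop_on && isTRUE(stop_correct))
    r <- r + params$mu
  if (params$extra_on)
    r <- r + switch(extreme, sharpest = params$delta,
                    least_sharp = -params$delta, neither = 0)
  r
}

#' Component gates for the five ablation reward variants
#'
#' Variant 1: sharpness only; 2: sharpness + stop; 3: sharpness + time step;
#' 4: sharpness + extra; 5: all four components (the full hybrid reward).
#'
#' @param variant Integer in 1..5.
#' @return Named list of the four logical gates, suitable for splicing into
#'   [reward_params()].
#' @export
variant_gates <- function(variant) {
  if (!is.numeric(variant) || length(variant) != 1L || !variant %in% 1:5)
    stop_param("variant must be an integer in 1..5, got %s", format(variant))
  list(sharpness_on = TRUE,
       time_on  = variant %in% c(3, 5),
       stop_on  = variant %in% c(2, 5),
       extra_on = variant %in% c(4, 5))
}
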