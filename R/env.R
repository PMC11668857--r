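# Episodic autofocus environment.
#
# An episode: a focal stack is drawn uniformly at random from the state
# dataset list, the lens starts at a uniformly random voltage (frame index),
# and each step the agent either moves the voltage by a signed control factor
# (boundary-clipped) or issues the stop action. Rewards follow compute_reward()
# on the per-stack normalized Energy sharpness curve. An episode ends on stop
# (by default; see done_gated_termination) or by truncation at max_steps.
#
# Implemented as a mutable environment object with all per-stack observation
# matrices and sharpness curves precomputed, so stepping is cheap.

#' Create an autofocus environment
#'
#' @param dataset_list A [build_dataset_list()] result (non-empty).
#' @param action_set An [build_action_set()] result.
#' @param reward A [reward_params()] object.
#' @param max_steps Episode truncation limit (steps), default 50.
#' @param tolerance_volts Success tolerance on the final voltage deviation (V);
#'   0.2 V by default, also the "near focus" window gating the stop reward.
#' @param obs_resolution Side length the observed frame is resized to; `NULL`
#'   keeps the native stack resolution.
#' @param obs_features Character subset of `c("frame", "diff", "prev_action",
#'   "step")`: pixels of the current frame, pixel difference to the previous
#'   frame, one-hot of the previous action, and normalized step count. The
#'   default observes the raw frame only; the sequence features address the
#'   direction ambiguity of symmetric defocus (see the methods vignette).
#' @param done_gated_termination If `TRUE`, the stop action ends the episode
#'   only when it is correct (within tolerance); an incorrect stop is a no-op
#'   move that still consumes a step. Default `FALSE`: stop always terminates.
#' @param least_sharp_threshold Normalized sharpness at or below which a frame
#'   counts as "least sharp" for the extreme-image reward component.
#' @param measure Focus measure used for the reward curve.
#' @param obs_encoder `"pixels"` exposes the raw (centered) pixel vector of
#'   the observed frame; `"randconv"` exposes a fixed, seeded random
#'   filter-bank embedding (translation-invariant multi-band texture-energy
#'   features) precomputed per frame. The encoder is part of the observation
#'   plumbing and is never trained; see the methods vignette.
#' @param encoder_seed Seed of the random filter bank (must match between
#'   training and evaluation environments; kept in the agent's config).
#' @param encoder_scales Optional list of filter-bank scales, each
#'   `c(down =, size =, n =)`; `NULL` uses the default three-scale bank.
#' @return Object of class `af_env` (a mutable environment).
#' @export
af_env <- function(dataset_list, action_set, reward = reward_params(),
                   max_steps = 50L, tolerance_volts = 0.2,
                   obs_resolution = NULL,
                   obs_features = "frame",
                   done_gated_termination = FALSE,
                   least_sharp_threshold = 0.05,
                   measure = "energy",
                   obs_encoder = c("pixels", "randconv"),
                   encoder_seed = 777L,
                   encoder_scales = NULL) {
  obs_encoder <- match.arg(obs_encoder)
  if (!inherits(dataset_list, "state_dataset_list") || length(dataset_list$stacks) == 0)
    stop_param("dataset_list must be a non-empty state_dataset_list")
  stopifnot(inherits(action_set, "action_set"), inherits(reward, "reward_params"))
  bad <- setdiff(obs_features, c("frame", "diff", "prev_action", "step"))
  if (length(bad)) stop_param("unknown obs_features: %s", paste(bad, collapse = ", "))
  if (!"frame" %in% obs_features) obs_features <- c("frame", obs_features)
  if (max_steps < 1) stop_param("max_steps must be >= 1")

  e <- new.env(parent = emptyenv())
  e$stacks <- dataset_list$stacks
  e$n_stacks <- length(e$stacks)
  e$factors <- action_set$control_factors
  e$n_actions <- length(e$factors)
  e$stop_action <- which(e$factors == 0L)
  e$action_set <- action_set
  e$reward <- reward
  e$max_steps <- as.integer(max_steps)
  e$tolerance <- tolerance_volts
  e$obs_features <- obs_features
  e$done_gated <- isTRUE(done_gated_termination)
  e$least_sharp_threshold <- least_sharp_threshold

  first <- e$stacks[[1]]
  nf <- length(first$frames)
  res <- if (is.null(obs_resolution)) nrow(first$frames[[1]]) else as.integer(obs_resolution)
  e$obs_resolution <- res
  e$n_frames <- nf
  e$v_step <- v_step_of(first)

  e$obs_encoder <- obs_encoder
  e$encoder <- if (obs_encoder == "randconv") {
    if (is.null(encoder_scales)) .make_encoder(encoder_seed)
    else .make_encoder(encoder_seed, encoder_scales)
  } else NULL

  # precompute per stack: centered pixel matrix (d x n_frames), encoded
  # observation matrix, and the normalized sharpness curve
  e$native <- nrow(first$frames[[1]]) == res
  e$Praw <- if (e$native && obs_encoder == "randconv") NULL
            else vector("list", e$n_stacks)
  e$P <- vector("list", e$n_stacks)
  e$fc <- vector("list", e$n_stacks)
  e$focus <- integer(e$n_stacks)
  for (i in seq_len(e$n_stacks)) {
    st <- e$stacks[[i]]
    if (length(st$frames) != nf)
      stop_param("all stacks in the list must share the frame count")
    resized <- lapply(st$frames, function(f) {
      if (nrow(f) != res)
        f <- clamp(as.matrix(EBImage::resize(EBImage::as.Image(f), w = res, h = res)), 0, 1)
      f
    })
    if (!is.null(e$Praw))
      e$Praw[[i]] <- vapply(resized, function(f) as.numeric(f) - 0.5, numeric(res * res))
    e$P[[i]] <- if (obs_encoder == "randconv") {
      vapply(resized, function(f) .encode_frame(f - 0.5, e$encoder),
             numeric(e$encoder$dim))
    } else e$Praw[[i]]
    e$fc[[i]] <- normalize_curve(sharpness_curve(st, measure))$values
    e$focus[i] <- st$focus_index
  }
  # single concatenated observation matrix for fast batch gathers
  e$Pall <- do.call(cbind, e$P)
  e$poff <- (seq_len(e$n_stacks) - 1L) * nf
  e$P <- NULL
  d <- nrow(e$Pall)
  e$layout <- list(
    frame = d,
    diff = if ("diff" %in% obs_features) d else 0L,
    prev_action = if ("prev_action" %in% obs_features) e$n_actions else 0L,
    step = if ("step" %in% obs_features) 1L else 0L
  )
  e$feat_dim <- sum(unlist(e$layout))
  e$active <- FALSE
  class(e) <- c("af_env", "environment")
  e
}

#' @export
print.af_env <- function(x, ...) {
  cat(sprintf("<af_env> %d stacks x %d frames, obs %dx%d (features: %s), actions (%s), max_steps %d%s\n",
              x$n_stacks, x$n_frames, x$obs_resolution, x$obs_resolution,
              paste(x$obs_features, collapse = "+"),
              paste(x$factors, collapse = ","), x$max_steps,
              if (x$done_gated) ", done-gated termination" else ""))
  invisible(x)
}

# Assemble feature vectors for (stack, index, prev index, prev action, n).
# Vectorized over equal-length inputs; returns feat_dim x B matrix.
env_features <- function(env, stack_i, idx, prev_idx, prev_action, n) {
  B <- length(idx)
  d <- env$layout$frame
  cur <- env$Pall[, env$poff[stack_i] + idx, drop = FALSE]
  out <- matrix(0, env$feat_dim, B)
  out[seq_len(d), ] <- cur
  off <- d
  if (env$layout$diff > 0) {
    out[off + seq_len(d), ] <- cur - env$Pall[, env$poff[stack_i] + prev_idx, drop = FALSE]
    off <- off + d
  }
  if (env$layout$prev_action > 0) {
    has <- which(prev_action > 0)
    if (length(has))
      out[cbind(off + prev_action[has], has)] <- 1
    off <- off + env$layout$prev_action
  }
  if (env$layout$step > 0)
    out[off + 1L, ] <- n / env$max_steps
  out
}

.env_obs <- function(env) {
  frame <- if (is.null(env$Praw)) env$stacks[[env$cur_stack]]$frames[[env$cur_idx]]
           else matrix(env$Praw[[env$cur_stack]][, env$cur_idx] + 0.5,
                       env$obs_resolution, env$obs_resolution)
  list(features = env_features(env, env$cur_stack, env$cur_idx,
                               env$prev_idx, env$prev_action, env$n)[, 1],
       frame = frame, n = env$n)
}

#' Start a new episode
#'
#' Draws a stack uniformly from the list and a start frame uniformly over all
#' frames (the success zone is not excluded), and zeroes the step counter.
#' Uses R's global random number generator; seed with [set.seed()].
#'
#' @param env An `af_env`.
#' @return Observation: list with `features` (numeric vector), `frame`
#'   (matrix) and `n` (step count, 0 at reset).
#' @export
env_reset <- function(env) {
  stopifnot(inherits(env, "af_env"))
  env$cur_stack <- sample.int(env$n_stacks, 1L)
  env$start_idx <- env$cur_idx <- sample.int(env$n_frames, 1L)
  env$prev_idx <- env$cur_idx
  env$prev_action <- 0L
  env$n <- 0L
  env$return_ <- 0
  env$active <- TRUE
  .env_obs(env)
}

#' Advance the environment by one action
#'
#' Non-stop actions move the frame index by the action's control factor
#' (clipped at the sweep boundaries). The stop action terminates the episode
#' (always, unless the environment was created with `done_gated_termination`,
#' in which case only a correct stop terminates). Episodes are truncated at
#' `max_steps` without a stop.
#'
#' @param env An `af_env` with an active episode (see [env_reset()]).
#' @param action_index 1-based index into the action set's control factors.
#' @return List with `obs`, `reward`, `done`, and `info`. On termination,
#'   `info$record` is the episode record (stack id, start/final indices, step
#'   count, deviation in volts, success, accuracy, return, truncation flag).
#' @export
env_step <- function(env, action_index) {
  stopifnot(inherits(env, "af_env"))
  if (!isTRUE(env$active))
    stop_param("episode is not active; call env_reset() first")
  if (!is.numeric(action_index) || length(action_index) != 1L ||
      action_index < 1 || action_index > env$n_actions)
    stop_param("action index %s out of range 1..%d", format(action_index), env$n_actions)
  action_index <- as.integer(action_index)
  factor <- env$factors[action_index]
  focus <- env$focus[env$cur_stack]

  env$prev_idx <- env$cur_idx
  stop_correct <- FALSE
  done <- FALSE
  truncated <- FALSE

  if (factor == 0L) {
    m <- episode_metrics(env$cur_idx, focus, env$v_step, env$tolerance)
    stop_correct <- m$success
    done <- !env$done_gated || stop_correct
  } else {
    env$cur_idx <- apply_action(env$cur_idx, factor, env$n_frames)
  }
  env$n <- env$n + 1L
  env$prev_action <- action_index

  fc <- env$fc[[env$cur_stack]][env$cur_idx]
  extreme <- if (!is.null(env$reward$extra_scope) &&
                 env$reward$extra_scope == "stop_only" && factor != 0L) "neither"
             else if (env$cur_idx == focus) "sharpest"
             else if (fc <= env$least_sharp_threshold) "least_sharp"
             else "neither"
  r <- compute_reward(fc, env$n, stop_correct, extreme, env$reward)
  env$return_ <- env$return_ + r

  if (!done && env$n >= env$max_steps) {
    done <- TRUE
    truncated <- TRUE
  }
  info <- list(stack_id = env$stacks[[env$cur_stack]]$sample_id,
               stack_index = env$cur_stack, index = env$cur_idx, n = env$n)
  if (done) {
    env$active <- FALSE
    m <- episode_metrics(env$cur_idx, focus, env$v_step, env$tolerance)
    info$record <- list(
      stack_id = info$stack_id,
      start_index = env$start_idx,
      final_index = env$cur_idx,
      steps = env$n,
      deviation_volts = m$deviation_volts,
      success = m$success && !truncated,
      accurate = m$accurate && !truncated,
      episode_return = env$return_,
      truncated = truncated
    )
  }
  list(obs = .env_obs(env), reward = r, done = done, info = info)
}

#' Deviation, success and accuracy of a final lens setting
#'
#' Deviation is `|final - focus| * v_step` volts. An episode is successful
#' when the deviation is at most `tolerance` (0.2 V by default, boundary
#' inclusive) and accurate when the deviation is exactly 0 V.
#'
#' @param final_index,focus_index 1-based frame indices (>= 1).
#' @param v_step Voltage per frame (V).
#' @param tolerance Success tolerance (V).
#' @return List with `deviation_volts`, `success`, `accurate`.
#' @examples
#' episode_metrics(52, 50, 0.1) # 0.2 V -> success, not accurate
#' @export
episode_metrics <- function(final_index, focus_index, v_step, tolerance = 0.2) {
  if (final_index < 1 || focus_index < 1)
    stop_param("indices must be >= 1")
  dev <- abs(final_index - focus_index) * v_step
  list(deviation_volts = dev,
       success = dev <= tolerance + 1e-12,
       accurate = final_index == focus_index)
}
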