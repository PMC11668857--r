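# Shared fixture builders; everything is generated in code at test time.

# focal stack with an exactly controlled, strictly unimodal energy curve:
# frame i carries a single pixel step whose squared-gradient energy decreases
# strictly with |i - peak|
mk_unimodal_stack <- function(n, peak, v_start = 35, v_step = 0.1) {
  frames <- lapply(seq_len(n), function(i) {
    m <- matrix(0.5, 8, 8)
    m[1, 2] <- 0.5 + 0.4 / (1 + abs(i - peak))
    m
  })
  structure(list(frames = frames,
                 voltage_grid = v_start + (seq_len(n) - 1) * v_step,
                 focus_index = as.integer(peak),
                 texture_family = "synthetic", sample_id = sprintf("uni_%d_%d", n, peak),
                 params = list()),
            class = "focal_stack")
}

# small rendered dataset list shared by env/agent tests
mk_tiny_list <- function(n_stacks = 2, n_frames = 16, size = 8, seed = 1,
                         families = "speckle", psf_slope = 0.6) {
  build_dataset_list(n_stacks, families, n_frames = n_frames, size = size,
                     seed = seed, psf_slope = psf_slope)
}

# tiny trained agent for plumbing tests (fast, not asserted for quality)
mk_micro_agent <- function(lst, train_steps = 600) {
  env <- af_env(lst, build_action_set(2, 3, "logarithmic"),
                reward_params(orientation = "corrected", extra_scope = "stop_only"),
                max_steps = 20,
                obs_features = c("frame", "diff", "prev_action"),
                obs_encoder = "randconv")
  cfg <- agent_config(train_steps = train_steps, hidden = c(16, 8),
                      replay_capacity = 2000, learn_start = 100,
                      target_update = 200, update_every = 2, seed = 11)
  train_dqn(env, cfg)
}

# exact optimal Q for the deterministic single-stack autofocus MDP by value
# iteration over (frame index, step budget is ignored: infinite-horizon
# discounted). Used as an independent tabular reference for the DQN.
tabular_optimal_q <- function(stack, action_set, reward, gamma,
                              tolerance = 0.2, iters = 500) {
  n <- length(stack$frames)
  fc <- normalize_curve(sharpness_curve(stack, "energy"))$values
  factors <- action_set$control_factors
  v_step <- stack$voltage_grid[2] - stack$voltage_grid[1]
  Q <- matrix(0, n, length(factors))
  rew <- function(idx, n_step, stop_correct, is_stop) {
    extreme <- if (!is.null(reward$extra_scope) && reward$extra_scope == "stop_only" &&
                   !is_stop) "neither"
               else if (idx == stack$focus_index) "sharpest"
               else if (fc[idx] <= 0.05) "least_sharp"
               else "neither"
    compute_reward(fc[idx], n_step, stop_correct, extreme, reward)
  }
  # time term varies with n; use n = 2 as the representative step count the
  # way an image-only (n-blind) policy experiences it near the start
  for (it in seq_len(iters)) {
    V <- apply(Q, 1, max)
    for (a in seq_along(factors)) {
      if (factors[a] == 0) {
        for (i in seq_len(n)) {
          ok <- abs(i - stack$focus_index) * v_step <= tolerance + 1e-12
          Q[i, a] <- rew(i, 2, ok, TRUE)
        }
      } else {
        nxt <- pmin(pmax(seq_len(n) + factors[a], 1L), n)
        for (i in seq_len(n)) Q[i, a] <- rew(nxt[i], 2, FALSE, FALSE) + gamma * V[nxt[i]]
      }
    }
  }
  Q
}
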