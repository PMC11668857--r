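# Value-based deep reinforcement learning agent.
#
# The Q-network is a fully connected ReLU network over the environment's
# observation feature vector (raw pixels plus optional sequence features),
# trained by experience replay with a periodically synchronized target
# network, epsilon-greedy exploration, Huber loss and Adam. Rewards are scaled
# by `reward_scale` inside the learner for well-conditioned targets; all
# reported returns are unscaled environment returns.
#
# Replay stores transitions as compact integer references into the
# environment's precomputed frame matrices; observation batches are gathered
# at update time, so memory stays small even for pixel observations.

#' Agent hyperparameter configuration
#'
#' @param train_steps Total environment steps.
#' @param hidden Integer vector of hidden layer widths.
#' @param gamma Discount factor in `[0, 1]`; 0.9 by default — the shaped
#'   reward already carries explicit time pressure.
#' @param lr Adam learning rate.
#' @param epsilon_start,epsilon_end,epsilon_decay_steps Linear exploration
#'   schedule; `epsilon_decay_steps = NULL` decays over half of training.
#' @param replay_capacity Replay buffer size (> 0).
#' @param batch_size Minibatch size.
#' @param target_update Environment steps between target-network syncs.
#' @param update_every Environment steps per gradient update.
#' @param learn_start Steps collected before updates begin.
#' @param eval_every Steps between logged evaluation epochs (0: log every
#'   `max(250, train_steps/50)` steps without greedy evaluation).
#' @param eval_episodes Episodes per logged greedy evaluation.
#' @param reward_scale Internal scaling applied to rewards for the loss.
#' @param huber_delta Huber loss transition point (scaled units).
#' @param n_step Multi-step return horizon for the TD target (1 = one-step).
#' @param seed Integer seed; a run is fully reproducible given the seed.
#' @return Object of class `agent_config`.
#' @export
agent_config <- function(train_steps = 20000L, hidden = c(64L, 32L),
                         gamma = 0.9, lr = 1e-3,
                         epsilon_start = 1.0, epsilon_end = 0.05,
                         epsilon_decay_steps = NULL,
                         replay_capacity = 10000L, batch_size = 32L,
                         target_update = 500L, update_every = 2L,
                         learn_start = 500L,
                         eval_every = 0L, eval_episodes = 100L,
                         reward_scale = 0.01, huber_delta = 1.0,
                         n_step = 3L,
                         seed = 1L) {
  if (gamma < 0 || gamma > 1) stop_param("gamma must lie in [0,1]")
  if (epsilon_start < 0 || epsilon_start > 1 || epsilon_end < 0 || epsilon_end > 1)
    stop_param("epsilon must lie in [0,1]")
  for (nm in c("train_steps", "replay_capacity", "batch_size", "target_update",
               "update_every", "learn_start", "n_step"))
    if (get(nm) < 1) stop_param("%s must be a positive count", nm)
  if (is.null(epsilon_decay_steps)) epsilon_decay_steps <- max(1L, train_steps %/% 2L)
  structure(list(train_steps = as.integer(train_steps), hidden = as.integer(hidden),
                 gamma = gamma, lr = lr,
                 epsilon_start = epsilon_start, epsilon_end = epsilon_end,
                 epsilon_decay_steps = as.integer(epsilon_decay_steps),
                 replay_capacity = as.integer(replay_capacity),
                 batch_size = as.integer(batch_size),
                 target_update = as.integer(target_update),
                 update_every = as.integer(update_every),
                 learn_start = as.integer(learn_start),
                 eval_every = as.integer(eval_every),
                 eval_episodes = as.integer(eval_episodes),
                 reward_scale = reward_scale, huber_delta = huber_delta,
                 n_step = as.integer(n_step),
                 seed = as.integer(seed)),
            class = "agent_config")
}

# ---- Q-network primitives -------------------------------------------------

qnet_init <- function(dims) {
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(dims[l + 1] * dims[l], sd = sqrt(2 / dims[l])),
                     dims[l + 1], dims[l])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b, dims = dims,
       mW = lapply(W, function(w) w * 0), vW = lapply(W, function(w) w * 0),
       mb = lapply(b, function(x) x * 0), vb = lapply(b, function(x) x * 0),
       t = 0L)
}

# forward pass; returns Q (n_actions x B) and pre-activations for backprop
qnet_forward <- function(net, X, keep = FALSE) {
  L <- length(net$W)
  A <- X
  Zs <- if (keep) vector("list", L) else NULL
  As <- if (keep) vector("list", L) else NULL
  for (l in seq_len(L)) {
    Z <- net$W[[l]] %*% A + net$b[[l]]
    if (l < L) {
      A2 <- Z * (Z > 0)
    } else A2 <- Z
    if (keep) { Zs[[l]] <- Z; As[[l]] <- A }
    A <- A2
  }
  if (keep) list(Q = A, Zs = Zs, As = As) else A
}

# One Huber/Adam update on (X, actions, targets); returns the batch loss.
# Weight/moment matrices are updated IN PLACE by the compiled Adam kernel;
# the caller must hold the only live reference to them (the target network
# is deep-copied on sync for this reason).
qnet_update <- function(net, X, actions, targets, lr, huber_delta = 1,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  B <- ncol(X)
  fw <- qnet_forward(net, X, keep = TRUE)
  L <- length(net$W)
  q_sel <- fw$Q[cbind(actions, seq_len(B))]
  err <- q_sel - targets
  a <- abs(err)
  loss <- mean(ifelse(a <= huber_delta, 0.5 * err^2, huber_delta * (a - 0.5 * huber_delta)))
  g <- clamp(err, -huber_delta, huber_delta) / B
  dZ <- matrix(0, nrow(fw$Q), B)
  dZ[cbind(actions, seq_len(B))] <- g
  net$t <- net$t + 1L
  corr1 <- 1 - beta1^net$t
  corr2 <- 1 - beta2^net$t
  for (l in seq.int(L, 1L)) {
    dW <- tcrossprod(dZ, fw$As[[l]])
    db <- rowSums(dZ)
    if (l > 1L) {
      dA <- crossprod(net$W[[l]], dZ)
      dZ <- dA * (fw$Zs[[l - 1L]] > 0)
    }
    .adam_step(net$W[[l]], net$mW[[l]], net$vW[[l]], dW,
               lr, beta1, beta2, eps, corr1, corr2)
    .adam_step(net$b[[l]], net$mb[[l]], net$vb[[l]], db,
               lr, beta1, beta2, eps, corr1, corr2)
  }
  list(net = net, loss = loss)
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action, otherwise the argmax
#' of the Q-values (ties broken toward the lowest index). Uses R's global RNG.
#'
#' @param q_values Numeric vector of per-action scores.
#' @param epsilon Exploration probability in `[0, 1]`.
#' @return 1-based action index.
#' @export
select_action <- function(q_values, epsilon = 0) {
  if (length(q_values) == 0) stop_param("empty q_values")
  if (epsilon > 0 && stats::runif(1) < epsilon)
    sample.int(length(q_values), 1L)
  else which.max(q_values)
}

#' One-step temporal-difference target
#'
#' `r + gamma * max_next_q * (1 - done)`; `done` marks environment-terminal
#' transitions (a correct stop), not time-limit truncations, which bootstrap.
#'
#' @param r Reward(s). @param gamma Discount. @param max_next_q Max Q of the
#'   next observation. @param done Terminal flag(s) (logical or 0/1).
#' @return Numeric target(s).
#' @export
bellman_target <- function(r, gamma, max_next_q, done) {
  r + gamma * max_next_q * (1 - as.numeric(done))
}

# ---- replay buffer --------------------------------------------------------

replay_init <- function(capacity) {
  e <- new.env(parent = emptyenv())
  e$cap <- as.integer(capacity); e$size <- 0L; e$ptr <- 0L
  for (nm in c("stack_i", "idx", "prev_idx", "prev_a", "n",
               "action", "next_idx", "next_prev_idx", "next_prev_a", "next_n"))
    assign(nm, integer(capacity), envir = e)
  e$reward <- numeric(capacity)
  e$disc <- numeric(capacity)
  e$done <- logical(capacity)
  e
}

replay_push <- function(rb, tr) {
  rb$ptr <- (rb$ptr %% rb$cap) + 1L
  rb$size <- min(rb$size + 1L, rb$cap)
  i <- rb$ptr
  rb$stack_i[i] <- tr$stack_i; rb$idx[i] <- tr$idx; rb$prev_idx[i] <- tr$prev_idx
  rb$prev_a[i] <- tr$prev_a; rb$n[i] <- tr$n
  rb$action[i] <- tr$action; rb$reward[i] <- tr$reward
  rb$next_idx[i] <- tr$next_idx; rb$next_prev_idx[i] <- tr$next_prev_idx
  rb$next_prev_a[i] <- tr$next_prev_a; rb$next_n[i] <- tr$next_n
  rb$disc[i] <- tr$disc; rb$done[i] <- tr$done
  invisible(rb)
}

# aggregate the head of a pending 1-step transition list into one n-step
# transition: summed discounted reward, bootstrap state from the tail
.nstep_head <- function(pend, gamma) {
  tr <- pend[[1]]
  R <- 0
  for (i in seq_along(pend)) R <- R + gamma^(i - 1) * pend[[i]]$reward
  last <- pend[[length(pend)]]
  tr$reward <- R
  tr$next_idx <- last$next_idx; tr$next_prev_idx <- last$next_prev_idx
  tr$next_prev_a <- last$next_prev_a; tr$next_n <- last$next_n
  tr$disc <- gamma^length(pend)
  tr$done <- last$done
  tr
}

# shallow clone of an af_env sharing the precomputed frame matrices
env_clone <- function(env) {
  e2 <- new.env(parent = emptyenv())
  for (nm in ls(env, all.names = TRUE)) assign(nm, get(nm, envir = env), envir = e2)
  class(e2) <- class(env)
  e2$active <- FALSE
  e2
}

# ---- training -------------------------------------------------------------

#' Train a deep Q-learning autofocus agent
#'
#' Runs epsilon-greedy episodes on the environment (each episode drawing a
#' stack at random from the environment's state dataset list), with experience
#' replay, a target network, Huber loss and Adam. Fully reproducible given
#' `config$seed`. Aborts with a diagnostic if the loss diverges (non-finite).
#'
#' @param env An [af_env()] built on the training dataset list.
#' @param config An [agent_config()].
#' @param eval_list Optional held-out `state_dataset_list`; when supplied and
#'   `config$eval_every > 0`, each logged epoch also records greedy return,
#'   step count and success rate on both the training and held-out lists (the
#'   learning-curve surfaces of the ablation study).
#' @return Object of class `af_agent`: the trained network, configs, the
#'   environment's observation/action specification, and `log`, a data frame
#'   of per-epoch training statistics including min-max `scaled_return`.
#' @export
train_dqn <- function(env, config = agent_config(), eval_list = NULL) {
  stopifnot(inherits(env, "af_env"), inherits(config, "agent_config"))
  set.seed(config$seed)
  dims <- c(env$feat_dim, config$hidden, env$n_actions)
  net <- qnet_init(dims)
  # weights are updated in place by the compiled Adam kernel, so the target
  # network must hold deep copies, never aliases
  copy_net <- function(n) list(W = lapply(n$W, `+`, 0), b = lapply(n$b, `+`, 0),
                               dims = n$dims)
  target <- copy_net(net)
  rb <- replay_init(config$replay_capacity)

  eval_train_env <- if (config$eval_every > 0) env_clone(env) else NULL
  eval_test_env <- if (config$eval_every > 0 && !is.null(eval_list)) {
    af_env(eval_list, env$action_set, env$reward, env$max_steps, env$tolerance,
           env$obs_resolution, env$obs_features, env$done_gated,
           env$least_sharp_threshold,
           obs_encoder = env$obs_encoder,
           encoder_seed = if (is.null(env$encoder)) 777L else env$encoder$seed,
           encoder_scales = if (is.null(env$encoder)) NULL else env$encoder$scales)
  } else NULL

  log_every <- if (config$eval_every > 0) config$eval_every
               else max(250L, config$train_steps %/% 50L)
  log_rows <- list()
  ep_returns <- numeric(0); ep_steps <- numeric(0); ep_succ <- logical(0)
  last_loss <- NA_real_
  obs <- env_reset(env)
  state <- list(stack_i = env$cur_stack, idx = env$cur_idx,
                prev_idx = env$prev_idx, prev_a = env$prev_action, n = env$n)
  pend <- list() # per-episode queue for n-step return aggregation

  for (step in seq_len(config$train_steps)) {
    eps <- config$epsilon_start +
      (config$epsilon_end - config$epsilon_start) *
      min(1, (step - 1) / config$epsilon_decay_steps)
    q <- qnet_forward(net, matrix(obs$features, ncol = 1))[, 1]
    a <- select_action(q, eps)
    res <- env_step(env, a)
    tr <- list(stack_i = state$stack_i, idx = state$idx,
               prev_idx = state$prev_idx, prev_a = state$prev_a, n = state$n,
               action = a, reward = res$reward * config$reward_scale,
               next_idx = env$cur_idx, next_prev_idx = env$prev_idx,
               next_prev_a = env$prev_action, next_n = env$n,
               disc = config$gamma,
               done = res$done && !isTRUE(res$info$record$truncated))
    pend[[length(pend) + 1L]] <- tr
    if (length(pend) == config$n_step) {
      replay_push(rb, .nstep_head(pend, config$gamma))
      pend <- pend[-1L]
    }
    if (res$done) {
      while (length(pend)) {
        replay_push(rb, .nstep_head(pend, config$gamma))
        pend <- pend[-1L]
      }
    }

    if (res$done) {
      rec <- res$info$record
      ep_returns <- c(ep_returns, rec$episode_return)
      ep_steps <- c(ep_steps, rec$steps)
      ep_succ <- c(ep_succ, rec$success)
      obs <- env_reset(env)
    } else obs <- res$obs
    state <- list(stack_i = env$cur_stack, idx = env$cur_idx,
                  prev_idx = env$prev_idx, prev_a = env$prev_action, n = env$n)

    if (rb$size >= max(config$learn_start, config$batch_size) &&
        step %% config$update_every == 0L) {
      ii <- sample.int(rb$size, config$batch_size)
      B <- length(ii)
      # one fused gather for current and next observations
      XX <- env_features(env,
                         c(rb$stack_i[ii], rb$stack_i[ii]),
                         c(rb$idx[ii], rb$next_idx[ii]),
                         c(rb$prev_idx[ii], rb$next_prev_idx[ii]),
                         c(rb$prev_a[ii], rb$next_prev_a[ii]),
                         c(rb$n[ii], rb$next_n[ii]))
      X <- XX[, seq_len(B), drop = FALSE]
      Xn <- XX[, B + seq_len(B), drop = FALSE]
      # fused compiled update: double-Q target (online argmax, target value),
      # Huber backprop and in-place Adam
      net$t <- net$t + 1L
      last_loss <- .qnet_update_cpp(net$W, net$b, net$mW, net$vW, net$mb, net$vb,
                                    target$W, target$b, X, Xn,
                                    rb$action[ii], rb$reward[ii], rb$disc[ii],
                                    as.numeric(rb$done[ii]),
                                    config$lr, config$huber_delta, net$t,
                                    0.9, 0.999, 1e-8)
      if (!is.finite(last_loss))
        stop_param("training diverged: non-finite loss at step %d", step)
    }
    if (step %% config$target_update == 0L) target <- copy_net(net)

    if (step %% log_every == 0L || step == config$train_steps) {
      row <- data.frame(step = step, episodes = length(ep_returns), epsilon = eps,
                        mean_return = if (length(ep_returns)) mean(ep_returns) else NA_real_,
                        mean_steps = if (length(ep_steps)) mean(ep_steps) else NA_real_,
                        success_rate = if (length(ep_succ)) mean(ep_succ) else NA_real_,
                        loss = last_loss)
      if (!is.null(eval_train_env)) {
        ev <- .greedy_rollouts(eval_train_env, net, config$eval_episodes)
        row$eval_train_return <- ev$mean_return
        row$eval_train_steps <- ev$mean_steps
        row$eval_train_success <- ev$success_rate
        if (!is.null(eval_test_env)) {
          ev2 <- .greedy_rollouts(eval_test_env, net, config$eval_episodes)
          row$eval_test_return <- ev2$mean_return
          row$eval_test_steps <- ev2$mean_steps
          row$eval_test_success <- ev2$success_rate
        }
      }
      log_rows[[length(log_rows) + 1L]] <- row
      ep_returns <- numeric(0); ep_steps <- numeric(0); ep_succ <- logical(0)
    }
  }
  log <- do.call(rbind, log_rows)
  log$scaled_return <- .minmax_scale(log$mean_return)
  if (!is.null(log$eval_train_return))
    log$eval_train_scaled_return <- .minmax_scale(log$eval_train_return)
  if (!is.null(log$eval_test_return))
    log$eval_test_scaled_return <- .minmax_scale(log$eval_test_return)

  structure(list(net = net, config = config,
                 env_config = list(action_set = env$action_set,
                                   reward = env$reward,
                                   max_steps = env$max_steps,
                                   tolerance = env$tolerance,
                                   obs_resolution = env$obs_resolution,
                                   obs_features = env$obs_features,
                                   done_gated = env$done_gated,
                                   least_sharp_threshold = env$least_sharp_threshold,
                                   obs_encoder = env$obs_encoder,
                                   encoder_seed = if (is.null(env$encoder)) 777L
                                                  else env$encoder$seed,
                                   encoder_scales = if (is.null(env$encoder)) NULL
                                                    else env$encoder$scales),
                 feat_dim = env$feat_dim, n_actions = env$n_actions,
                 log = log),
            class = "af_agent")
}

.minmax_scale <- function(x) {
  ok <- is.finite(x)
  if (!any(ok) || diff(range(x[ok])) == 0) return(rep(NA_real_, length(x)))
  (x - min(x[ok])) / (max(x[ok]) - min(x[ok]))
}

#' @export
print.af_agent <- function(x, ...) {
  cat(sprintf("<af_agent> %s network, %d actions, trained %d steps (seed %d)\n",
              paste(x$net$dims, collapse = "-"), x$n_actions,
              x$config$train_steps, x$config$seed))
  invisible(x)
}

# greedy episodes returning summary stats (internal, reuses a cloned env)
.greedy_rollouts <- function(env, net, n_episodes) {
  recs <- vector("list", n_episodes)
  for (ep in seq_len(n_episodes)) {
    obs <- env_reset(env)
    repeat {
      q <- qnet_forward(net, matrix(obs$features, ncol = 1))[, 1]
      res <- env_step(env, which.max(q))
      if (res$done) { recs[[ep]] <- res$info$record; break }
      obs <- res$obs
    }
  }
  list(mean_return = mean(vapply(recs, `[[`, numeric(1), "episode_return")),
       mean_steps = mean(vapply(recs, `[[`, numeric(1), "steps")),
       success_rate = mean(vapply(recs, `[[`, logical(1), "success")),
       records = recs)
}

# ---- evaluation -----------------------------------------------------------

.report_from_records <- function(records) {
  dev <- vapply(records, `[[`, numeric(1), "deviation_volts")
  succ <- vapply(records, `[[`, logical(1), "success")
  acc <- vapply(records, `[[`, logical(1), "accurate")
  steps <- vapply(records, `[[`, numeric(1), "steps")
  ret <- vapply(records, `[[`, numeric(1), "episode_return")
  trunc <- vapply(records, `[[`, logical(1), "truncated")
  hist_bins <- table(sprintf("%.1f", round(dev, 1)))
  structure(list(success_rate = mean(succ), accuracy_rate = mean(acc),
                 mean_steps = mean(steps),
                 mae_volts = mean(dev), rmse_volts = sqrt(mean(dev^2)),
                 deviation_histogram = hist_bins,
                 mean_return = mean(ret),
                 non_termination_rate = mean(trunc),
                 n_episodes = length(records),
                 records = records),
            class = "af_eval_report")
}

#' @export
print.af_eval_report <- function(x, ...) {
  msg <- sprintf(paste0("<af_eval_report> %d episodes: success %.1f%%, accuracy %.1f%%, ",
                        "mean steps %.2f, MAE %.4g V, RMSE %.4g V, mean return %.1f"),
                 x$n_episodes, 100 * x$success_rate, 100 * x$accuracy_rate,
                 x$mean_steps, x$mae_volts, x$rmse_volts, x$mean_return)
  if (x$non_termination_rate > 0)
    msg <- paste0(msg, sprintf(", non-terminating %.1f%%", 100 * x$non_termination_rate))
  cat(msg, "\n", sep = "")
  invisible(x)
}

#' Evaluate a trained agent on a dataset list
#'
#' Runs `n_episodes` greedy episodes (uniform random stack and start index per
#' episode) and aggregates the outcome metrics: success and accuracy rates,
#' mean time steps, mean absolute error and root-mean-square error of the
#' final voltage in volts, the per-0.1 V deviation histogram, mean return and
#' the fraction of episodes that failed to terminate autonomously.
#'
#' @param agent An `af_agent` from [train_dqn()].
#' @param dataset_list A `state_dataset_list` to evaluate on.
#' @param n_episodes Number of episodes (>= 1); 1000 matches the standard
#'   evaluation protocol.
#' @param greedy If `FALSE`, uses the agent's final epsilon instead of pure
#'   argmax.
#' @param seed Optional seed for the episode draw.
#' @return An `af_eval_report`.
#' @export
evaluate_agent <- function(agent, dataset_list, n_episodes = 1000L,
                           greedy = TRUE, seed = NULL) {
  stopifnot(inherits(agent, "af_agent"))
  if (n_episodes < 1) stop_param("n_episodes must be >= 1")
  ec <- agent$env_config
  env <- af_env(dataset_list, ec$action_set, ec$reward, ec$max_steps,
                ec$tolerance, ec$obs_resolution, ec$obs_features,
                ec$done_gated, ec$least_sharp_threshold,
                obs_encoder = if (is.null(ec$obs_encoder)) "pixels" else ec$obs_encoder,
                encoder_seed = if (is.null(ec$encoder_seed)) 777L else ec$encoder_seed,
                encoder_scales = ec$encoder_scales)
  eps <- if (greedy) 0 else agent$config$epsilon_end
  policy <- function(env, obs) {
    q <- qnet_forward(agent$net, matrix(obs$features, ncol = 1))[, 1]
    select_action(q, eps)
  }
  evaluate_policy(env, policy, n_episodes, seed = seed)
}

#' Evaluate an arbitrary policy
#'
#' Generic episode runner for baselines and oracles. The policy is a function
#' `(env, obs) -> action index`; it may inspect the environment (e.g. the
#' oracle policy reads the ground-truth focus index).
#'
#' @param env An `af_env`.
#' @param policy Function of `(env, obs)` returning a 1-based action index.
#' @param n_episodes Number of episodes.
#' @param seed Optional seed.
#' @return An `af_eval_report`.
#' @export
evaluate_policy <- function(env, policy, n_episodes = 1000L, seed = NULL) {
  stopifnot(inherits(env, "af_env"))
  if (n_episodes < 1) stop_param("n_episodes must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  recs <- vector("list", n_episodes)
  for (ep in seq_len(n_episodes)) {
    obs <- env_reset(env)
    repeat {
      res <- env_step(env, policy(env, obs))
      if (res$done) { recs[[ep]] <- res$info$record; break }
      obs <- res$obs
    }
  }
  .report_from_records(recs)
}

#' Reference policies
#'
#' `make_oracle_policy()` returns the shortest-path reference: it jumps to the
#' ground-truth focus via breadth-first-search-minimal moves and then stops —
#' a lower bound on achievable mean steps for a given action set.
#' `always_stop_policy` stops immediately, whatever the state.
#'
#' @param env An `af_env` (the oracle precomputes one BFS table per stack).
#' @return A policy function for [evaluate_policy()].
#' @export
make_oracle_policy <- function(env) {
  stopifnot(inherits(env, "af_env"))
  moves <- env$factors
  nonstop <- which(moves != 0L)
  dist_tabs <- lapply(seq_len(env$n_stacks), function(s)
    bfs_min_moves(env$action_set, env$n_frames, env$focus[s]))
  function(env, obs) {
    target <- env$focus[env$cur_stack]
    i <- env$cur_idx
    if (i == target) return(env$stop_action)
    D <- dist_tabs[[env$cur_stack]]
    nxt <- vapply(nonstop, function(a) {
      j <- clamp(i + moves[a], 1L, env$n_frames)
      D[j]
    }, numeric(1))
    cand <- nonstop[nxt == min(nxt)]
    cand[which.min(abs(moves[cand]))]
  }
}

#' @rdname make_oracle_policy
#' @export
always_stop_policy <- function(env, obs) env$stop_action
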