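test_that("epsilon-greedy selection: argmax, low-index ties, uniform exploration", {
  expect_identical(select_action(c(1, 3, 2), epsilon = 0), 2L)
  expect_identical(select_action(c(2, 2, 1), epsilon = 0), 1L) # tie -> lowest index
  expect_error(select_action(numeric(0)), "empty")
  set.seed(123)
  draws <- replicate(10000, select_action(rep(0, 7), epsilon = 1))
  chi <- suppressWarnings(chisq.test(tabulate(draws, 7)))
  expect_gt(chi$p.value, 0.01)
})

test_that("one-step targets follow the Bellman backup", {
  expect_identical(bellman_target(5, 0.9, 10, TRUE), 5)
  expect_equal(bellman_target(1, 0.9, 2, FALSE), 2.8)
  expect_identical(bellman_target(3, 0, 99, FALSE), 3)
})

test_that("the compiled fused update matches the reference R implementation", {
  set.seed(14)
  d <- 20; B <- 8; nA <- 3
  net1 <- focusrl:::qnet_init(c(d, 10, 6, nA))
  net2 <- rapply(net1, function(x) x + 0, how = "replace")
  tW <- lapply(net1$W, `+`, 0); tb <- lapply(net1$b, `+`, 0)
  X <- matrix(rnorm(d * B), d, B); Xn <- matrix(rnorm(d * B), d, B)
  acts <- sample.int(nA, B, TRUE); rew <- rnorm(B)
  disc <- rep(0.9^3, B); done <- as.numeric(runif(B) < 0.3)
  # reference route: explicit double-Q target then the R update
  qt <- focusrl:::qnet_forward(list(W = tW, b = tb), Xn)
  qo <- focusrl:::qnet_forward(net1, Xn)
  amax <- max.col(t(qo), ties.method = "first")
  tgt <- rew + disc * qt[cbind(amax, seq_len(B))] * (1 - done)
  net1$t <- 0L
  ref <- focusrl:::qnet_update(net1, X, acts, tgt, 1e-3, 1)
  loss2 <- focusrl:::.qnet_update_cpp(net2$W, net2$b, net2$mW, net2$vW,
                                      net2$mb, net2$vb, tW, tb, X, Xn,
                                      acts, rew, disc, done,
                                      1e-3, 1, 1L, 0.9, 0.999, 1e-8)
  expect_equal(loss2, ref$loss, tolerance = 1e-12)
  for (l in seq_along(net2$W)) {
    expect_equal(net2$W[[l]], ref$net$W[[l]], tolerance = 1e-12)
    expect_equal(net2$b[[l]], ref$net$b[[l]], tolerance = 1e-12)
  }
})

test_that("training is deterministic given the seed and rejects bad configs", {
  lst <- mk_tiny_list(2, n_frames = 12, size = 8, seed = 21)
  mk <- function() {
    env <- af_env(lst, build_action_set(2, 3, "logarithmic"), max_steps = 12,
                  obs_features = c("frame", "diff", "prev_action"))
    cfg <- agent_config(train_steps = 700, hidden = c(12, 8), replay_capacity = 1000,
                        learn_start = 100, target_update = 200, seed = 5)
    train_dqn(env, cfg)
  }
  a <- mk(); b <- mk()
  expect_identical(a$log, b$log)
  expect_identical(a$net$W, b$net$W)
  expect_error(agent_config(replay_capacity = 0), "replay_capacity")
  expect_error(agent_config(gamma = 1.2), "gamma")
  expect_error(agent_config(epsilon_start = 2), "epsilon")
})

test_that("the agent solves the toy autofocus problem and approaches the tabular optimum", {
  # 16-frame stacks of 8x8 frames, three actions; small-instance convergence
  # within a 5000-step training budget
  lst <- mk_tiny_list(2, n_frames = 16, size = 8, seed = 1)
  rw <- reward_params(orientation = "corrected", extra_scope = "stop_only")
  env <- af_env(lst, build_action_set(2, 3, "logarithmic"), rw, max_steps = 30,
                obs_features = c("frame", "diff", "prev_action"),
                obs_encoder = "pixels")
  cfg <- agent_config(train_steps = 5000, hidden = c(32, 16), replay_capacity = 5000,
                      update_every = 1, learn_start = 200, target_update = 250,
                      lr = 2e-3, epsilon_end = 0.05, n_step = 3, seed = 3)
  agent <- train_dqn(env, cfg)
  rep <- evaluate_agent(agent, lst, 300, seed = 9)
  expect_gte(rep$success_rate, 0.85)
  expect_lt(rep$mean_steps, 10)

  # greedy actions at episode-start observations match an optimal action of
  # the exact dynamic-programming solution on >= 90% of states, per stack
  for (si in 1:2) {
    match_frac <- local({
      stack <- lst$stacks[[si]]
      Qdp <- tabular_optimal_q(stack, env$action_set, rw, cfg$gamma)
      hits <- 0L
      for (i in seq_len(16)) {
        feats <- focusrl:::env_features(env, si, i, i, 0L, 0L)
        qa <- focusrl:::qnet_forward(agent$net, feats)[, 1]
        best_dp <- which(Qdp[i, ] >= max(Qdp[i, ]) - 1e-9)
        hits <- hits + as.integer(which.max(qa) %in% best_dp)
      }
      hits / 16
    })
    expect_gte(match_frac, 0.9)
  }
})

test_that("reference policies bound the agent: oracle is perfect, always-stop is chance", {
  lst <- mk_tiny_list(2, n_frames = 100, size = 8, seed = 31)
  aset <- build_action_set(3, 7, "logarithmic")
  env <- af_env(lst, aset, max_steps = 50)
  oracle <- make_oracle_policy(env)
  rep_o <- evaluate_policy(env, oracle, 300, seed = 4)
  expect_identical(rep_o$success_rate, 1)
  expect_identical(rep_o$accuracy_rate, 1)
  # always-stop on 100-frame stacks with uniform starts: the success zone is
  # 5 frames out of 100
  rep_s <- evaluate_policy(env, always_stop_policy, 4000, seed = 5)
  expect_gt(rep_s$success_rate, 0.05 - 3 * sqrt(0.05 * 0.95 / 4000) - 1e-9)
  expect_lt(rep_s$success_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 4000))
  # oracle step counts equal the BFS minimum plus the final stop action
  ids <- vapply(lst$stacks, function(s) s$sample_id, character(1))
  dist_tab <- lapply(lst$stacks, function(s) bfs_min_moves(aset, 100, s$focus_index))
  for (r in rep_o$records[1:100]) {
    d <- dist_tab[[match(r$stack_id, ids)]]
    expect_identical(r$steps, d[r$start_index] + 1L)
  }
  expect_error(evaluate_policy(env, oracle, 0), "n_episodes")
})
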