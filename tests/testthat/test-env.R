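test_that("episode metrics implement the inclusive 0.2 V success threshold", {
  m <- episode_metrics(52, 50, 0.1)
  expect_equal(m$deviation_volts, 0.2)
  expect_true(m$success)
  expect_false(m$accurate)
  m0 <- episode_metrics(50, 50, 0.1)
  expect_identical(c(m0$deviation_volts, m0$success, m0$accurate), c(0, 1, 1))
  m7 <- episode_metrics(57, 50, 0.1)
  expect_equal(m7$deviation_volts, 0.7)
  expect_false(m7$success)
  expect_error(episode_metrics(-1, 50, 0.1), ">= 1")
})

test_that("reset samples stacks uniformly and is reproducible", {
  lst <- mk_tiny_list(10, n_frames = 8, size = 8, seed = 2)
  env <- af_env(lst, build_action_set(2, 3, "logarithmic"))
  set.seed(99)
  picks <- replicate(10000, { env_reset(env); env$cur_stack })
  counts <- tabulate(picks, 10)
  # each stack's frequency within 3 sd of uniform
  expect_true(all(abs(counts - 1000) <= 3 * sqrt(10000 * 0.1 * 0.9)))
  set.seed(7); env_reset(env); a <- c(env$cur_stack, env$cur_idx)
  set.seed(7); env_reset(env); b <- c(env$cur_stack, env$cur_idx)
  expect_identical(a, b)
  empty <- structure(list(stacks = list(), family_counts = table(character(0))),
                     class = "state_dataset_list")
  expect_error(af_env(empty, build_action_set(2, 3)), "non-empty")
})

test_that("stepping follows the stop/move/truncation contract", {
  lst <- mk_tiny_list(1, n_frames = 16, size = 8, seed = 3)
  focus <- lst$stacks[[1]]$focus_index
  aset <- build_action_set(2, 3, "logarithmic") # (-1, 0, 1)
  env <- af_env(lst, aset, max_steps = 5)
  # stop exactly at focus: done, success, accurate
  set.seed(1); env_reset(env)
  env$cur_idx <- focus; env$prev_idx <- focus
  res <- env_step(env, which(env$factors == 0L))
  expect_true(res$done)
  expect_true(res$info$record$success)
  expect_true(res$info$record$accurate)
  # stop at 0.3 V deviation: done but unsuccessful
  set.seed(1); env_reset(env)
  env$cur_idx <- focus + 3L; env$prev_idx <- env$cur_idx
  res <- env_step(env, which(env$factors == 0L))
  expect_true(res$done)
  expect_false(res$info$record$success)
  expect_equal(res$info$record$deviation_volts, 0.3)
  # truncation at max_steps without stop
  set.seed(2); env_reset(env)
  for (k in 1:4) {
    res <- env_step(env, which(env$factors == 1L))
    expect_false(res$done)
  }
  res <- env_step(env, which(env$factors == 1L))
  expect_true(res$done)
  expect_true(res$info$record$truncated)
  expect_error(env_step(env, 1), "not active")
  set.seed(2); env_reset(env)
  expect_error(env_step(env, 9), "out of range")
})

test_that("episode return equals the sum of per-step rewards and accurate implies success", {
  lst <- mk_tiny_list(3, n_frames = 12, size = 8, seed = 4)
  env <- af_env(lst, build_action_set(2, 5, "logarithmic"), max_steps = 15)
  set.seed(11)
  for (ep in 1:30) {
    env_reset(env)
    total <- 0
    repeat {
      res <- env_step(env, sample.int(env$n_actions, 1))
      total <- total + res$reward
      if (res$done) break
    }
    rec <- res$info$record
    expect_equal(rec$episode_return, total)
    if (rec$accurate) expect_true(rec$success)
    expect_lte(rec$steps, 15)
    expect_gte(rec$deviation_volts, 0)
  }
})

test_that("done-gated termination turns an incorrect stop into a counted no-op", {
  lst <- mk_tiny_list(1, n_frames = 16, size = 8, seed = 5)
  focus <- lst$stacks[[1]]$focus_index
  env <- af_env(lst, build_action_set(2, 3, "logarithmic"), max_steps = 10,
                done_gated_termination = TRUE)
  set.seed(1); env_reset(env)
  env$cur_idx <- if (focus > 8) 1L else 16L # far from focus
  env$prev_idx <- env$cur_idx
  res <- env_step(env, which(env$factors == 0L))
  expect_false(res$done) # incorrect stop does not terminate
  expect_identical(env$n, 1L)
  env$cur_idx <- focus; env$prev_idx <- focus
  res <- env_step(env, which(env$factors == 0L))
  expect_true(res$done) # correct stop does
  expect_true(res$info$record$success)
})

test_that("observation features expose frame, difference and previous action as configured", {
  lst <- mk_tiny_list(1, n_frames = 10, size = 8, seed = 6)
  env <- af_env(lst, build_action_set(2, 3, "logarithmic"),
                obs_features = c("frame", "diff", "prev_action", "step"))
  d <- 64
  expect_identical(env$feat_dim, as.integer(d + d + 3 + 1))
  set.seed(3); obs <- env_reset(env)
  expect_identical(obs$n, 0L)
  expect_equal(obs$features[(d + 1):(2 * d)], rep(0, d)) # no previous frame yet
  expect_equal(obs$features[(2 * d + 1):(2 * d + 3)], rep(0, 3))
  res <- env_step(env, 3L) # move +1
  expect_equal(res$obs$features[2 * d + 3], 1) # one-hot of the action taken
  expect_equal(res$obs$features[2 * d + 4], 1 / env$max_steps)
  expect_equal(res$obs$features[(d + 1):(2 * d)],
               res$obs$features[1:d] -
                 (env$Pall[, env$poff[1] + env$prev_idx]))
  expect_error(af_env(lst, build_action_set(2, 3), obs_features = "pixels2"),
               "unknown obs_features")
})
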