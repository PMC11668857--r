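test_that("reports round-trip through CSV and JSON losslessly", {
  rep <- data.frame(variant = 1:3, success_rate = c(0, 0.54, 0.83),
                    mean_steps = c(50, 3.55, 3.15), mae_volts = c(10.94, 13.06, 1.43),
                    config_hash = c("ab", "cd", "ef"), seed = 1L)
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_report(rep, path, fmt)
    back <- import_report(path, fmt)
    expect_equal(back$success_rate, rep$success_rate)
    expect_equal(back$mean_steps, rep$mean_steps)
    expect_equal(back$mae_volts, rep$mae_volts)
    expect_identical(nrow(back), 3L)
  }
  expect_error(export_report(rep, tempfile(), "xml"), "unknown report format")
})

test_that("experiment runners validate their configuration", {
  lst <- mk_tiny_list(1, n_frames = 10, size = 8)
  expect_error(run_action_space_study(sizes = integer(0), train_list = lst,
                                      test_list = lst), "empty configuration")
  expect_error(run_ablation(variants = 7, train_list = lst, test_list = lst),
               "variants")
  expect_error(run_generalization(unseen_family = "speckle",
                                  single_family = "speckle",
                                  pair_families = c("regular_grid", "bar_target")),
               "overlaps")
  expect_error(run_sampling_study(list_sizes = 0), "positive")
})

test_that("baseline comparison reports per-stack probe counts with a stated convention", {
  lst <- mk_tiny_list(2, n_frames = 20, size = 8, seed = 41)
  agent <- mk_micro_agent(lst)
  tab <- run_baseline_comparison(lst, agent, episodes_per_stack = 20, seed = 3)
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$sweep_probes == 20))
  expect_true(all(tab$golden_probes <= 20 & tab$fibonacci_probes <= 20))
  expect_true(all(tab$agent_mean_steps < tab$sweep_probes))
  expect_match(attr(tab, "convention"), "probes")
  expect_match(attr(tab, "convention"), "stop")
})

test_that("run configs validate blocks and name offending fields", {
  good <- list(seed = 3,
               action_space = list(b = 5, n_A = 7, method = "logarithmic"),
               reward = list(alpha = 100, beta = 30),
               agent = list(train_steps = 100, gamma = 0.9))
  expect_identical(validate_run_config(good)$seed, 3)
  bad_block <- c(good, list(rewards = list()))
  expect_error(validate_run_config(bad_block), "unknown config block")
  bad_field <- good
  bad_field$reward$alpha_decay <- 2
  expect_error(validate_run_config(bad_field), "alpha_decay")
  bad_value <- good
  bad_value$agent$gamma <- 3
  expect_error(validate_run_config(bad_value), "gamma")
})

test_that("identical configuration and seed regenerate identical study rows", {
  lst <- mk_tiny_list(2, n_frames = 12, size = 8, seed = 51)
  tst <- mk_tiny_list(2, n_frames = 12, size = 8, seed = 52)
  cfg <- agent_config(train_steps = 300, hidden = c(8, 8), replay_capacity = 500,
                      learn_start = 50, target_update = 100, seed = 1)
  run <- function() {
    run_action_space_study(sizes = 3, bases = 2, methods = "logarithmic",
                           train_list = lst, test_list = tst, seeds = 1L,
                           config = cfg, eval_episodes = 20,
                           env_options = list(max_steps = 12))
  }
  a <- run(); b <- run()
  expect_identical(a, b)
  expect_true(all(c("config_hash", "seed", "action_set") %in% names(a)))
  expect_gte(a$train_success_rate, a$train_accuracy_rate) # definitional
  expect_gte(a$train_rmse_volts, a$train_mae_volts)       # Jensen
  expect_gte(a$test_rmse_volts, a$test_mae_volts)
})

test_that("the sampling study reports one row per list size with valid rates", {
  cfg <- agent_config(train_steps = 300, hidden = c(8, 8), replay_capacity = 500,
                      learn_start = 50, target_update = 100, seed = 1)
  tab <- run_sampling_study(list_sizes = c(1, 2), families = "speckle", seeds = 1L,
                            n_frames = 12, size = 8, data_seed = 3,
                            config = cfg, eval_episodes = 20,
                            env_options = list(max_steps = 12))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$list_size, c(1, 2))
  rates <- c(tab$train_success_rate, tab$test_success_rate,
             tab$train_accuracy_rate, tab$test_accuracy_rate)
  expect_true(all(rates >= 0 & rates <= 1))
  expect_true(all(tab$test_rmse_volts >= tab$test_mae_volts))
})
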