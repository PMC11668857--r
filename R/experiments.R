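# Scripted studies: action-space size/construction, state-list size,
# reward ablation, cross-sample generalization, and the classical-search
# baseline comparison. Each runner returns a plain data frame, one row per
# condition x seed, stamped with a config hash for regeneration.

.stamp <- function(df, cfg, seed) {
  df$config_hash <- config_hash(cfg)
  df$seed <- seed
  df
}

.eval_cols <- function(report, prefix) {
  out <- data.frame(x = report$success_rate, y = report$accuracy_rate,
                    z = report$mean_steps, m = report$mae_volts,
                    r = report$rmse_volts, g = report$mean_return,
                    n = report$non_termination_rate)
  names(out) <- paste0(prefix, c("success_rate", "accuracy_rate", "mean_steps",
                                 "mae_volts", "rmse_volts", "mean_return",
                                 "non_termination_rate"))
  out
}

#' Action-space study
#'
#' Trains one agent per combination of action-space size, base and
#' construction method and evaluates it greedily on the training and held-out
#' lists. Reproduces the qualitative findings that larger action spaces focus
#' more accurately and in fewer steps.
#'
#' @param sizes Odd action-space sizes, e.g. `c(3, 5, 7)`.
#' @param bases Integer bases (>= 2).
#' @param methods Construction methods.
#' @param train_list,test_list State dataset lists (disjoint).
#' @param seeds Integer vector of training seeds.
#' @param config Base [agent_config()]; the seed field is overridden per run.
#' @param reward Reward parameters for training; the default grants the
#'   extreme-image bonus on the stop step only (see [reward_params()]).
#' @param env_options Named list forwarded to [af_env()] (e.g. obs_features).
#' @param eval_episodes Greedy evaluation episodes per list.
#' @return Data frame, one row per (size, base, method, seed).
#' @export
run_action_space_study <- function(sizes = c(3, 5, 7), bases = 5,
                                   methods = "logarithmic",
                                   train_list, test_list, seeds = 1L,
                                   config = agent_config(),
                                   reward = reward_params(extra_scope = "stop_only"),
                                   env_options = list(),
                                   eval_episodes = 300L) {
  grid <- expand.grid(size = sizes, base = bases, method = methods,
                      seed = seeds, stringsAsFactors = FALSE)
  if (nrow(grid) == 0) stop_param("empty configuration grid")
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    aset <- build_action_set(g$base, g$size, g$method)
    cfg <- config; cfg$seed <- fan_seed(g$seed, k)
    env <- do.call(af_env, c(list(dataset_list = train_list, action_set = aset,
                                  reward = reward),
                             env_options))
    agent <- train_dqn(env, cfg)
    tr <- evaluate_agent(agent, train_list, eval_episodes, seed = fan_seed(g$seed, 1000L + k))
    te <- evaluate_agent(agent, test_list, eval_episodes, seed = fan_seed(g$seed, 2000L + k))
    row <- data.frame(size = g$size, base = g$base, method = g$method,
                      action_set = format(aset))
    row <- cbind(row, .eval_cols(tr, "train_"), .eval_cols(te, "test_"))
    .stamp(row, list(g = g, config = cfg, env = env_options), g$seed)
  })
  do.call(rbind, rows)
}

#' State-list size (random sampling) study
#'
#' Trains agents on state dataset lists of increasing size (default 1, 5, 10,
#' 50) and evaluates on held-out lists of matching size, reproducing the
#' finding that random sampling over more state datasets improves success,
#' accuracy and generalization.
#'
#' @param list_sizes Training list sizes.
#' @param families Texture families for the generated stacks.
#' @param seeds Training seeds.
#' @param action_set Action set (default: logarithmic, base 5, 7 actions).
#' @param n_frames,size,data_seed Stack geometry and generation seed.
#' @inheritParams run_action_space_study
#' @return Data frame, one row per (list_size, seed).
#' @export
run_sampling_study <- function(list_sizes = c(1, 5, 10, 50),
                               families = texture_families(),
                               seeds = 1L,
                               action_set = build_action_set(5, 7, "logarithmic"),
                               n_frames = 100L, size = 64L, data_seed = 99L,
                               config = agent_config(),
                               reward = reward_params(extra_scope = "stop_only"),
                               env_options = list(),
                               eval_episodes = 300L) {
  if (any(list_sizes < 1)) stop_param("list sizes must be positive")
  grid <- expand.grid(list_size = list_sizes, seed = seeds)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    train_list <- build_dataset_list(g$list_size, families, n_frames, size,
                                     seed = fan_seed(data_seed, 2L * k))
    test_list <- build_dataset_list(g$list_size, families, n_frames, size,
                                    seed = fan_seed(data_seed, 2L * k + 1L))
    cfg <- config; cfg$seed <- fan_seed(g$seed, k)
    env <- do.call(af_env, c(list(dataset_list = train_list, action_set = action_set,
                                  reward = reward),
                             env_options))
    agent <- train_dqn(env, cfg)
    tr <- evaluate_agent(agent, train_list, eval_episodes, seed = fan_seed(g$seed, 1000L + k))
    te <- evaluate_agent(agent, test_list, eval_episodes, seed = fan_seed(g$seed, 2000L + k))
    row <- data.frame(list_size = g$list_size)
    row <- cbind(row, .eval_cols(tr, "train_"), .eval_cols(te, "test_"))
    .stamp(row, list(g = g, config = cfg, env = env_options), g$seed)
  })
  do.call(rbind, rows)
}

#' Reward-function ablation study
#'
#' Trains agents under the five reward variants (see [variant_gates()]) and
#' evaluates them greedily, reporting mean return (raw and min-max scaled),
#' MAE, mean time steps, the non-termination fraction, accuracy and success.
#' Episodes that hit the step limit without an autonomous stop are reported
#' through `non_termination_rate` and enter `mean_steps` at the truncation
#' limit.
#'
#' The ablation environment ends an episode only on a correct stop
#' (`done_gated_termination = TRUE`) and uses the literal printed sharpness
#' orientation; under a stop-anywhere contract a sharpness-only reward makes
#' immediate stopping optimal and the variant comparison degenerates (see the
#' methods vignette).
#'
#' @param variants Subset of 1..5.
#' @param seeds Training seeds (3 by default, matching the study protocol).
#' @param train_list,test_list State dataset lists.
#' @param action_set Default: logarithmic, base 5, 7 actions.
#' @param orientation Sharpness-term orientation for the ablation.
#' @param extra_scope Scope of the extreme-image bonus (see [reward_params()]);
#'   granted on the stop step by default so the sharpness+extra variant is not
#'   pushed into stopping by the least-sharp penalty on its loiter region.
#' @inheritParams run_action_space_study
#' @return Data frame, one row per (variant, seed); per-epoch learning curves
#'   for each run are attached as the `"curves"` attribute.
#' @export
run_ablation <- function(variants = 1:5, seeds = 1:3,
                         train_list, test_list,
                         action_set = build_action_set(5, 7, "logarithmic"),
                         config = agent_config(),
                         env_options = list(),
                         orientation = "literal",
                         extra_scope = "stop_only",
                         eval_episodes = 300L) {
  if (!all(variants %in% 1:5)) stop_param("variants must lie in 1..5")
  grid <- expand.grid(variant = variants, seed = seeds)
  curves <- list()
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    rw <- do.call(reward_params, c(variant_gates(g$variant),
                                   list(orientation = orientation,
                                        extra_scope = extra_scope)))
    cfg <- config; cfg$seed <- fan_seed(g$seed, 7000L + k)
    env <- do.call(af_env, c(list(dataset_list = train_list, action_set = action_set,
                                  reward = rw, done_gated_termination = TRUE),
                             env_options))
    agent <- train_dqn(env, cfg, eval_list = test_list)
    tr <- evaluate_agent(agent, train_list, eval_episodes, seed = fan_seed(g$seed, 2500L + k))
    te <- evaluate_agent(agent, test_list, eval_episodes, seed = fan_seed(g$seed, 3000L + k))
    curves[[sprintf("variant%d_seed%d", g$variant, g$seed)]] <<- agent$log
    row <- data.frame(variant = g$variant,
                      mean_return = te$mean_return,
                      mae_volts = te$mae_volts,
                      mean_steps = te$mean_steps,
                      non_termination_rate = te$non_termination_rate,
                      accuracy_rate = te$accuracy_rate,
                      success_rate = te$success_rate,
                      train_mean_steps = tr$mean_steps,
                      train_non_termination_rate = tr$non_termination_rate,
                      train_success_rate = tr$success_rate)
    .stamp(row, list(g = g, config = cfg, orientation = orientation), g$seed)
  })
  out <- do.call(rbind, rows)
  out$scaled_return <- .minmax_scale(out$mean_return)
  attr(out, "curves") <- curves
  out
}

#' Cross-sample generalization study
#'
#' Compares random-sampling training on a single texture family against
#' training on two families (half of the list each), evaluating both on a
#' third, completely unfamiliar family.
#'
#' @param list_size Total training list size (the two-family method uses half
#'   per family).
#' @param single_family Family for the one-family method.
#' @param pair_families Two families for the mixed method.
#' @param unseen_family Held-out family; must not occur in either training
#'   configuration.
#' @param seeds Training seeds.
#' @param n_frames,size,data_seed Stack geometry and generation seed.
#' @inheritParams run_action_space_study
#' @return Data frame, one row per (method, seed) with success on the unseen
#'   family.
#' @export
run_generalization <- function(list_size = 10L,
                               single_family = "bar_target",
                               pair_families = c("regular_grid", "bar_target"),
                               unseen_family = "speckle",
                               seeds = 1:3,
                               action_set = build_action_set(3, 7, "logarithmic"),
                               n_frames = 100L, size = 64L, data_seed = 7L,
                               config = agent_config(),
                               reward = reward_params(extra_scope = "stop_only"),
                               env_options = list(),
                               eval_episodes = 300L) {
  if (unseen_family %in% c(single_family, pair_families))
    stop_param("unseen_family '%s' overlaps a training family", unseen_family)
  if (length(pair_families) != 2L) stop_param("pair_families must name two families")
  unseen_list <- build_dataset_list(list_size, unseen_family, n_frames, size,
                                    seed = fan_seed(data_seed, 1L))
  methods <- list(single_family = single_family, two_families = pair_families)
  rows <- list()
  for (s in seeds) {
    for (mname in names(methods)) {
      train_list <- build_dataset_list(list_size, methods[[mname]], n_frames, size,
                                       seed = fan_seed(data_seed, 100L + s))
      cfg <- config; cfg$seed <- fan_seed(s, match(mname, names(methods)))
      env <- do.call(af_env, c(list(dataset_list = train_list, action_set = action_set,
                                    reward = reward),
                               env_options))
      agent <- train_dqn(env, cfg)
      ev <- evaluate_agent(agent, unseen_list, eval_episodes,
                           seed = fan_seed(s, 4000L + match(mname, names(methods))))
      row <- data.frame(method = mname, list_size = list_size,
                        families = paste(methods[[mname]], collapse = "+"),
                        unseen_family = unseen_family)
      row <- cbind(row, .eval_cols(ev, "unseen_"))
      rows[[length(rows) + 1L]] <- .stamp(row, list(m = mname, config = cfg), s)
    }
  }
  do.call(rbind, rows)
}

#' Baseline comparison: trained agent vs classical searches
#'
#' For each stack, runs the sweep, golden-section and Fibonacci searches and
#' evaluates the agent on that stack alone, reporting mean time steps per
#' method. Counting convention (stated in the `"convention"` attribute):
#' search "steps" are probes, i.e. distinct sharpness evaluations / image
#' captures; agent steps count actions taken including the final stop.
#'
#' @param stacks List of `focal_stack` objects (or a `state_dataset_list`).
#' @param agent A trained `af_agent`.
#' @param measure Focus measure for the searches.
#' @param tol_indices Search stopping tolerance in frames.
#' @param episodes_per_stack Agent evaluation episodes per stack.
#' @param seed Evaluation seed.
#' @return Data frame, one row per stack.
#' @export
run_baseline_comparison <- function(stacks, agent, measure = "energy",
                                    tol_indices = 2L, episodes_per_stack = 50L,
                                    seed = 1L) {
  stopifnot(inherits(agent, "af_agent"))
  if (inherits(stacks, "state_dataset_list")) stacks <- stacks$stacks
  rows <- lapply(seq_along(stacks), function(i) {
    st <- stacks[[i]]
    gold <- golden_section_search(st, measure, tol_indices)
    fib <- fibonacci_search(st, measure, tol_indices)
    swp <- sweep_search(st, measure)
    single <- structure(list(stacks = list(st),
                             family_counts = table(st$texture_family)),
                        class = "state_dataset_list")
    ev <- evaluate_agent(agent, single, episodes_per_stack,
                         seed = fan_seed(seed, i))
    data.frame(sample_id = st$sample_id, family = st$texture_family,
               sweep_probes = swp$probes,
               golden_probes = gold$probes, golden_best = gold$best_index,
               fibonacci_probes = fib$probes, fibonacci_best = fib$best_index,
               agent_mean_steps = ev$mean_steps,
               agent_success_rate = ev$success_rate,
               focus_index = st$focus_index)
  })
  out <- do.call(rbind, rows)
  attr(out, "convention") <-
    paste("search steps = probes (distinct sharpness evaluations / image",
          "captures); agent steps = actions taken including the final stop")
  out
}

#' Export / import an experiment report
#'
#' Lossless round-trip of the numeric report fields to CSV or JSON.
#'
#' @param report Data frame as produced by the `run_*` functions.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `export_report` returns `path` invisibly; `import_report` the data
#'   frame.
#' @export
export_report <- function(report, path, format = c("csv", "json")) {
  if (length(format) != 1L || !format %in% c("csv", "json"))
    stop_param("unknown report format: %s", paste(format, collapse = ","))
  if (format == "csv") {
    utils::write.csv(report, path, row.names = FALSE)
  } else {
    jsonlite::write_json(report, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname export_report
#' @export
import_report <- function(path, format = c("csv", "json")) {
  if (length(format) != 1L || !format %in% c("csv", "json"))
    stop_param("unknown report format: %s", paste(format, collapse = ","))
  if (format == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
  else as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
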