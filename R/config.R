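# Structured run configuration for scripted/CLI use.

#' Validate a structured run configuration
#'
#' A run configuration is a nested named list with optional blocks
#' `simulation`, `action_space`, `reward`, `agent`, `environment`,
#' `experiment`, `output` and a top-level integer `seed`. Each block is
#' validated against the corresponding module constructor; errors name the
#' offending field. Unknown fields inside a block are rejected, so typos fail
#' loudly rather than being silently ignored.
#'
#' @param config Named list (e.g. parsed from YAML or JSON).
#' @return The validated config, with defaults filled in, invisibly usable by
#'   the CLI runner.
#' @export
validate_run_config <- function(config) {
  if (!is.list(config)) stop_param("config must be a named list")
  known_blocks <- c("simulation", "action_space", "reward", "agent",
                    "environment", "experiment", "output", "seed")
  extra <- setdiff(names(config), known_blocks)
  if (length(extra))
    stop_param("unknown config block(s): %s", paste(extra, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.numeric(config$seed)) stop_param("field 'seed' must be an integer")

  check_block <- function(block, allowed, fn = NULL) {
    b <- config[[block]]
    if (is.null(b)) return(invisible(NULL))
    bad <- setdiff(names(b), allowed)
    if (length(bad))
      stop_param("config block '%s': unknown field(s) %s", block,
                 paste(bad, collapse = ", "))
    if (!is.null(fn)) do.call(fn, b) # constructor performs value validation
    invisible(NULL)
  }
  check_block("action_space", c("b", "n_A", "method", "v_step"), build_action_set)
  check_block("reward", c("alpha", "beta", "mu", "delta", "sharpness_on",
                          "time_on", "stop_on", "extra_on", "orientation"),
              reward_params)
  check_block("agent", c("train_steps", "hidden", "gamma", "lr", "epsilon_start",
                         "epsilon_end", "epsilon_decay_steps", "replay_capacity",
                         "batch_size", "target_update", "update_every",
                         "learn_start", "eval_every", "eval_episodes",
                         "reward_scale", "huber_delta", "seed"), agent_config)
  check_block("simulation", c("n_stacks", "families", "n_frames", "size",
                              "contrast", "v_start", "v_step", "psf_sigma0",
                              "psf_slope", "noise_sd", "augment", "seed"))
  check_block("environment", c("max_steps", "tolerance_volts", "obs_resolution",
                               "obs_features", "done_gated_termination",
                               "least_sharp_threshold", "measure"))
  check_block("experiment", c("name", "sizes", "bases", "methods", "list_sizes",
                              "variants", "seeds", "eval_episodes",
                              "tol_indices"))
  check_block("output", c("dir", "format"))
  config
}
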