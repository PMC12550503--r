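# Shared fixtures, computed lazily and cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small fast profile set: five variables spanning dense and sparse sampling
small_profiles <- function() {
  p <- variable_profiles()
  p[p$variable %in% c("HR", "MAP", "LAC", "PH", "WBC"), ]
}

small_cohort <- function() {
  cached("small_cohort", {
    simulate_cohort(cohort_spec(n_episodes = 40, seed = 11,
                                profiles = small_profiles()))
  })
}

small_windows <- function() {
  cached("small_windows", fit_windows(small_cohort()))
}

small_mgp <- function() {
  cached("small_mgp", {
    cfg <- mgp_config(task_rank = 3)
    hyper <- mgp_hyperparameters(small_cohort(), small_windows(), cfg,
                                 seed = 2)
    list(cfg = cfg, hyper = hyper)
  })
}

small_grids <- function() {
  cached("small_grids", {
    m <- small_mgp()
    impute_cohort(small_cohort(), small_windows(), m$cfg, hyper = m$hyper)
  })
}

# cheap boosting settings for structural tests
fast_boost <- function(seed = 1) {
  boost_config(learning_rates = 0.1, max_depths = 3, n_rounds_max = 40,
               cv_folds = 3, seed = seed)
}

# a hand-built single-variable cohort: observations given explicitly
manual_cohort <- function(obs_times, obs_values, variable = "HR",
                          anchor = NULL, label = "control",
                          onset = NULL) {
  anchor <- anchor %||% max(obs_times)
  episodes <- tibble::tibble(
    episode_id = "e1", age_years = 2, sex = "male", weight_kg = 12,
    label = label,
    onset_time_h = if (label == "septic") onset else NA_real_,
    anchor_time_h = if (label == "control") anchor else NA_real_)
  obs <- tibble::tibble(episode_id = "e1", time_h = obs_times,
                        variable = variable, value = obs_values)
  sepsis_cohort(episodes, obs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
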