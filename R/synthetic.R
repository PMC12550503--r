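#' Default per-variable simulation profiles
#'
#' One row per panel variable, describing how the synthetic generator
#' samples it:
#' * `baseline`, `sd` — population mean and total spread in variable units;
#' * `interval_q70_h` — targeted 70% quantile of the inter-measurement
#'   interval distribution (log-normal with `interval_sdlog`); vitals are
#'   sampled every few hours, sparse labs every day or slower, mirroring
#'   the sampling-frequency spread of real paediatric EHRs;
#' * `re_sd`, `ou_sd`, `ou_length_h`, `noise_sd` — decomposition of `sd`
#'   into a stable between-episode effect, a smooth Ornstein-Uhlenbeck
#'   within-episode process (length scale tied to the sampling window) and
#'   white measurement noise — this is what gives successive windows their
#'   decaying correlation;
#' * `drift_slope` — units/hour of the linear pre-onset deterioration ramp
#'   in septic episodes (lactate, heart rate and creatinine rise; blood
#'   pressures, pH and GCS fall);
#' * `missing_rate` — probability that an episode records the variable not
#'   at all.
#'
#' @return A tibble with the columns above.
#' @export
variable_profiles <- function() {
  p <- tibble::tribble(
    ~variable, ~baseline, ~sd,  ~interval_q70_h, ~drift_slope, ~missing_rate,
    "T",       37.0,  0.5,   5,    0.15,  0.00,
    "R",       25,    5,     4,    2.0,   0.00,
    "HR",      110,   15,    4,    6.0,   0.00,
    "MAP",     65,    8,     10,  -2.0,   0.05,
    "DBP",     55,    8,     10,  -2.0,   0.05,
    "SBP",     95,    10,    9,   -3.0,   0.05,
    "INR",     1.1,   0.15,  24,   0.02,  0.10,
    "WBC",     9,     3,     26,   1.5,   0.02,
    "TB",      10,    4,     22,   0.5,   0.10,
    "Cr",      35,    10,    32,   5.0,   0.05,
    "LAC",     1.2,   0.4,   14,   0.5,   0.08,
    "PLT",     250,   60,    28,  -5.0,   0.02,
    "CRP",     10,    8,     3,    3.0,   0.05,
    "SO2",     98,    1.5,   14,  -0.4,   0.02,
    "ALB",     40,    4,     24,  -0.5,   0.10,
    "HCT",     36,    4,     4,   -0.2,   0.02,
    "PCO2",    40,    5,     22,   0.5,   0.10,
    "ALP",     180,   50,    21,   0,     0.10,
    "HGB",     115,   12,    3,   -0.5,   0.02,
    "K",       4.2,   0.4,   15,   0.04,  0.05,
    "BSD",     -2,    2,     22,  -0.5,   0.10,
    "AC",      1.2,   0.2,   20,   0.02,  0.10,
    "GCS",     14,    1,     19,  -0.5,   0.05,
    "DBIL",    4,     2,     22,   0.2,   0.10,
    "FIB",     3,     0.6,   24,   0.1,   0.10,
    "AST",     35,    12,    27,   3.0,   0.10,
    "PH",      7.38,  0.04,  10.3, -0.015, 0.08,
    "BG",      6,     1.5,   12,   0.3,   0.05
  )
  p$interval_sdlog <- 0.6
  p$re_sd <- 0.6 * p$sd
  p$ou_sd <- 0.5 * p$sd
  p$ou_length_h <- 2 * p$interval_q70_h
  p$noise_sd <- 0.35 * p$sd
  p
}

#' Specify a synthetic cohort
#'
#' @param n_episodes Number of episodes (> 0).
#' @param prevalence Septic fraction; the septic count is
#'   `floor(n_episodes * prevalence)` exactly, assigned by permutation
#'   (default 0.262).
#' @param seed Integer seed; the cohort is fully deterministic given it.
#' @param profiles Per-variable profile tibble ([variable_profiles()]).
#' @param drift_duration_h Hours before onset over which septic episodes
#'   ramp linearly towards deterioration (default 6).
#' @param drift_scale Multiplier on all drift slopes (0 switches the
#'   deterioration signature off; default 1).
#' @param onset_range_h Septic onset drawn uniformly in this window after
#'   admission; controls draw their anchor from the same window so a full
#'   trailing history always exists (default `c(18, 60)`).
#' @param horizon_h Maximum forecast horizon the cohort must support
#'   (default 12).
#' @param panel A `sw_panel`.
#' @param intervention_probs Named list of probabilities for onset-locked
#'   therapy events in septic episodes plus the background antibiotic rate
#'   in controls.
#' @return A list of class `sw_cohort_spec`.
#' @export
cohort_spec <- function(n_episodes, prevalence = 0.262, seed = 1,
                        profiles = variable_profiles(),
                        drift_duration_h = 6, drift_scale = 1,
                        onset_range_h = c(18, 60), horizon_h = 12,
                        panel = default_panel(),
                        intervention_probs = list(
                          antibiotics = 0.9, vasopressors = 0.4,
                          glucocorticoids = 0.3,
                          mechanical_ventilation = 0.25,
                          control_antibiotics = 0.3)) {
  if (n_episodes <= 0) stop("n_episodes must be positive", call. = FALSE)
  if (prevalence < 0 || prevalence > 1) {
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  }
  if (any(profiles$noise_sd <= 0) || any(profiles$sd <= 0)) {
    stop("all noise standard deviations must be positive", call. = FALSE)
  }
  stopifnot(all(profiles$variable %in% panel$variable))
  structure(list(n_episodes = as.integer(n_episodes), prevalence = prevalence,
                 seed = as.integer(seed), profiles = profiles,
                 drift_duration_h = drift_duration_h,
                 drift_scale = drift_scale,
                 onset_range_h = onset_range_h, horizon_h = horizon_h,
                 panel = panel, intervention_probs = intervention_probs),
            class = "sw_cohort_spec")
}

# lognormal meanlog such that the q-quantile equals `target`
.interval_meanlog <- function(target, sdlog, q = 0.70) {
  log(target) - stats::qnorm(q) * sdlog
}

#' Simulate a single episode
#'
#' Observation times per variable are drawn from a log-normal
#' inter-measurement interval distribution; values follow
#' baseline + episode effect + Ornstein-Uhlenbeck trajectory + noise,
#' clipped to the panel's plausible range. Septic episodes add a linear
#' deterioration ramp over the final `drift_duration_h` hours before onset.
#'
#' @param spec A `sw_cohort_spec`.
#' @param episode_id Episode identifier string.
#' @param septic Logical.
#' @param reference_time_h Onset (septic) or anchor (control) time in hours
#'   after admission.
#' @param seed Integer seed for this episode; content depends only on it and
#'   the spec, never on cohort ordering.
#' @return List with `episode` (static row), `observations`,
#'   `interventions` tibbles.
#' @export
simulate_episode <- function(spec, episode_id, septic, reference_time_h,
                             seed) {
  set.seed(seed)
  prof <- spec$profiles
  panel <- spec$panel
  t_end <- reference_time_h

  # static features: age lognormal around a toddler-weighted census,
  # sex ~65% male, weight loosely tied to age
  age <- min(17, max(0.05, stats::rlnorm(1, log(1.88), 1.0)))
  sex <- if (stats::runif(1) < 0.649) "male" else "female"
  weight <- max(2.5, 3.3 + 2.2 * age + stats::rnorm(1, 0, 2))

  obs_list <- vector("list", nrow(prof))
  for (i in seq_len(nrow(prof))) {
    v <- prof$variable[i]
    if (stats::runif(1) < prof$missing_rate[i]) next
    mlog <- .interval_meanlog(prof$interval_q70_h[i], prof$interval_sdlog[i])
    # draw enough gaps to span the episode
    n_max <- ceiling(t_end / exp(mlog - 2 * prof$interval_sdlog[i])) + 2L
    gaps <- stats::rlnorm(n_max, mlog, prof$interval_sdlog[i])
    times <- cumsum(c(stats::runif(1, 0, gaps[1]), gaps[-1]))
    times <- times[times <= t_end]
    if (length(times) == 0) times <- stats::runif(1, 0, t_end)
    n_t <- length(times)

    b_ep <- stats::rnorm(1, 0, prof$re_sd[i])
    # OU sampled sequentially at the irregular times
    x <- numeric(n_t)
    x[1] <- stats::rnorm(1, 0, prof$ou_sd[i])
    if (n_t > 1) {
      dt <- diff(times)
      a <- exp(-dt / prof$ou_length_h[i])
      innov_sd <- prof$ou_sd[i] * sqrt(1 - a^2)
      for (k in 2:n_t) x[k] <- a[k - 1] * x[k - 1] +
          stats::rnorm(1, 0, innov_sd[k - 1])
    }
    mu <- prof$baseline[i] + b_ep + x +
      stats::rnorm(n_t, 0, prof$noise_sd[i])
    if (septic && spec$drift_scale != 0) {
      ramp_start <- reference_time_h - spec$drift_duration_h
      ramp <- pmax(0, times - ramp_start)
      mu <- mu + spec$drift_scale * prof$drift_slope[i] * ramp
    }
    j <- match(v, panel$variable)
    mu <- pmin(pmax(mu, panel$plausible_low[j]), panel$plausible_high[j])
    obs_list[[i]] <- tibble::tibble(episode_id = episode_id, time_h = times,
                                    variable = v, value = mu)
  }
  observations <- dplyr::bind_rows(obs_list)

  iv <- list()
  p <- spec$intervention_probs
  if (septic) {
    if (stats::runif(1) < p$antibiotics) {
      iv$ab <- c(max(0, reference_time_h - stats::runif(1, 0, 4)),
                 "antibiotics")
    }
    if (stats::runif(1) < p$vasopressors) {
      iv$vp <- c(max(0, reference_time_h - stats::runif(1, 0, 2)),
                 "vasopressors")
    }
    if (stats::runif(1) < p$glucocorticoids) {
      iv$gc <- c(max(0, reference_time_h - stats::runif(1, 0, 3)),
                 "glucocorticoids")
    }
    if (stats::runif(1) < p$mechanical_ventilation) {
      iv$mv <- c(max(0, reference_time_h - stats::runif(1, 0, 2)),
                 "mechanical_ventilation")
    }
  } else if (stats::runif(1) < p$control_antibiotics) {
    iv$ab <- c(stats::runif(1, 0, reference_time_h), "antibiotics")
  }
  interventions <- if (length(iv) > 0) {
    tibble::tibble(episode_id = episode_id,
                   time_h = as.numeric(vapply(iv, `[`, "", 1)),
                   code = vapply(iv, `[`, "", 2))
  } else {
    tibble::tibble(episode_id = character(), time_h = numeric(),
                   code = character())
  }

  episode <- tibble::tibble(
    episode_id = episode_id, age_years = age, sex = sex, weight_kg = weight,
    label = if (septic) "septic" else "control",
    onset_time_h = if (septic) reference_time_h else NA_real_,
    anchor_time_h = if (septic) NA_real_ else reference_time_h
  )
  list(episode = episode, observations = observations,
       interventions = interventions)
}

#' Simulate a full two-class cohort
#'
#' Deterministic given the spec's seed. Exactly
#' `floor(n_episodes * prevalence)` episodes are septic, assigned by
#' permutation; each episode's content is generated from its own derived
#' seed so it does not depend on cohort ordering.
#'
#' @param spec A `sw_cohort_spec` from [cohort_spec()].
#' @return A validated `sw_cohort`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_episodes = 20, seed = 42))
#' cohort
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sw_cohort_spec"))
  n <- spec$n_episodes
  n_septic <- floor(n * spec$prevalence)
  set.seed(spec$seed)
  septic <- rep(FALSE, n)
  septic[sample.int(n, n_septic)] <- TRUE
  refs <- stats::runif(n, spec$onset_range_h[1], spec$onset_range_h[2])
  ep_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("ep%04d", seq_len(n))

  sims <- purrr::pmap(list(ids, septic, refs, ep_seeds),
                      function(id, s, r, sd) {
                        simulate_episode(spec, id, s, r, sd)
                      })
  suppressWarnings(sepsis_cohort(
    episodes = purrr::map_dfr(sims, "episode"),
    observations = purrr::map_dfr(sims, "observations"),
    interventions = purrr::map_dfr(sims, "interventions"),
    panel = spec$panel
  ))
}

#' Remove whole variables from episodes at a given rate
#'
#' Emulates episode-level missingness: with probability `rates[v]`, an
#' episode's observations of variable `v` are removed entirely.
#'
#' @param cohort A `sw_cohort`.
#' @param rates Named numeric vector of per-variable removal probabilities
#'   in `[0, 1]`; a single unnamed value applies to all panel variables.
#' @param seed Integer seed.
#' @return A `sw_cohort` with observations removed.
#' @export
inject_missingness <- function(cohort, rates, seed = 1) {
  panel <- attr(cohort, "panel")
  if (is.null(names(rates))) {
    if (length(rates) != 1) stop("unnamed rates must be length 1",
                                 call. = FALSE)
    rates <- stats::setNames(rep(rates, nrow(panel)), panel$variable)
  }
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  combos <- tidyr::expand_grid(episode_id = cohort$episodes$episode_id,
                               variable = names(rates))
  combos$drop <- stats::runif(nrow(combos)) < rates[combos$variable]
  drop_keys <- combos[combos$drop, c("episode_id", "variable")]
  obs <- dplyr::anti_join(cohort$observations, drop_keys,
                          by = c("episode_id", "variable"))
  out <- cohort
  out$observations <- obs
  out
}
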