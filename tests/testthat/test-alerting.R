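test_that("tier mapping reproduces both published schemes", {
  A <- tier_scheme("A")
  expect_equal(as.character(map_tier(c(0.55, 0.70, 0.85), A)),
               c("low", "medium", "high"))
  expect_equal(as.character(map_tier(0.60, A)), "medium")  # closed below
  expect_equal(as.character(map_tier(0.80, A)), "high")
  expect_equal(as.character(map_tier(0.49, A)), "none")
  B <- tier_scheme("B")
  expect_equal(as.character(map_tier(0.95, B)), "tier3")
  expect_equal(as.character(map_tier(0.85, B)), "tier2")
  expect_equal(as.character(map_tier(0.70, B)), "tier1")
  expect_equal(as.character(map_tier(0.65, B)), "none")   # open below
})

test_that("tier mapping is total and monotone on [0, 1]", {
  s <- seq(0, 1, by = 0.001)
  for (scheme in list(tier_scheme("A"), tier_scheme("B"))) {
    tiers <- map_tier(s, scheme)
    expect_false(any(is.na(tiers)))
    expect_true(all(diff(as.integer(tiers)) >= 0))
  }
  expect_error(tier_scheme(tibble::tibble(
    tier = c("x", "y"), lower = c(0.8, 0.5), upper = Inf,
    closed_lower = TRUE)), "increasing")
})

# a hand-written alert trace with the scheme attached
planted_alerts <- function(df, scheme = tier_scheme("A")) {
  structure(df, scheme = scheme,
            class = c("sw_alerts", class(tibble::tibble())))
}

test_that("lead times are onset minus first qualifying alert", {
  episodes <- tibble::tibble(
    episode_id = c("s1", "s2", "s3", "c1"), age_years = 1, sex = "male",
    weight_kg = 10, label = c("septic", "septic", "septic", "control"),
    onset_time_h = c(30, 40, 50, NA), anchor_time_h = c(NA, NA, NA, 35))
  obs <- tibble::tibble(episode_id = c("s1", "s2", "s3", "c1"),
                        time_h = 1, variable = "HR", value = 120)
  cohort <- sepsis_cohort(episodes, obs)
  trace <- planted_alerts(tibble::tibble(
    episode_id = c("s1", "s1", "s2", "s3", "c1"),
    time_h = c(24, 30, 33.8, 49, 30),
    rel_time_h = 0,
    score = c(0.7, 0.9, 0.85, 0.95, 0.55),
    tier = c("medium", "high", "high", "high", "low"),
    alert = TRUE))
  lt <- lead_time(trace, cohort, "high")
  expect_equal(lt$lead_time_h[lt$episode_id == "s1"], 0)    # at onset
  expect_equal(lt$lead_time_h[lt$episode_id == "s2"], 6.2)  # early alert
  expect_equal(lt$lead_time_h[lt$episode_id == "s3"], 1)
  summ <- lead_time_summary(trace, cohort, "high")
  expect_equal(summ$median_lead_h, sort(c(0, 6.2, 1))[2])   # direct sort
  expect_equal(summ$alert_sensitivity, 1)
  expect_equal(summ$max_lead_h, 6.2)
  only_controls <- sepsis_cohort(episodes[4, ], obs[4, ])
  expect_error(lead_time(trace, only_controls, "high"), "septic")
})

test_that("alert agreement binarizes episodes and scores kappa", {
  episodes <- tibble::tibble(
    episode_id = c("s1", "s2", "c1", "c2"), age_years = 1, sex = "male",
    weight_kg = 10, label = c("septic", "septic", "control", "control"),
    onset_time_h = c(30, 30, NA, NA), anchor_time_h = c(NA, NA, 30, 30))
  obs <- tibble::tibble(episode_id = episodes$episode_id, time_h = 1,
                        variable = "HR", value = 120)
  cohort <- sepsis_cohort(episodes, obs)
  trace <- planted_alerts(tibble::tibble(
    episode_id = c("s1", "s2", "c1", "c2"),
    time_h = 25, rel_time_h = -5,
    score = c(0.9, 0.55, 0.85, 0.3),
    tier = c("high", "low", "high", "none"),
    alert = c(TRUE, TRUE, TRUE, FALSE)))
  ag <- alert_agreement(trace, cohort, "high")
  expect_equal(unname(ag$predicted), c(1, 0, 1, 0))
  expect_equal(ag$kappa, cohens_kappa(c(1, 0, 1, 0), c(1, 1, 0, 0)))
})

test_that("outcome contrasts recompute absolute and relative reductions", {
  oc <- outcome_contrast(29.7, 19.6)
  expect_equal(oc$absolute_reduction, 10.1)
  expect_equal(outcome_contrast(50, 25)$absolute_reduction, 25)
  expect_equal(outcome_contrast(50, 25)$relative_reduction, 50)
  expect_equal(outcome_contrast(40, 40)$absolute_reduction, 0)
  expect_equal(outcome_contrast(40, 40)$relative_reduction, 0)
  expect_error(outcome_contrast(0, 0), "zero baseline")
})

test_that("replayed alerts use only past data and rise with tier", {
  prof <- small_profiles()
  cohort <- simulate_cohort(cohort_spec(n_episodes = 14, seed = 17,
                                        profiles = prof))
  windows <- fit_windows(cohort)
  cfg <- mgp_config(task_rank = 3)
  hyper <- mgp_hyperparameters(cohort, windows, cfg, seed = 1)
  grids <- impute_cohort(cohort, windows, cfg, hyper = hyper)
  bank <- build_bank(cohort, grids, horizons = 0,
                     variant = "tabular_boosted", boost = fast_boost())
  sub_ids <- c(cohort$episodes$episode_id[cohort$episodes$label == "control"][1],
               cohort$episodes$episode_id[cohort$episodes$label == "septic"][1])
  sub <- cohort
  sub$episodes <- sub$episodes[sub$episodes$episode_id %in% sub_ids, ]
  sub$observations <- sub$observations[
    sub$observations$episode_id %in% sub_ids, ]
  sub$interventions <- sub$interventions[
    sub$interventions$episode_id %in% sub_ids, ]
  trace <- simulate_alerts(bank, sub, windows, hyper, cfg,
                           scheme = tier_scheme("A"), replay_h = 4)
  expect_equal(nrow(trace), 2 * 5)
  expect_true(all(trace$score >= 0 & trace$score <= 1))
  # alerts only fire when the tier rises above everything seen before
  for (id in sub_ids) {
    tr <- trace[trace$episode_id == id, ]
    ti <- match(tr$tier, c("none", "low", "medium", "high")) - 1L
    seen <- cummax(c(0L, utils::head(ti, -1)))
    expect_equal(tr$alert, ti > seen)
  }

  # leakage probe: corrupt observations strictly after a replay step
  id <- sub_ids[2]
  t_probe <- trace$time_h[trace$episode_id == id][2]
  poisoned <- sub
  late <- poisoned$observations$episode_id == id &
    poisoned$observations$time_h > t_probe
  poisoned$observations$value[late] <-
    poisoned$observations$value[late] * 0 +
    default_panel()$plausible_high[match(
      poisoned$observations$variable[late], default_panel()$variable)]
  rt1 <- predict_risk(bank, sub, id, t_probe, windows, hyper, cfg)
  rt2 <- predict_risk(bank, poisoned, id, t_probe, windows, hyper, cfg)
  expect_identical(rt1$score, rt2$score)
})
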