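test_that("the generator is deterministic in the seed and exact in counts", {
  spec <- cohort_spec(n_episodes = 25, prevalence = 0.262, seed = 5,
                      profiles = small_profiles())
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$observations, b$observations)
  expect_identical(a$episodes, b$episodes)
  c2 <- simulate_cohort(cohort_spec(n_episodes = 25, prevalence = 0.262,
                                    seed = 6, profiles = small_profiles()))
  expect_false(identical(a$observations$value, c2$observations$value))
  # floor convention: floor(25 * 0.262) = 6 septic episodes
  expect_equal(sum(a$episodes$label == "septic"), 6L)
  expect_true(all(is.finite(
    a$episodes$onset_time_h[a$episodes$label == "septic"])))
  expect_true(all(is.na(
    a$episodes$onset_time_h[a$episodes$label == "control"])))
})

test_that("zero prevalence yields no septic episodes or onset times", {
  cohort <- simulate_cohort(cohort_spec(n_episodes = 10, prevalence = 0,
                                        seed = 1,
                                        profiles = small_profiles()))
  expect_equal(sum(cohort$episodes$label == "septic"), 0L)
  expect_true(all(is.na(cohort$episodes$onset_time_h)))
})

test_that("a linear lactate ramp shifts the pre-onset mean by its closed-form average", {
  # slope s over the final d hours: the mean offset of values uniformly
  # sampled in that stretch is s*d/2 (mid-ramp average)
  prof <- small_profiles()
  prof$drift_slope <- 0
  prof$drift_slope[prof$variable == "LAC"] <- 0.5
  prof$missing_rate <- 0
  # dense sampling of lactate so the window estimate is stable
  prof$interval_q70_h[prof$variable == "LAC"] <- 1
  prof$ou_length_h[prof$variable == "LAC"] <- 2
  n <- 400
  spec_s <- cohort_spec(n_episodes = n, prevalence = 1, seed = 21,
                        profiles = prof, drift_duration_h = 6)
  spec_c <- cohort_spec(n_episodes = n, prevalence = 0, seed = 21,
                        profiles = prof)
  last6 <- function(cohort) {
    refs <- reference_times(cohort)
    obs <- dplyr::left_join(cohort$observations,
                            refs[, c("episode_id", "reference_time_h")],
                            by = "episode_id")
    obs <- obs[obs$variable == "LAC" &
                 obs$reference_time_h - obs$time_h <= 6 &
                 obs$reference_time_h - obs$time_h >= 0, ]
    mean(obs$value)
  }
  delta <- last6(simulate_cohort(spec_s)) - last6(simulate_cohort(spec_c))
  expect_lt(abs(delta - 0.5 * 6 / 2), 0.25)
})

test_that("interval quantiles of the generator are recoverable", {
  prof <- small_profiles()[small_profiles()$variable == "HR", ]
  prof$interval_q70_h <- 4
  prof$missing_rate <- 0
  cohort <- simulate_cohort(cohort_spec(n_episodes = 200, prevalence = 0,
                                        seed = 9, profiles = prof))
  hist <- interval_histogram(cohort, "HR")
  w <- window_size(hist, q = 0.70)
  expect_lt(abs(w - 4) / 4, 0.10)
})

test_that("zero drift makes septic and control episodes indistinguishable", {
  prof <- small_profiles()
  prof$missing_rate <- 0
  spec <- cohort_spec(n_episodes = 60, prevalence = 0.5, seed = 31,
                      profiles = prof, drift_scale = 0)
  cohort <- simulate_cohort(spec)
  refs <- reference_times(cohort)
  obs <- dplyr::left_join(cohort$observations, refs, by = "episode_id")
  obs <- obs[obs$variable == "LAC" &
               obs$reference_time_h - obs$time_h <= 6 &
               obs$reference_time_h - obs$time_h >= 0, ]
  per_ep <- tapply(obs$value, obs$episode_id, mean)
  lab <- refs$label[match(names(per_ep), refs$episode_id)]
  p <- stats::wilcox.test(per_ep[lab == "septic"],
                          per_ep[lab == "control"])$p.value
  expect_gt(p, 0.01)
})

test_that("episode-level missingness injection hits its rate", {
  expect_error(inject_missingness(small_cohort(), 1.2), "rates")
  cohort <- small_cohort()
  same <- inject_missingness(cohort, c(HR = 0), seed = 1)
  expect_identical(same$observations, cohort$observations)
  gone <- inject_missingness(cohort, c(HR = 1), seed = 1)
  expect_false("HR" %in% gone$observations$variable)
  # rate 0.3 across 200 episodes x 5 variables = 1000 Bernoulli draws
  big <- simulate_cohort(cohort_spec(n_episodes = 200, seed = 13,
                                     profiles = small_profiles()))
  rates <- stats::setNames(rep(0.3, 5), small_profiles()$variable)
  thin <- inject_missingness(big, rates, seed = 4)
  present <- dplyr::distinct(thin$observations, episode_id, variable)
  frac_missing <- 1 - nrow(present) / (200 * 5)
  # generator's own baseline missingness is near zero for these variables
  base <- 1 - nrow(dplyr::distinct(big$observations, episode_id,
                                   variable)) / (200 * 5)
  expect_lt(abs((frac_missing - base) - 0.3 * (1 - base)), 0.035)
})

test_that("episode content does not depend on cohort ordering", {
  spec <- cohort_spec(n_episodes = 12, seed = 3,
                      profiles = small_profiles())
  a <- simulate_cohort(spec)
  spec2 <- cohort_spec(n_episodes = 12, seed = 3,
                       profiles = small_profiles())
  b <- simulate_cohort(spec2)
  expect_identical(a$observations, b$observations)
})
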