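# hand-made hyperparameter state for controlled single/two-variable tests
manual_hyper <- function(vars, B, ls, mu = 0, sdv = 1, s2 = 1,
                         noise = 1e-6) {
  structure(list(
    variables = vars,
    mu = stats::setNames(rep(mu, length(vars)), vars),
    sd = stats::setNames(rep(sdv, length(vars)), vars),
    median = stats::setNames(rep(mu, length(vars)), vars),
    B = B, length_scale_h = stats::setNames(rep(ls, length(vars)), vars),
    s2 = s2, noise = noise, kernel = "exponential"),
    class = "sw_mgp_hyper")
}

one_var_windows <- function(variable = "HR", W = 2, N = 2, r1 = 0.8) {
  structure(tibble::tibble(variable = variable, window_size_h = W,
                           n_windows = N, span_h = W * N,
                           lag_r = list(c(lag1 = r1))),
            class = c("sw_windows", class(tibble::tibble())))
}

test_that("the GP posterior interpolates a single observation", {
  cohort <- manual_cohort(9.5, 130, anchor = 10)
  windows <- one_var_windows(W = 6, N = 2)
  hyper <- manual_hyper("HR", matrix(1, 1, 1, dimnames = list("HR", "HR")),
                        ls = 6, mu = 110, sdv = 15)
  post <- fit_mgp(cohort, "e1", windows, hyper)
  pr <- predict(post, 9.5, "HR")
  expect_lt(abs(pr$mean - 130), 1e-3)
  expect_lt(pr$sd, 0.1)
})

test_that("posterior matches a closed-form dense GP oracle", {
  # independent oracle: textbook GP regression with the same kernel,
  # computed with solve() on the dense system
  tt <- c(1, 3, 4.5)
  yy <- c(120, 100, 126)
  ls <- 3; mu <- 110; sdv <- 15; s2 <- 1.3; noise <- 0.05
  cohort <- manual_cohort(tt, yy, anchor = 5)
  windows <- one_var_windows(W = 10, N = 2)
  hyper <- manual_hyper("HR", matrix(1, 1, 1, dimnames = list("HR", "HR")),
                        ls = ls, mu = mu, sdv = sdv, s2 = s2, noise = noise)
  post <- fit_mgp(cohort, "e1", windows, hyper,
                  config = mgp_config(jitter = 1e-12))
  tq <- c(0.5, 2, 3.7, 4.9, 5)
  got <- predict(post, tq, "HR")

  kfun <- function(a, b) s2 * exp(-abs(outer(a, b, "-")) / ls)
  yz <- (yy - mu) / sdv
  K <- kfun(tt, tt) + diag(noise + 1e-12, 3)
  Ks <- kfun(tq, tt)
  m_or <- Ks %*% solve(K, yz)
  v_or <- s2 - rowSums(Ks * t(solve(K, t(Ks))))
  expect_lt(max(abs(got$mean - (m_or * sdv + mu))), 1e-8)
  expect_lt(max(abs(got$sd - sqrt(pmax(v_or, 0)) * sdv)), 1e-8)
})

test_that("a strongly coupled second variable tracks the observed one", {
  set.seed(8)
  tt <- seq(0.5, 11.5, by = 1)
  f <- sin(tt / 2)
  episodes <- tibble::tibble(episode_id = "e1", age_years = 1, sex = "male",
                             weight_kg = 10, label = "control",
                             anchor_time_h = 12)
  obs <- tibble::tibble(episode_id = "e1", time_h = tt, variable = "HR",
                        value = 110 + 15 * f)
  cohort <- sepsis_cohort(episodes, obs)
  B <- matrix(c(1, 0.99, 0.99, 1), 2, 2,
              dimnames = list(c("HR", "MAP"), c("HR", "MAP")))
  windows <- structure(
    tibble::tibble(variable = c("HR", "MAP"), window_size_h = 6,
                   n_windows = 2, span_h = 12,
                   lag_r = list(c(lag1 = 0.8), c(lag1 = 0.8))),
    class = c("sw_windows", class(tibble::tibble())))
  hyper <- manual_hyper(c("HR", "MAP"), B, ls = 6, mu = 0, sdv = 1,
                        noise = 1e-4)
  hyper$mu <- c(HR = 110, MAP = 65)
  hyper$sd <- c(HR = 15, MAP = 8)
  hyper$median <- hyper$mu
  post <- fit_mgp(cohort, "e1", windows, hyper)
  pr_hr <- predict(post, tt, "HR")
  pr_map <- predict(post, tt, "MAP")
  z_hr <- (pr_hr$mean - 110) / 15
  z_map <- (pr_map$mean - 65) / 8
  expect_gt(stats::cor(z_hr, z_map), 0.95)
})

test_that("adding an observation never inflates posterior uncertainty", {
  cohort <- manual_cohort(c(2, 5, 9), c(120, 115, 125), anchor = 10)
  windows <- one_var_windows(W = 10, N = 1)
  hyper <- manual_hyper("HR", matrix(1, 1, 1, dimnames = list("HR", "HR")),
                        ls = 4, mu = 110, sdv = 15, noise = 0.05)
  post <- fit_mgp(cohort, "e1", windows, hyper)
  tq <- seq(0, 10, by = 1)
  sd_before <- predict(post, tq, "HR")$sd
  more <- manual_cohort(c(2, 5, 7, 9), c(120, 115, 118, 125), anchor = 10)
  sd_after <- predict(fit_mgp(more, "e1", windows, hyper), tq, "HR")$sd
  expect_true(all(sd_after <= sd_before + 1e-6))
  expect_true(all(sd_after >= 0))
})

test_that("far from data the posterior reverts to the prior", {
  cohort <- manual_cohort(99.5, 130, anchor = 100)
  windows <- one_var_windows(W = 50, N = 2)
  hyper <- manual_hyper("HR", matrix(1, 1, 1, dimnames = list("HR", "HR")),
                        ls = 2, mu = 110, sdv = 15, noise = 0.01)
  post <- fit_mgp(cohort, "e1", windows, hyper)
  far <- predict(post, 5, "HR")
  expect_lt(abs(far$mean - 110), 0.5)          # prior mean
  expect_lt(abs(far$sd - 15), 0.5)             # prior sd
})

test_that("the windowed estimate is a correlation-weighted mean", {
  # two windows with means 4 and 8, weights 1 and 0.5
  cohort <- manual_cohort(c(0.5, 1.5), c(8, 4), variable = "LAC",
                          anchor = 2)
  windows <- one_var_windows("LAC", W = 1, N = 2, r1 = 0.5)
  est <- ctwh_estimate(cohort, "e1", "LAC", windows, t = 2)
  expect_equal(est$value, (1 * 4 + 0.5 * 8) / 1.5)
  expect_equal(est$weight, 1)

  # constant windows are invariant to the weights
  flat <- manual_cohort(c(0.5, 1.5), c(5, 5), variable = "LAC", anchor = 2)
  expect_equal(ctwh_estimate(flat, "e1", "LAC", windows, t = 2)$value, 5)

  # all windows empty: undefined with zero weight
  empty <- ctwh_estimate(cohort, "e1", "LAC", windows, t = 20)
  expect_equal(empty$weight, 0)
  expect_true(is.na(empty$value))
})

test_that("merging is a convex combination with documented endpoints", {
  cfg_fixed <- mgp_config(merge_weight_mode = "fixed", fixed_weight = 0)
  expect_equal(merge_estimates(4, 8, 1, cfg_fixed)$value, 4)
  cfg_fixed1 <- mgp_config(merge_weight_mode = "fixed", fixed_weight = 1)
  expect_equal(merge_estimates(4, 8, 1, cfg_fixed1)$value, 8)
  cfg25 <- mgp_config(merge_weight_mode = "fixed", fixed_weight = 0.25)
  expect_equal(merge_estimates(4, 8, 1, cfg25)$value, 5.0)
  # fallbacks
  expect_equal(merge_estimates(NA, 8, 1, cfg25)$source, "ctwh")
  expect_equal(merge_estimates(4, NA, 0, cfg25)$source, "mgp")
  expect_equal(merge_estimates(NA, NA, 0, cfg25)$source, "undefined")
})

test_that("imputed grids are finite, flagged, and reproduce observations", {
  grids <- small_grids()
  expect_true(all(is.finite(grids$value)))
  expect_true(all(grids$source %in%
                    c("observed", "ctwh_merge", "mgp", "ctwh",
                      "out_of_span", "median_fallback")))
  expect_true(all(grids$sd[!is.na(grids$sd)] >= 0))
  # posterior predictive close to the data at observed cells
  cohort <- small_cohort()
  m <- small_mgp()
  obs_cells <- grids[grids$source == "observed", ]
  nearest <- dplyr::inner_join(
    obs_cells, cohort$observations,
    by = c("episode_id", "variable"), suffix = c("", "_obs"),
    relationship = "many-to-many")
  nearest <- nearest[abs(nearest$time_h - nearest$time_h_obs) <= 0.5, ]
  resid <- abs(nearest$value - nearest$value_obs)
  tol <- 2 * sqrt(m$hyper$noise) *
    m$hyper$sd[nearest$variable] + 2 * nearest$sd
  expect_gt(mean(resid <= tol + 1e-9), 0.90)
})
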