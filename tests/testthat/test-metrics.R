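test_that("auroc equals exhaustive pairwise concordance and rank-sum", {
  # brute-force oracle: count concordant pairs, ties at half credit
  pair_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    total <- 0
    for (p in pos) for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
    total / (length(pos) * length(neg))
  }
  set.seed(1)
  for (rep in 1:20) {
    n <- sample(6:50, 1)
    y <- c(rep(1, 3), rep(0, 3), rbinom(n - 6, 1, 0.5))
    s <- round(stats::runif(n), 2)   # rounding forces ties
    expect_equal(auroc(s, y), pair_auc(s, y), tolerance = 1e-12)
    # Mann-Whitney identity via wilcox.test's U statistic
    w <- suppressWarnings(stats::wilcox.test(s[y == 1], s[y == 0]))
    expect_equal(auroc(s, y),
                 unname(w$statistic) / (sum(y == 1) * sum(y == 0)),
                 tolerance = 1e-12)
  }
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("auprc has the documented endpoints and baseline", {
  expect_equal(auprc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auprc(c(10, 1:9), c(1, rep(0, 9))), 1.0)
  set.seed(2)
  n <- 20000; prev <- 0.3
  y <- rbinom(n, 1, prev)
  s <- stats::runif(n)
  expect_lt(abs(auprc(s, y) - prev), 0.02)
  expect_error(auprc(1:3, c(0, 0, 0)), "no positives")
})

test_that("confusion metrics reproduce a hand 2x2 table", {
  # TP=88 FN=12 TN=84 FP=16 at threshold 0.5
  scores <- c(rep(0.9, 88), rep(0.1, 12), rep(0.1, 84), rep(0.9, 16))
  labels <- c(rep(1, 100), rep(0, 100))
  cf <- confusion_at(scores, labels, 0.5)
  expect_equal(cf$sensitivity, 0.88)
  expect_equal(cf$specificity, 0.84)
  expect_equal(cf$accuracy, 0.86)
  expect_equal(confusion_at(scores, labels, 0)$sensitivity, 1)
  hi <- confusion_at(scores, labels, 0.95)
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
})

test_that("the Youden index is sensitivity + specificity - 1", {
  expect_equal(round(youden(0.818, 0.828), 3), 0.646)
  expect_equal(round(youden(0.777, 0.785), 3), 0.562)
  expect_equal(youden(1, 1), 1)
})

test_that("the Brier score is the mean squared probability error", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 8), rep(c(0, 1), 4)), 0.25)
  expect_equal(brier(c(0.8, 0.3, 0.6, 0.1), c(1, 0, 0, 0)),
               mean(c(0.04, 0.09, 0.36, 0.01)))
})

test_that("bootstrap intervals are seeded percentile intervals", {
  set.seed(3)
  y <- rep(c(0, 1), each = 40)
  s <- y + stats::rnorm(80, 0, 0.8)
  ci1 <- bootstrap_ci(auroc, s, y, B = 200, seed = 7)
  ci2 <- bootstrap_ci(auroc, s, y, B = 200, seed = 7)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lo, ci1$point)
  expect_gte(ci1$hi, ci1$point)
  const <- bootstrap_ci(function(s, y) 0.42, s, y, B = 100, seed = 1)
  expect_equal(const$lo, 0.42)
  expect_equal(const$hi, 0.42)
})

test_that("Cohen's kappa matches its closed form and limits", {
  # 2x2 agreement table a=40 b=10 c=10 d=40: p_o=0.8, p_e=0.5, kappa=0.6
  pred <- c(rep(1, 50), rep(0, 50))
  conf <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  expect_equal(cohens_kappa(pred, conf), 0.6)
  expect_equal(cohens_kappa(conf, conf), 1.0)
  set.seed(4)
  a <- rbinom(20000, 1, 0.4)
  b <- rbinom(20000, 1, 0.6)
  expect_lt(abs(cohens_kappa(a, b)), 0.02)
  expect_error(cohens_kappa(rep(1, 5), rep(1, 5)), "constant")
})

test_that("indicator frequency deviation counts per-episode sampling", {
  a <- manual_cohort(c(0.5, 1.5), c(110, 120), anchor = 2)
  b <- manual_cohort(1, 115, anchor = 2)
  dev <- indicator_frequency_deviation(a, b, cumulative_windows_h = 2)
  expect_equal(dev$dev_2h[dev$variable == "HR"], 1.0)
  none <- indicator_frequency_deviation(a, a)
  expect_true(all(as.matrix(none[, -1]) == 0))
  swapped <- indicator_frequency_deviation(b, a, cumulative_windows_h = 2)
  expect_equal(swapped$dev_2h, -dev$dev_2h)
})

test_that("tree Shapley values are exact and symmetric", {
  set.seed(5)
  n <- 200
  x <- cbind(a = rep(c(0, 1), each = n / 2), b = stats::rnorm(n))
  y <- x[, "a"]
  bst <- train_boosted(x, y, config = fast_boost())
  attr_rep <- shapley_attributions(bst, x)
  shap <- attr(attr_rep, "shap")
  base <- attr(attr_rep, "base")
  # local accuracy on the margin scale
  marg <- stats::qlogis(pmin(pmax(predict(bst, x), 1e-12), 1 - 1e-12))
  expect_lt(max(abs(rowSums(shap) + base - marg)), 1e-4)

  # brute-force oracle on a single-split stump: phi_split = f(x) - E[f]
  d1 <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  stump <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                            max_depth = 1, eta = 1,
                                            nthread = 1),
                              data = d1, nrounds = 1, verbose = 0)
  sb <- structure(list(model = stump, feature_names = colnames(x)),
                  class = "sw_booster")
  rep2 <- shapley_attributions(sb, x)
  shap2 <- attr(rep2, "shap")
  f <- stats::qlogis(stats::predict(stump, d1))
  expect_lt(max(abs(shap2[, "a"] - (f - mean(f)))), 1e-6)
  expect_lt(max(abs(shap2[, "b"])), 1e-9)

})

test_that("duplicated features get symmetric credit from the sampling estimator", {
  set.seed(9)
  u <- stats::rnorm(40)
  x <- cbind(u = u, u2 = u, w = stats::rnorm(40))
  rep_s <- shapley_attributions(function(m) m[, "u"] + m[, "u2"], x,
                                nsim = 400, seed = 3)
  m <- tibble::as_tibble(rep_s)
  expect_lt(abs(m$mean_abs_shap[m$feature == "u"] -
                  m$mean_abs_shap[m$feature == "u2"]),
            0.1 * m$mean_abs_shap[m$feature == "u"])
})

test_that("sampling Shapley handles black-box models with a null case", {
  set.seed(6)
  x <- matrix(stats::rnorm(40), 20, 2, dimnames = list(NULL, c("u", "v")))
  const_rep <- shapley_attributions(function(m) rep(2, nrow(m)), x,
                                    nsim = 20)
  expect_equal(max(abs(attr(const_rep, "shap"))), 0)
  lin_rep <- shapley_attributions(function(m) 3 * m[, "u"], x, nsim = 300,
                                  seed = 2)
  m <- tibble::as_tibble(lin_rep)
  expect_gt(m$mean_abs_shap[m$feature == "u"],
            5 * m$mean_abs_shap[m$feature == "v"])
})

test_that("evaluate_bank produces a coherent per-horizon table", {
  cohort <- small_cohort()
  grids <- small_grids()
  bank <- build_bank(cohort, grids, horizons = c(0, 6),
                     variant = "tabular_boosted", boost = fast_boost())
  mt <- evaluate_bank(bank, cohort, grids, B = 150, seed = 2)
  expect_equal(nrow(mt), 2L)
  expect_true(all(mt$auroc >= 0 & mt$auroc <= 1))
  expect_true(all(mt$auroc_lo <= mt$auroc & mt$auroc <= mt$auroc_hi))
  # Youden recomputes from the table's own sensitivity/specificity
  expect_equal(mt$youden, mt$sensitivity + mt$specificity - 1)
  td <- tidy(mt)
  expect_setequal(unique(td$metric),
                  c("auroc", "auprc", "accuracy", "sensitivity",
                    "specificity", "youden", "brier"))
  expect_equal(glance(mt)$n_horizons, 2L)
})
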