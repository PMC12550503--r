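#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the probability that a
#' random positive outscores a random negative, ties counted one half.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (0/1 or logical).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) area: walking down the score-sorted list,
#' precision is averaged at each recall increment — the average-precision
#' convention. Ties are handled by grouping equal scores.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0) stop("no positives", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # collapse tied scores to their final cumulative counts
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_tie]; fp <- fp[last_of_tie]
  prec <- tp / (tp + fp)
  rec <- tp / sum(y)
  d_rec <- diff(c(0, rec))
  sum(prec * d_rec)
}

#' Confusion metrics at a threshold
#'
#' Predicted positive iff `score >= threshold` (closed lower boundary).
#'
#' @inheritParams auroc
#' @param threshold Decision threshold in `[0, 1]`.
#' @return Named list: `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(labels))
}

#' Youden index
#'
#' `J = sensitivity + specificity - 1`, the standard summary of a binary
#' operating point.
#'
#' @param sensitivity,specificity Values in `[0, 1]`.
#' @return J in `[-1, 1]`.
#' @export
#' @examples
#' youden(0.818, 0.828)  # 0.646
youden <- function(sensitivity, specificity) {
  stopifnot(all(sensitivity >= 0 & sensitivity <= 1),
            all(specificity >= 0 & specificity <= 1))
  sensitivity + specificity - 1
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome.
#'
#' @inheritParams auroc
#' @return Value in `[0, 1]`.
#' @export
brier <- function(scores, labels) {
  stopifnot(all(scores >= 0 & scores <= 1))
  mean((scores - as.integer(labels))^2)
}

#' Percentile bootstrap confidence interval for a score metric
#'
#' Episode-level stratified resampling (positives and negatives drawn
#' separately, preserving class counts); the interval is the percentile
#' interval of the replicate metrics. Resamples on which the metric is
#' undefined are redrawn, counted and capped at `10 * B`.
#'
#' @param metric_fn Function `(scores, labels) -> scalar`, e.g. [auroc()].
#' @param scores,labels As in [auroc()].
#' @param B Number of replicates (>= 100; default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List `point`, `lo`, `hi`, `B`, `n_redrawn`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, B = 1000, conf = 0.95,
                         seed = 1) {
  if (B < 100) stop("B must be at least 100", call. = FALSE)
  labels <- as.integer(labels)
  point <- metric_fn(scores, labels)
  idx1 <- which(labels == 1)
  idx0 <- which(labels == 0)
  set.seed(seed)
  vals <- numeric(B)
  redrawn <- 0
  b <- 1
  draws <- 0
  while (b <= B) {
    draws <- draws + 1
    if (draws > 10 * B) stop("metric undefined on too many resamples",
                             call. = FALSE)
    take <- c(sample(idx1, length(idx1), replace = TRUE),
              sample(idx0, length(idx0), replace = TRUE))
    v <- tryCatch(metric_fn(scores[take], labels[take]),
                  error = function(e) NA_real_)
    if (is.finite(v)) {
      vals[b] <- v
      b <- b + 1
    } else {
      redrawn <- redrawn + 1
    }
  }
  a <- (1 - conf) / 2
  q <- unname(stats::quantile(vals, c(a, 1 - a)))
  list(point = point, lo = q[1], hi = q[2], B = B, n_redrawn = redrawn)
}

#' Chance-corrected agreement between two binary labelings
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement from the
#' marginal products.
#'
#' @param predicted,confirmed Equal-length binary vectors.
#' @return Cohen's kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(predicted, confirmed) {
  stopifnot(length(predicted) == length(confirmed))
  p <- as.integer(predicted)
  y <- as.integer(confirmed)
  n <- length(p)
  po <- mean(p == y)
  pe <- mean(p) * mean(y) + mean(1 - p) * mean(1 - y)
  if (abs(1 - pe) < 1e-12) {
    stop("kappa undefined: both raters are constant", call. = FALSE)
  }
  (po - pe) / (1 - pe)
}

#' Cumulative per-indicator sampling-frequency deviation between cohorts
#'
#' For each cumulative window `w` (hours back from each episode's
#' reference time) and shared variable: frequency = total observation count
#' within the window divided by the number of episodes; the deviation is
#' `freq_a - freq_b`, so a negative value means cohort B samples the
#' indicator more often.
#'
#' @param cohort_a,cohort_b Two `sw_cohort`s sharing variable codes.
#' @param cumulative_windows_h Window depths in hours (default
#'   `c(2, 6, 8)`).
#' @return Tibble `variable`, one column per window (`dev_<w>h`).
#' @export
indicator_frequency_deviation <- function(cohort_a, cohort_b,
                                          cumulative_windows_h = c(2, 6, 8)) {
  freq <- function(cohort, w) {
    n_ep <- nrow(cohort$episodes)
    if (n_ep == 0) stop("empty cohort", call. = FALSE)
    refs <- reference_times(cohort)
    obs <- dplyr::left_join(cohort$observations,
                            refs[, c("episode_id", "reference_time_h")],
                            by = "episode_id")
    back <- obs$reference_time_h - obs$time_h
    obs <- obs[back >= 0 & back <= w, ]
    dplyr::count(obs, .data$variable, name = "n") |>
      dplyr::mutate(freq = .data$n / n_ep)
  }
  vars <- intersect(unique(cohort_a$observations$variable),
                    unique(cohort_b$observations$variable))
  out <- tibble::tibble(variable = sort(vars))
  for (w in cumulative_windows_h) {
    fa <- freq(cohort_a, w)
    fb <- freq(cohort_b, w)
    dev <- (fa$freq[match(out$variable, fa$variable)] %|0% 0) -
      (fb$freq[match(out$variable, fb$variable)] %|0% 0)
    out[[paste0("dev_", w, "h")]] <- dev
  }
  out
}

# NA-to-zero helper for frequency joins
`%|0%` <- function(x, default) ifelse(is.na(x), default, x)

#' Evaluate the model bank on held-out data
#'
#' Scores every horizon, picks the operating threshold that maximizes the
#' Youden index on the evaluation scores, and reports AUROC, AUPRC,
#' accuracy, sensitivity, specificity, Youden index and Brier score with
#' percentile-bootstrap confidence intervals. Optional stratification by a
#' static episode feature evaluates each stratum separately (a stratum with
#' one class is skipped with a warning).
#'
#' @param bank A `sw_bank`.
#' @param cohort,grids Held-out cohort and its imputed grids.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param strata Optional name of an `episodes` column (e.g. an age band)
#'   to stratify by.
#' @return A `sw_metrics` tibble: one row per horizon (and stratum), with
#'   `point`/`lo`/`hi` columns per metric and the chosen threshold.
#' @export
evaluate_bank <- function(bank, cohort, grids, B = 1000, seed = 1,
                          strata = NULL) {
  groups <- list(all = cohort$episodes$episode_id)
  if (!is.null(strata)) {
    sv <- cohort$episodes[[strata]]
    groups <- split(cohort$episodes$episode_id, sv)
  }
  rows <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    for (h in bank$horizons) {
      sc <- score_horizon(bank, cohort, grids, h)
      sc <- sc[sc$episode_id %in% ids, ]
      if (length(unique(sc$label)) < 2) {
        warning("stratum '", g, "' has one class at horizon ", h,
                "; skipped", call. = FALSE)
        next
      }
      # operating threshold: maximize Youden over observed scores
      cand <- sort(unique(sc$score))
      js <- vapply(cand, function(th) {
        cf <- confusion_at(sc$score, sc$label, th)
        cf$sensitivity + cf$specificity - 1
      }, numeric(1))
      th <- cand[which.max(js)]
      cf <- confusion_at(sc$score, sc$label, th)
      ci <- function(fn) bootstrap_ci(fn, sc$score, sc$label, B = B,
                                      seed = seed)
      a <- ci(auroc)
      p <- ci(auprc)
      br <- ci(brier)
      rows[[length(rows) + 1]] <- tibble::tibble(
        stratum = g, horizon_h = h, n = nrow(sc), threshold = th,
        auroc = a$point, auroc_lo = a$lo, auroc_hi = a$hi,
        auprc = p$point, auprc_lo = p$lo, auprc_hi = p$hi,
        accuracy = cf$accuracy, sensitivity = cf$sensitivity,
        specificity = cf$specificity,
        youden = youden(cf$sensitivity, cf$specificity),
        brier = br$point, brier_lo = br$lo, brier_hi = br$hi,
        n_boot = B
      )
    }
  }
  structure(dplyr::bind_rows(rows),
            class = c("sw_metrics", class(tibble::tibble())))
}
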