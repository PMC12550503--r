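#' Pooled inter-measurement interval histogram for one variable
#'
#' Consecutive observation gaps are computed within each episode and pooled
#' across the cohort; episodes with fewer than two observations of the
#' variable contribute nothing.
#'
#' @param cohort A `sw_cohort`.
#' @param variable Panel variable code.
#' @return A `sw_intervals` tibble (`episode_id`, `interval_h`) with the
#'   variable stored as an attribute.
#' @export
interval_histogram <- function(cohort, variable) {
  obs <- cohort$observations[cohort$observations$variable == variable, ]
  gaps <- obs |>
    dplyr::group_by(.data$episode_id) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::summarise(interval_h = list(diff(.data$time_h)),
                     .groups = "drop") |>
    tidyr::unnest("interval_h")
  gaps <- gaps[gaps$interval_h > 0, ]
  if (nrow(gaps) == 0) {
    stop("cannot estimate window: no episode has two or more observations ",
         "of '", variable, "'", call. = FALSE)
  }
  structure(gaps, variable = variable,
            class = c("sw_intervals", class(tibble::tibble())))
}

#' Window size as an interval quantile
#'
#' The per-variable interpolation window size is the `q`-quantile of the
#' interval histogram (default the 70% quantile), with linear interpolation
#' between closest order statistics (R quantile type 7). With
#' `pooling = "per_episode_median"` the quantile is taken over per-episode
#' median intervals instead of the pooled multiset.
#'
#' @param hist A `sw_intervals` from [interval_histogram()].
#' @param q Quantile in (0, 1); default 0.70.
#' @param pooling `"pooled"` or `"per_episode_median"`.
#' @return Window size in hours (strictly positive scalar).
#' @export
window_size <- function(hist, q = 0.70,
                        pooling = c("pooled", "per_episode_median")) {
  pooling <- match.arg(pooling)
  x <- if (pooling == "pooled") {
    hist$interval_h
  } else {
    tapply(hist$interval_h, hist$episode_id, stats::median)
  }
  if (length(x) == 0) stop("empty interval set", call. = FALSE)
  unname(stats::quantile(x, probs = q, type = 7))
}

#' Correlation between the reference window and lagged windows
#'
#' Windows of width `window_size_h` are stacked back from each episode's
#' reference time: `T_k = [ref - (k+1) W, ref - k W)`. The within-window
#' summary is the arithmetic mean of observations falling in the window.
#' For each lag `k` the summaries of `T_0` and `T_k` are paired across
#' episodes (complete pairs only — both windows non-empty) and a Pearson
#' correlation computed.
#'
#' @param cohort A `sw_cohort`.
#' @param variable Panel variable code.
#' @param window_size_h Window width in hours (> 0).
#' @param config A `sw_ctwh_config`.
#' @return Tibble `lag`, `r`, `n_pairs` for lags `1..max_windows - 1`.
#' @export
window_correlation <- function(cohort, variable, window_size_h,
                               config = ctwh_config()) {
  stopifnot(window_size_h > 0)
  refs <- reference_times(cohort)
  obs <- cohort$observations[cohort$observations$variable == variable, ]
  obs <- dplyr::left_join(obs, refs[, c("episode_id", "reference_time_h")],
                          by = "episode_id")
  back <- obs$reference_time_h - obs$time_h
  obs <- obs[back >= 0, ]
  back <- back[back >= 0]
  obs$k <- floor(back / window_size_h)

  max_lag <- config$max_windows - 1L
  means <- obs[obs$k <= max_lag, ] |>
    dplyr::group_by(.data$episode_id, .data$k) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "k", values_from = "m",
                       names_prefix = "w")
  out <- tibble::tibble(lag = seq_len(max_lag), r = NA_real_,
                        n_pairs = 0L)
  if (max_lag == 0L) return(out[0, ])
  for (k in seq_len(max_lag)) {
    c0 <- means[["w0"]]
    ck <- means[[paste0("w", k)]]
    if (is.null(c0) || is.null(ck)) next
    keep <- is.finite(c0) & is.finite(ck)
    out$n_pairs[k] <- sum(keep)
    if (sum(keep) >= 2 && stats::sd(c0[keep]) > 0 &&
        stats::sd(ck[keep]) > 0) {
      out$r[k] <- stats::cor(c0[keep], ck[keep])
    }
  }
  out
}

#' Number of referenced windows from successive-window correlation
#'
#' Sequential rule: `N` is the largest `k` such that the lag-`j`
#' correlation exceeds `r_threshold` for every `j <= k - 1`; the current
#' window is always usable, so `N >= 1`, and `N <= max_windows`. When fewer
#' than `min_pairs` complete pairs support the lag-1 correlation the count
#' falls back to 1 with a warning.
#'
#' @inheritParams window_correlation
#' @param wcorr Optional precomputed [window_correlation()] table.
#' @return Integer window count.
#' @export
window_count <- function(cohort, variable, window_size_h,
                         config = ctwh_config(), wcorr = NULL) {
  if (is.null(wcorr)) {
    wcorr <- window_correlation(cohort, variable, window_size_h, config)
  }
  if (nrow(wcorr) == 0) return(1L)
  if (wcorr$n_pairs[1] < config$min_pairs) {
    warning("fewer than ", config$min_pairs, " complete pairs at lag 1 for '",
            variable, "'; window count set to 1", call. = FALSE)
    return(1L)
  }
  n <- 1L
  for (k in seq_len(nrow(wcorr))) {
    if (is.finite(wcorr$r[k]) && wcorr$r[k] > config$r_threshold &&
        wcorr$n_pairs[k] >= config$min_pairs) {
      n <- k + 1L
    } else {
      break
    }
  }
  min(n, config$max_windows)
}

#' Interpolation span
#'
#' The temporal reach of the windowed estimate: window size times window
#' count, e.g. a 10.3 h window referenced over 2 windows spans ~20.6 h.
#'
#' @param window_size_h Window width in hours (> 0).
#' @param n_windows Number of referenced windows (>= 1).
#' @return Span in hours.
#' @export
interpolation_span <- function(window_size_h, n_windows) {
  stopifnot(window_size_h > 0, n_windows >= 1)
  window_size_h * n_windows
}

#' Estimate the full per-variable window configuration
#'
#' Runs the interval-quantile window size, the correlation-based window
#' count and the span rule for every variable retained by the missingness
#' filter. Variables whose windows cannot be estimated (no episode with two
#' observations) are excluded and reported via the `excluded` attribute.
#'
#' @param cohort A `sw_cohort`.
#' @param panel A `sw_panel`; defaults to the cohort's panel.
#' @param config A `sw_ctwh_config`.
#' @return A `sw_windows` tibble: `variable`, `window_size_h`, `n_windows`,
#'   `span_h`, plus a list column `lag_r` of fitted lag correlations used as
#'   merge weights downstream.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_episodes = 30, seed = 1))
#' fit_windows(cohort)
fit_windows <- function(cohort, panel = NULL, config = ctwh_config()) {
  panel <- panel %||% attr(cohort, "panel")
  vars <- retained_variables(cohort, panel)
  rows <- vector("list", length(vars))
  excluded <- character()
  for (i in seq_along(vars)) {
    v <- vars[i]
    hist <- tryCatch(interval_histogram(cohort, v), error = function(e) NULL)
    if (is.null(hist)) {
      excluded <- c(excluded, v)
      next
    }
    w <- window_size(hist, q = config$quantile_q,
                     pooling = config$interval_pooling)
    wc <- window_correlation(cohort, v, w, config)
    n <- suppressWarnings(window_count(cohort, v, w, config, wcorr = wc))
    rows[[i]] <- tibble::tibble(
      variable = v, window_size_h = w, n_windows = n,
      span_h = interpolation_span(w, n),
      lag_r = list(stats::setNames(wc$r, paste0("lag", wcorr_lags(wc))))
    )
  }
  out <- dplyr::bind_rows(rows)
  structure(out, excluded = excluded,
            class = c("sw_windows", class(tibble::tibble())))
}

wcorr_lags <- function(wc) if (nrow(wc) == 0) integer() else wc$lag
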