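#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a per-horizon metrics table
#'
#' One row per (stratum, horizon, metric) with point estimate and, where
#' bootstrapped, confidence bounds.
#'
#' @param x A `sw_metrics` from [evaluate_bank()].
#' @param ... Unused.
#' @return A long tibble `stratum`, `horizon_h`, `metric`, `estimate`,
#'   `conf_low`, `conf_high`.
#' @export
tidy.sw_metrics <- function(x, ...) {
  base <- tibble::as_tibble(x)
  long <- base |>
    tidyr::pivot_longer(
      cols = c("auroc", "auprc", "accuracy", "sensitivity", "specificity",
               "youden", "brier"),
      names_to = "metric", values_to = "estimate")
  long$conf_low <- dplyr::case_when(
    long$metric == "auroc" ~ base$auroc_lo[match(
      paste(long$stratum, long$horizon_h),
      paste(base$stratum, base$horizon_h))],
    long$metric == "auprc" ~ base$auprc_lo[match(
      paste(long$stratum, long$horizon_h),
      paste(base$stratum, base$horizon_h))],
    long$metric == "brier" ~ base$brier_lo[match(
      paste(long$stratum, long$horizon_h),
      paste(base$stratum, base$horizon_h))],
    TRUE ~ NA_real_)
  long$conf_high <- dplyr::case_when(
    long$metric == "auroc" ~ base$auroc_hi[match(
      paste(long$stratum, long$horizon_h),
      paste(base$stratum, base$horizon_h))],
    long$metric == "auprc" ~ base$auprc_hi[match(
      paste(long$stratum, long$horizon_h),
      paste(base$stratum, base$horizon_h))],
    long$metric == "brier" ~ base$brier_hi[match(
      paste(long$stratum, long$horizon_h),
      paste(base$stratum, base$horizon_h))],
    TRUE ~ NA_real_)
  long[, c("stratum", "horizon_h", "metric", "estimate", "conf_low",
           "conf_high")]
}

#' @rdname tidy.sw_metrics
#' @export
glance.sw_metrics <- function(x, ...) {
  tibble::tibble(
    n_horizons = length(unique(x$horizon_h)),
    n_strata = length(unique(x$stratum)),
    auroc_t0 = x$auroc[x$horizon_h == min(x$horizon_h)][1],
    auroc_max = max(x$auroc),
    n_boot = x$n_boot[1]
  )
}

#' Tidy a window configuration
#'
#' @param x A `sw_windows` from [fit_windows()].
#' @param ... Unused.
#' @return Tibble `variable`, `window_size_h`, `n_windows`, `span_h`.
#' @export
tidy.sw_windows <- function(x, ...) {
  tibble::as_tibble(x)[, c("variable", "window_size_h", "n_windows",
                           "span_h")]
}

#' Tidy an attribution report
#'
#' @param x A `sw_attr` from [shapley_attributions()].
#' @param ... Unused.
#' @return Tibble `feature`, `mean_abs_shap`, `mean_shap`, `rank`.
#' @export
tidy.sw_attr <- function(x, ...) tibble::as_tibble(x)

#' Summaries of a fitted booster / model bank
#'
#' @param x A `sw_booster` or `sw_bank`.
#' @param ... Unused.
#' @return One-row tibble of training metadata (per horizon for a bank).
#' @export
glance.sw_booster <- function(x, ...) {
  tibble::tibble(eta = x$report$eta, max_depth = x$report$max_depth,
                 n_rounds = x$report$n_rounds,
                 cv_logloss = x$report$cv_logloss,
                 n_features = length(x$feature_names),
                 schema_hash = x$schema_hash)
}

#' @rdname glance.sw_booster
#' @export
glance.sw_bank <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    row <- tibble::tibble(horizon_h = m$horizon_h, variant = x$variant)
    if (!is.null(m$booster)) {
      row <- dplyr::bind_cols(row, glance(m$booster))
    }
    if (!is.null(m$encoder)) {
      row$encoder_epochs <- m$encoder$report$epochs_run
      row$encoder_val_loss <- m$encoder$report$val_loss
    }
    row
  })
}
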