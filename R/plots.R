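#' Plot per-horizon discrimination with bootstrap ribbons
#'
#' @param object A `sw_metrics` from [evaluate_bank()].
#' @param metric Metric to plot (default `"auroc"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sw_metrics <- function(object, metric = "auroc", ...) {
  df <- tibble::as_tibble(object)
  lo <- paste0(metric, "_lo")
  hi <- paste0(metric, "_hi")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$horizon_h,
                                        y = .data[[metric]],
                                        colour = .data$stratum,
                                        fill = .data$stratum))
  if (lo %in% names(df)) {
    p <- p + ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[lo]],
                                               ymax = .data[[hi]]),
                                  alpha = 0.2, colour = NA)
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse(breaks = unique(df$horizon_h)) +
    ggplot2::labs(x = "Forecast horizon before onset (h)",
                  y = toupper(metric)) +
    ggplot2::theme_minimal()
}

#' Plot top Shapley attributions
#'
#' @param object A `sw_attr`.
#' @param top_n Number of features shown (default 10).
#' @param ... Unused.
#' @return A ggplot bar chart ranked by mean absolute Shapley value;
#'   bar colour encodes the sign of the mean attribution.
#' @export
autoplot.sw_attr <- function(object, top_n = 10, ...) {
  df <- utils::head(tibble::as_tibble(object), top_n)
  df$direction <- ifelse(df$mean_shap >= 0, "risk-increasing",
                         "risk-decreasing")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_abs_shap,
    y = stats::reorder(.data$feature, .data$mean_abs_shap),
    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean |Shapley value|", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an imputed trajectory for one episode and variable
#'
#' Shows the merged hourly estimate with its posterior uncertainty band
#' and the raw observations.
#'
#' @param object A `sw_grids` from [impute_cohort()].
#' @param cohort The source `sw_cohort`.
#' @param episode_id,variable Which trajectory to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sw_grids <- function(object, cohort, episode_id, variable, ...) {
  g <- object[object$episode_id == episode_id &
                object$variable == variable, ]
  obs <- cohort$observations[
    cohort$observations$episode_id == episode_id &
      cohort$observations$variable == variable, ]
  ggplot2::ggplot(g, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - 2 * .data$sd,
                                      ymax = .data$value + 2 * .data$sd),
                         alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(linetype = .data$source == "out_of_span"),
                       show.legend = FALSE) +
    ggplot2::geom_point(data = obs, colour = "red", size = 1) +
    ggplot2::labs(x = "time since admission (h)", y = variable) +
    ggplot2::theme_minimal()
}

#' Plot an alert replay trace
#'
#' @param object A `sw_alerts` from [simulate_alerts()].
#' @param ... Unused.
#' @return A ggplot of score trajectories with alert events marked.
#' @export
autoplot.sw_alerts <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_time_h, y = .data$score,
                                   group = .data$episode_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point(data = df[df$alert, ],
                        ggplot2::aes(colour = .data$tier), size = 2) +
    ggplot2::labs(x = "time before reference (h)", y = "risk score",
                  colour = "tier") +
    ggplot2::theme_minimal()
}
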