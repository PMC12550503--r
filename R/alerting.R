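#' Alert tier schemes
#'
#' Two shipped presets map a risk score in `[0, 1]` to an alert tier:
#' * `"A"` — low `[0.5, 0.6)`, medium `[0.6, 0.8)`, high `[0.8, Inf)`;
#'   intervals closed below, open above.
#' * `"B"` — tier1 `(0.65, Inf)`, tier2 `(0.80, Inf)`, tier3
#'   `(0.90, Inf)`, resolved to the highest matching tier (bounds open
#'   below).
#' Scores below the lowest bound map to `"none"`.
#'
#' @param name `"A"`, `"B"`, or a tibble with columns `tier`, `lower`,
#'   `upper`, `closed_lower` defining a custom scheme.
#' @return A `sw_tier_scheme` tibble ordered by increasing `lower`.
#' @export
tier_scheme <- function(name = "A") {
  if (is.data.frame(name)) {
    sch <- tibble::as_tibble(name)
    lbl <- attr(name, "scheme_name") %||% "custom"
  } else if (identical(name, "A")) {
    sch <- tibble::tibble(
      tier = c("low", "medium", "high"),
      lower = c(0.5, 0.6, 0.8),
      upper = c(0.6, 0.8, Inf),
      closed_lower = TRUE)
    lbl <- "A"
  } else if (identical(name, "B")) {
    sch <- tibble::tibble(
      tier = c("tier1", "tier2", "tier3"),
      lower = c(0.65, 0.80, 0.90),
      upper = Inf,
      closed_lower = FALSE)
    lbl <- "B"
  } else {
    stop("unknown scheme '", name, "'", call. = FALSE)
  }
  if (is.unsorted(sch$lower, strictly = TRUE)) {
    stop("tier lower bounds must be strictly increasing", call. = FALSE)
  }
  structure(sch, scheme_name = lbl,
            class = c("sw_tier_scheme", class(tibble::tibble())))
}

#' Map scores to alert tiers
#'
#' Deterministic interval lookup; overlapping tiers (scheme B) resolve to
#' the highest matching tier; tier is non-decreasing in score.
#'
#' @param score Numeric scores in `[0, 1]` (vectorized).
#' @param scheme A `sw_tier_scheme`.
#' @return Ordered factor with levels `none` < tiers in scheme order.
#' @export
#' @examples
#' map_tier(c(0.55, 0.70, 0.85), tier_scheme("A"))
map_tier <- function(score, scheme = tier_scheme("A")) {
  stopifnot(all(score >= 0 & score <= 1))
  lv <- c("none", scheme$tier)
  out <- rep("none", length(score))
  for (i in seq_len(nrow(scheme))) {
    hit <- if (scheme$closed_lower[i]) {
      score >= scheme$lower[i] & score < scheme$upper[i]
    } else {
      score > scheme$lower[i] & (score < scheme$upper[i] |
                                   is.infinite(scheme$upper[i]))
    }
    out[hit] <- scheme$tier[i]
  }
  factor(out, levels = lv, ordered = TRUE)
}

#' Replay episodes and emit tiered alerts
#'
#' At each hourly step `t` over the final `replay_h` hours before each
#' episode's reference time, the risk score is computed from observations
#' at or before `t` only (the trailing 12 h grid is re-imputed at each
#' step), mapped to a tier, and an alert event is recorded whenever the
#' tier rises above the highest tier seen so far in the episode.
#'
#' The alert score is the T = 0 model's probability for the trailing
#' window ending at `t`; scores from the other horizon models can be
#' obtained with [predict_risk()].
#'
#' @param bank A `sw_bank` containing a horizon-0 model.
#' @param cohort A `sw_cohort`.
#' @param windows,hyper,config Imputation state (as at training time).
#' @param scheme A `sw_tier_scheme` (default preset A).
#' @param step_h Replay step in hours (default 1).
#' @param replay_h Hours of replay before the reference time (default 12).
#' @return A `sw_alerts` tibble: `episode_id`, `time_h`, `rel_time_h`,
#'   `score`, `tier`, `alert` (TRUE when the tier rose).
#' @export
simulate_alerts <- function(bank, cohort, windows, hyper,
                            config = mgp_config(), scheme = tier_scheme("A"),
                            step_h = 1, replay_h = 12) {
  refs <- reference_times(cohort)
  m0 <- bank$models[["0"]]
  if (is.null(m0)) stop("bank has no horizon-0 model", call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(refs))) {
    id <- refs$episode_id[i]
    ref <- refs$reference_time_h[i]
    steps <- seq(ref - replay_h, ref, by = step_h)
    best <- 0L  # index into c(none, tiers)
    lv <- c("none", scheme$tier)
    for (t in steps) {
      cut <- cohort
      keep <- cut$observations$episode_id != id |
        cut$observations$time_h <= t
      cut$observations <- cut$observations[keep, ]
      sub <- cut
      sub$episodes <- sub$episodes[sub$episodes$episode_id == id, ]
      sub$episodes$onset_time_h <-
        ifelse(sub$episodes$label == "septic", t, NA_real_)
      sub$episodes$anchor_time_h <-
        ifelse(sub$episodes$label == "control", t, NA_real_)
      sub$observations <- sub$observations[
        sub$observations$episode_id == id, ]
      sub$interventions <- sub$interventions[
        sub$interventions$episode_id == id, ]
      g <- impute_episode(cut, id, windows, hyper, config,
                          lookback_h = 12, reference_time_h = t)
      g <- structure(g, windows = windows, hyper = hyper, config = config,
                     lookback_h = 12, horizon_h = 0L,
                     class = c("sw_grids", class(tibble::tibble())))
      score <- score_horizon(bank, sub, g, 0)$score
      tier <- map_tier(score, scheme)
      ti <- match(as.character(tier), lv) - 1L
      rows[[length(rows) + 1]] <- tibble::tibble(
        episode_id = id, time_h = t, rel_time_h = t - ref,
        score = score, tier = as.character(tier), alert = ti > best)
      if (ti > best) best <- ti
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, scheme = scheme,
            class = c("sw_alerts", class(tibble::tibble())))
}

#' Lead time of the first qualifying alert
#'
#' Onset time minus the time of the first alert at or above the
#' qualifying tier; `NA` when the episode never alerts at that tier.
#' Calling it on control episodes is an error.
#'
#' @param alerts A `sw_alerts` trace.
#' @param cohort The `sw_cohort` the trace was computed on.
#' @param qualifying_tier Tier label (default `"high"`).
#' @return Tibble `episode_id`, `lead_time_h`.
#' @export
lead_time <- function(alerts, cohort, qualifying_tier = "high") {
  scheme <- attr(alerts, "scheme")
  lv <- c("none", scheme$tier)
  qi <- match(qualifying_tier, lv)
  if (is.na(qi)) stop("unknown tier '", qualifying_tier, "'", call. = FALSE)
  septic <- cohort$episodes[cohort$episodes$label == "septic", ]
  if (nrow(septic) == 0) {
    stop("lead time is defined for septic episodes only", call. = FALSE)
  }
  onset <- stats::setNames(septic$onset_time_h, septic$episode_id)
  a <- alerts[alerts$episode_id %in% septic$episode_id, ]
  a$tier_i <- match(a$tier, lv)
  first <- a[a$tier_i >= qi, ] |>
    dplyr::group_by(.data$episode_id) |>
    dplyr::summarise(t_first = min(.data$time_h), .groups = "drop")
  out <- tibble::tibble(episode_id = septic$episode_id)
  out$lead_time_h <- unname(onset[out$episode_id]) -
    first$t_first[match(out$episode_id, first$episode_id)]
  out
}

#' Cohort lead-time summary
#'
#' Median and interquartile range of the defined lead times, the maximum
#' lead, and the alert sensitivity (fraction of septic episodes with any
#' qualifying alert).
#'
#' @inheritParams lead_time
#' @return One-row tibble.
#' @export
lead_time_summary <- function(alerts, cohort, qualifying_tier = "high") {
  lt <- lead_time(alerts, cohort, qualifying_tier)
  ok <- is.finite(lt$lead_time_h)
  tibble::tibble(
    n_septic = nrow(lt),
    alert_sensitivity = mean(ok),
    median_lead_h = if (any(ok)) stats::median(lt$lead_time_h[ok]) else NA_real_,
    iqr_lo_h = if (any(ok)) unname(stats::quantile(lt$lead_time_h[ok], 0.25)) else NA_real_,
    iqr_hi_h = if (any(ok)) unname(stats::quantile(lt$lead_time_h[ok], 0.75)) else NA_real_,
    max_lead_h = if (any(ok)) max(lt$lead_time_h[ok]) else NA_real_
  )
}

#' Episode-level alert agreement with confirmed labels
#'
#' Binarizes each episode as alert-positive iff it raised any alert at or
#' above the qualifying tier, and computes Cohen's kappa against the
#' confirmed sepsis labels.
#'
#' @inheritParams lead_time
#' @return List with `kappa`, `predicted`, `confirmed` (per episode).
#' @export
alert_agreement <- function(alerts, cohort, qualifying_tier = "high") {
  scheme <- attr(alerts, "scheme")
  lv <- c("none", scheme$tier)
  qi <- match(qualifying_tier, lv)
  pred_tbl <- alerts |>
    dplyr::group_by(.data$episode_id) |>
    dplyr::summarise(pos = any(match(.data$tier, lv) >= qi),
                     .groups = "drop")
  ep <- cohort$episodes
  pred <- as.integer(pred_tbl$pos[match(ep$episode_id,
                                        pred_tbl$episode_id)])
  pred[is.na(pred)] <- 0L
  conf <- as.integer(ep$label == "septic")
  list(kappa = cohens_kappa(pred, conf),
       predicted = stats::setNames(pred, ep$episode_id),
       confirmed = stats::setNames(conf, ep$episode_id))
}

#' Absolute and relative contrast of two outcome rates
#'
#' For baseline rate `rate_a` and intervention rate `rate_b` (percent):
#' absolute reduction `rate_a - rate_b` and relative reduction
#' `100 * (rate_a - rate_b) / rate_a`.
#'
#' @param rate_a,rate_b Rates in percent, `[0, 100]`.
#' @return List `absolute_reduction`, `relative_reduction`.
#' @export
#' @examples
#' outcome_contrast(29.7, 19.6)
outcome_contrast <- function(rate_a, rate_b) {
  stopifnot(rate_a >= 0, rate_a <= 100, rate_b >= 0, rate_b <= 100)
  absolute <- rate_a - rate_b
  if (rate_a == 0) {
    stop("relative reduction undefined for a zero baseline rate",
         call. = FALSE)
  }
  list(absolute_reduction = absolute,
       relative_reduction = 100 * absolute / rate_a)
}
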