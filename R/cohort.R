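#' Assemble and validate a cohort of clinical episodes
#'
#' A cohort bundles three tidy tables:
#' * `episodes`: one row per encounter — `episode_id`, `age_years`, `sex`
#'   (`"male"`/`"female"`), `weight_kg`, `label` (`"septic"`/`"control"`),
#'   `onset_time_h` (defined iff septic) and `anchor_time_h` (the reference
#'   time used for controls; for septic episodes the reference is the onset).
#' * `observations`: long format — `episode_id`, `time_h`, `variable`, `value`.
#' * `interventions`: timed binary therapy events — `episode_id`, `time_h`,
#'   `code`.
#'
#' Validation sorts observations by (`episode_id`, `time_h`, `variable`),
#' checks that septic episodes carry an onset time, drops rows whose variable
#' is not in the panel or whose value breaches the panel's hard physical
#' bounds (collected in the `rejected` attribute), and warns about values
#' outside the plausible range without dropping them.
#'
#' @param episodes,observations,interventions Data frames as described above;
#'   `interventions` may be `NULL`.
#' @param panel A `sw_panel` (default [default_panel()]).
#' @param validate Run validation (default `TRUE`).
#' @return A `sw_cohort` list of tibbles with attributes `panel` and
#'   `rejected` (a tibble of dropped observation rows with a `reason` column).
#' @export
sepsis_cohort <- function(episodes, observations, interventions = NULL,
                          panel = default_panel(), validate = TRUE) {
  episodes <- tibble::as_tibble(episodes)
  observations <- tibble::as_tibble(observations)
  if (is.null(interventions)) {
    interventions <- tibble::tibble(episode_id = character(),
                                    time_h = numeric(), code = character())
  }
  interventions <- tibble::as_tibble(interventions)

  need_ep <- c("episode_id", "age_years", "sex", "weight_kg", "label")
  miss <- setdiff(need_ep, names(episodes))
  if (length(miss) > 0) {
    stop("episodes table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"onset_time_h" %in% names(episodes)) episodes$onset_time_h <- NA_real_
  if (!"anchor_time_h" %in% names(episodes)) episodes$anchor_time_h <- NA_real_
  need_ob <- c("episode_id", "time_h", "variable", "value")
  miss <- setdiff(need_ob, names(observations))
  if (length(miss) > 0) {
    stop("observations table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  episodes$episode_id <- as.character(episodes$episode_id)
  observations$episode_id <- as.character(observations$episode_id)

  rejected <- tibble::tibble(episode_id = character(), time_h = numeric(),
                             variable = character(), value = numeric(),
                             reason = character())
  if (validate) {
    if (anyDuplicated(episodes$episode_id) > 0) {
      stop("episode_id values must be unique", call. = FALSE)
    }
    if (!all(episodes$label %in% c("septic", "control"))) {
      stop("label must be 'septic' or 'control'", call. = FALSE)
    }
    if (!all(episodes$sex %in% c("male", "female"))) {
      stop("sex must be 'male' or 'female'", call. = FALSE)
    }
    bad_onset <- episodes$label == "septic" & !is.finite(episodes$onset_time_h)
    if (any(bad_onset)) {
      stop("septic episodes without onset_time_h: ",
           paste(utils::head(episodes$episode_id[bad_onset], 5),
                 collapse = ", "), call. = FALSE)
    }
    # controls with no explicit anchor fall back to their last observation
    no_anchor <- episodes$label == "control" &
      !is.finite(episodes$anchor_time_h)
    if (any(no_anchor)) {
      last_t <- observations |>
        dplyr::group_by(.data$episode_id) |>
        dplyr::summarise(last_t = max(.data$time_h), .groups = "drop")
      episodes <- dplyr::left_join(episodes, last_t, by = "episode_id")
      episodes$anchor_time_h <- ifelse(no_anchor, episodes$last_t,
                                       episodes$anchor_time_h)
      episodes$last_t <- NULL
    }

    ok_finite <- is.finite(observations$time_h) &
      is.finite(observations$value)
    ok_var <- observations$variable %in% panel$variable
    bounds <- panel[match(observations$variable, panel$variable),
                    c("hard_low", "hard_high",
                      "plausible_low", "plausible_high")]
    ok_hard <- ok_var & ok_finite & observations$value >= bounds$hard_low &
      observations$value <= bounds$hard_high
    ok_hard[is.na(ok_hard)] <- FALSE
    drop <- !(ok_finite & ok_var & ok_hard)
    if (any(drop)) {
      reason <- dplyr::case_when(
        !ok_finite[drop] ~ "non-finite time or value",
        !ok_var[drop] ~ "variable not in panel",
        TRUE ~ "value outside hard physical bounds"
      )
      rejected <- dplyr::bind_cols(observations[drop, need_ob],
                                   tibble::tibble(reason = reason))
      observations <- observations[!drop, ]
      bounds <- bounds[!drop, ]
    }
    implaus <- observations$value < bounds$plausible_low |
      observations$value > bounds$plausible_high
    if (any(implaus, na.rm = TRUE)) {
      warning(sum(implaus, na.rm = TRUE),
              " observation(s) outside the plausible range (kept)",
              call. = FALSE)
    }
    unknown_ep <- !observations$episode_id %in% episodes$episode_id
    if (any(unknown_ep)) {
      stop("observations reference unknown episode ids", call. = FALSE)
    }
    observations <- dplyr::arrange(observations, .data$episode_id,
                                   .data$time_h, .data$variable)
    interventions <- dplyr::arrange(interventions, .data$episode_id,
                                    .data$time_h, .data$code)
  }

  structure(list(episodes = episodes, observations = observations,
                 interventions = interventions),
            panel = panel, rejected = rejected, class = "sw_cohort")
}

#' @export
print.sw_cohort <- function(x, ...) {
  n_sep <- sum(x$episodes$label == "septic")
  cat("<sw_cohort> ", nrow(x$episodes), " episodes (", n_sep, " septic, ",
      nrow(x$episodes) - n_sep, " control), ",
      nrow(x$observations), " observations, ",
      nrow(x$interventions), " intervention events\n", sep = "")
  invisible(x)
}

#' Reference time of each episode
#'
#' Sepsis onset for septic episodes, the control anchor otherwise. All
#' trailing windows, grids and horizon cutoffs are measured back from this
#' time.
#'
#' @param cohort A `sw_cohort`.
#' @return Tibble `episode_id`, `label`, `reference_time_h`.
#' @export
reference_times <- function(cohort) {
  ep <- cohort$episodes
  tibble::tibble(
    episode_id = ep$episode_id, label = ep$label,
    reference_time_h = ifelse(ep$label == "septic", ep$onset_time_h,
                              ep$anchor_time_h)
  )
}

#' Read a cohort from long-format CSV files
#'
#' Files are comma-separated UTF-8 with `.` decimal marks. `events_path`
#' must have columns `episode_id,time_h,variable,value`; `episodes_path`
#' columns `episode_id,age_years,sex,weight_kg,label,onset_time_h` (an
#' optional `anchor_time_h` column is honoured); `interventions_path`
#' columns `episode_id,time_h,code`.
#'
#' Rows with unknown variables, non-numeric values or values outside hard
#' physical bounds are rejected and reported via the cohort's `rejected`
#' attribute and a message.
#'
#' @param events_path,episodes_path,interventions_path CSV paths
#'   (`interventions_path` optional).
#' @param panel A `sw_panel`.
#' @return A validated `sw_cohort`.
#' @export
read_cohort <- function(events_path, episodes_path,
                        interventions_path = NULL, panel = default_panel()) {
  # base read.csv: correctly rounded double parsing, so writing a cohort
  # and reading it back is exact (write_csv emits shortest round-trip form)
  events <- tibble::as_tibble(utils::read.csv(
    events_path, colClasses = c(episode_id = "character",
                                time_h = "numeric",
                                variable = "character",
                                value = "numeric")))
  episodes <- tibble::as_tibble(utils::read.csv(
    episodes_path, colClasses = c(episode_id = "character")))
  interventions <- NULL
  if (!is.null(interventions_path)) {
    interventions <- tibble::as_tibble(utils::read.csv(
      interventions_path, colClasses = c(episode_id = "character",
                                         time_h = "numeric",
                                         code = "character")))
  }
  cohort <- sepsis_cohort(episodes, events, interventions, panel = panel)
  rej <- attr(cohort, "rejected")
  if (nrow(rej) > 0) {
    message(nrow(rej), " observation row(s) rejected; see attr(x, 'rejected')")
  }
  cohort
}

#' Write a cohort to long-format CSV files
#'
#' Row order is deterministic: events by (`episode_id`, `time_h`,
#' `variable`), episodes by `episode_id`, interventions by (`episode_id`,
#' `time_h`, `code`). Together with [read_cohort()] this round-trips a
#' validated cohort exactly.
#'
#' @param cohort A `sw_cohort`.
#' @param dir Output directory (created if absent); files `events.csv`,
#'   `episodes.csv`, `interventions.csv`.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("events.csv", "episodes.csv",
                            "interventions.csv"))
  ev <- dplyr::arrange(cohort$observations, .data$episode_id, .data$time_h,
                       .data$variable)
  ep <- dplyr::arrange(cohort$episodes, .data$episode_id)
  iv <- dplyr::arrange(cohort$interventions, .data$episode_id, .data$time_h,
                       .data$code)
  readr::write_csv(ev, paths[1])
  readr::write_csv(ep, paths[2])
  readr::write_csv(iv, paths[3])
  invisible(paths)
}

#' Keep a subset of episodes
#'
#' Filters all three cohort tables to the given episode ids — the usual way
#' to form train/test splits.
#'
#' @param cohort A `sw_cohort`.
#' @param episode_ids Character vector of ids to keep.
#' @return A `sw_cohort` restricted to those episodes.
#' @export
filter_episodes <- function(cohort, episode_ids) {
  out <- cohort
  out$episodes <- out$episodes[out$episodes$episode_id %in% episode_ids, ]
  out$observations <- out$observations[
    out$observations$episode_id %in% episode_ids, ]
  out$interventions <- out$interventions[
    out$interventions$episode_id %in% episode_ids, ]
  out
}

#' Per-variable episode-level missingness report
#'
#' For each panel variable, the fraction of episodes with no observation of
#' that variable at all. Variables whose missingness strictly exceeds the
#' panel's threshold are flagged for exclusion; a variable missing in exactly
#' the threshold fraction is retained.
#'
#' @param cohort A `sw_cohort`.
#' @param panel A `sw_panel`; defaults to the cohort's panel.
#' @return Tibble `variable`, `n_episodes_missing`, `missingness`, `retained`.
#' @export
missingness_report <- function(cohort, panel = NULL) {
  panel <- panel %||% attr(cohort, "panel")
  n_ep <- nrow(cohort$episodes)
  if (n_ep == 0) stop("cohort has no episodes", call. = FALSE)
  thr <- attr(panel, "missingness_threshold")
  present <- dplyr::distinct(cohort$observations, .data$episode_id,
                             .data$variable)
  counts <- dplyr::count(present, .data$variable, name = "n_present")
  out <- tibble::tibble(variable = panel$variable) |>
    dplyr::left_join(counts, by = "variable") |>
    dplyr::mutate(
      n_present = dplyr::coalesce(.data$n_present, 0L),
      n_episodes_missing = n_ep - .data$n_present,
      missingness = .data$n_episodes_missing / n_ep,
      retained = .data$missingness <= thr
    ) |>
    dplyr::select("variable", "n_episodes_missing", "missingness", "retained")
  out
}

#' Variables surviving the missingness filter
#'
#' @inheritParams missingness_report
#' @return Character vector of retained variable codes.
#' @export
retained_variables <- function(cohort, panel = NULL) {
  rep <- missingness_report(cohort, panel)
  rep$variable[rep$retained]
}
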