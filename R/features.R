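#' Assemble a supervised dataset for one forecast horizon
#'
#' For horizon `T`, each episode contributes one row whose features use only
#' information up to the cutoff `reference_time - T` (onset minus `T` for
#' septic episodes, anchor minus `T` for controls): the model answers "will
#' onset occur `T` hours after this cutoff?".
#'
#' * `mode = "tabular"`: per dynamic variable the last value, mean, min,
#'   max and least-squares slope over the trailing 12 h of imputed grid,
#'   plus static features (`age_years`, `sex_male`, `weight_kg`) and binary
#'   any-before-cutoff intervention indicators.
#' * `mode = "sequence"`: the hourly 13-point-by-variable grid tensor for
#'   the recurrent encoder (static features carried alongside).
#'
#' @param cohort A `sw_cohort`.
#' @param grids A `sw_grids` from [impute_cohort()] (lookback of at least
#'   `12 + horizon_h` hours).
#' @param horizon_h Integer horizon in `0..12`.
#' @param mode `"tabular"` or `"sequence"`.
#' @return A `sw_horizon` object: for tabular, a tibble with `episode_id`,
#'   `label` and feature columns; for sequence, a list with array
#'   `x` (episode x time x variable), `static`, `label`, `episode_id`.
#'   Both carry `horizon_h` as an attribute.
#' @export
assemble_horizon <- function(cohort, grids, horizon_h,
                             mode = c("tabular", "sequence")) {
  mode <- match.arg(mode)
  if (!(horizon_h %in% 0:12)) {
    stop("horizon_h must be an integer in 0..12", call. = FALSE)
  }
  # grids imputed at the horizon cutoff itself (impute_horizons) carry
  # their horizon; a retrospective grid (impute_cohort) carries 0 and the
  # window is shifted back accordingly
  g_h <- attr(grids, "horizon_h") %||% 0L
  shift <- horizon_h - g_h
  if (shift < 0) {
    stop("grids were imputed at horizon ", g_h,
         "; cannot assemble the later horizon ", horizon_h, call. = FALSE)
  }
  lookback <- attr(grids, "lookback_h") %||% max(-grids$rel_time_h)
  if (lookback < shift + 12) {
    stop("grids cover only ", lookback, " h; horizon ", horizon_h,
         " needs ", shift + 12, call. = FALSE)
  }
  # trailing 12 h window ending at the cutoff, relative to the grid's
  # own reference time
  lo <- -(shift + 12)
  hi <- -shift
  win <- grids[grids$rel_time_h >= lo - 1e-9 & grids$rel_time_h <= hi + 1e-9, ]
  vars <- sort(unique(win$variable))

  ep <- cohort$episodes
  refs <- reference_times(cohort)
  static <- tibble::tibble(
    episode_id = ep$episode_id,
    age_years = ep$age_years,
    sex_male = as.numeric(ep$sex == "male"),
    weight_kg = ep$weight_kg
  )
  cutoff <- refs$reference_time_h - horizon_h
  iv <- cohort$interventions
  iv_flags <- purrr::map_dfc(intervention_codes(), function(code) {
    hit <- iv[iv$code == code, ]
    got <- vapply(seq_along(refs$episode_id), function(i) {
      any(hit$episode_id == refs$episode_id[i] & hit$time_h <= cutoff[i])
    }, logical(1))
    stats::setNames(tibble::tibble(as.numeric(got)), paste0("any_", code))
  })
  static <- dplyr::bind_cols(static, iv_flags)
  labels <- tibble::tibble(episode_id = refs$episode_id,
                           label = as.integer(refs$label == "septic"))

  if (mode == "sequence") {
    ids <- ep$episode_id
    n_t <- 13L
    x <- array(0, dim = c(length(ids), n_t, length(vars)),
               dimnames = list(ids, NULL, vars))
    win <- dplyr::arrange(win, .data$episode_id, .data$variable,
                          .data$rel_time_h)
    for (v in vars) {
      wv <- win[win$variable == v, ]
      m <- matrix(wv$value, nrow = n_t)
      colnames(m) <- unique(wv$episode_id)
      x[colnames(m), , v] <- t(m)
    }
    out <- list(x = x, static = static[match(ids, static$episode_id), ],
                label = labels$label[match(ids, labels$episode_id)],
                episode_id = ids)
    return(structure(out, horizon_h = horizon_h, mode = "sequence",
                     class = "sw_horizon_seq"))
  }

  summ <- win |>
    dplyr::group_by(.data$episode_id, .data$variable) |>
    dplyr::arrange(.data$rel_time_h, .by_group = TRUE) |>
    dplyr::summarise(
      last = dplyr::last(.data$value),
      mean = mean(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      slope = {
        tt <- .data$rel_time_h - mean(.data$rel_time_h)
        if (sum(tt^2) > 0) sum(tt * (.data$value - mean(.data$value))) /
          sum(tt^2) else 0
      },
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "variable",
                       values_from = c("last", "mean", "min", "max", "slope"),
                       names_glue = "{variable}_{.value}")
  out <- labels |>
    dplyr::left_join(static, by = "episode_id") |>
    dplyr::left_join(summ, by = "episode_id")
  feat_cols <- setdiff(names(out), c("episode_id", "label"))
  structure(out, horizon_h = horizon_h, mode = "tabular",
            feature_names = feat_cols,
            class = c("sw_horizon", class(tibble::tibble())))
}

#' Stratified episode-disjoint cross-validation folds
#'
#' @param dataset A `sw_horizon` tabular dataset (or any tibble with
#'   `episode_id` and binary `label`).
#' @param k Number of folds (default 5).
#' @param seed Integer seed; assignment is deterministic given it.
#' @return Tibble `episode_id`, `label`, `fold`.
#' @export
make_folds <- function(dataset, k = 5, seed = 1) {
  lab <- dataset$label
  if (any(table(lab) < k)) {
    stop("every class needs at least k = ", k, " episodes", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(nrow(dataset))
  for (cl in unique(lab)) {
    idx <- which(lab == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  tibble::tibble(episode_id = dataset$episode_id, label = lab, fold = fold)
}
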