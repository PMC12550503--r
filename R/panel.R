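#' The default 28-variable dynamic feature panel
#'
#' Returns the panel of dynamic clinical variables the pipeline models:
#' core vital signs (heart rate, respiratory rate, blood pressures,
#' temperature, oxygen saturation), blood-gas and metabolic markers
#' (pH, lactate, base deficit, glucose, pCO2, pO2-related indices),
#' haematology and chemistry (WBC, platelets, haemoglobin, haematocrit,
#' creatinine, bilirubin, albumin, potassium, calcium-adjacent markers),
#' coagulation (INR, fibrinogen) and the Glasgow Coma Scale.
#'
#' Each variable carries two ranges:
#' * `plausible_low`/`plausible_high` — the physiologically plausible band;
#'   values outside it are loaded with a warning (they occur in real EHRs).
#' * `hard_low`/`hard_high` — physical impossibility bounds; rows outside
#'   them are rejected at read time.
#'
#' @param missingness_threshold Episode-level missingness fraction above which
#'   a variable is excluded from modelling (strictly greater than; default 0.20).
#' @return A `sw_panel` tibble with columns `variable`, `unit`,
#'   `plausible_low`, `plausible_high`, `hard_low`, `hard_high`, `dynamic`.
#' @export
#' @examples
#' default_panel()
default_panel <- function(missingness_threshold = 0.20) {
  spec <- tibble::tribble(
    ~variable, ~unit,      ~plausible_low, ~plausible_high, ~hard_low, ~hard_high,
    "T",       "degC",     34,    42,    20,   47,
    "R",       "breaths/min", 10, 90,    0,    250,
    "HR",      "beats/min",   50, 230,   0,    400,
    "MAP",     "mmHg",     25,    130,   0,    300,
    "DBP",     "mmHg",     20,    110,   0,    300,
    "SBP",     "mmHg",     40,    180,   0,    350,
    "INR",     "ratio",    0.6,   8,     0,    20,
    "WBC",     "10^9/L",   0.5,   60,    0,    500,
    "TB",      "umol/L",   1,     400,   0,    1000,
    "Cr",      "umol/L",   8.84,  309.4, 0,    2000,
    "LAC",     "mmol/L",   0.3,   18,    0,    40,
    "PLT",     "10^9/L",   5,     900,   0,    3000,
    "CRP",     "mg/L",     0,     300,   0,    1000,
    "SO2",     "%",        60,    100,   0,    100,
    "ALB",     "g/L",      15,    60,    0,    100,
    "HCT",     "%",        15,    65,    0,    100,
    "PCO2",    "mmHg",     15,    110,   0,    250,
    "ALP",     "U/L",      20,    1200,  0,    5000,
    "HGB",     "g/L",      40,    220,   0,    300,
    "K",       "mmol/L",   2,     8,     0,    15,
    "BSD",     "mmol/L",   -30,   15,    -50,  50,
    "AC",      "mmol/L",   0.5,   3.5,   0,    10,
    "GCS",     "score",    3,     15,    3,    15,
    "DBIL",    "umol/L",   0,     200,   0,    600,
    "FIB",     "g/L",      0.5,   10,    0,    20,
    "AST",     "U/L",      5,     2000,  0,    20000,
    "PH",      "unitless", 7.10,  7.55,  6.0,  8.0,
    "BG",      "mmol/L",   1,     30,    0,    100
  )
  spec$dynamic <- TRUE
  feature_panel(spec, missingness_threshold = missingness_threshold)
}

#' Construct a feature panel
#'
#' @param variables Tibble with columns `variable`, `unit`, `plausible_low`,
#'   `plausible_high`, `hard_low`, `hard_high` and optionally `dynamic`
#'   (defaults to `TRUE`).
#' @inheritParams default_panel
#' @return A validated `sw_panel` tibble.
#' @export
feature_panel <- function(variables, missingness_threshold = 0.20) {
  stopifnot(is.data.frame(variables))
  need <- c("variable", "unit", "plausible_low", "plausible_high",
            "hard_low", "hard_high")
  miss <- setdiff(need, names(variables))
  if (length(miss) > 0) {
    stop("panel is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  variables <- tibble::as_tibble(variables)
  if (!"dynamic" %in% names(variables)) variables$dynamic <- TRUE
  if (anyDuplicated(variables$variable) > 0) {
    stop("panel variable codes must be unique", call. = FALSE)
  }
  if (any(variables$plausible_low >= variables$plausible_high)) {
    stop("plausible_low must be < plausible_high for every variable",
         call. = FALSE)
  }
  if (any(variables$hard_low > variables$plausible_low) ||
      any(variables$hard_high < variables$plausible_high)) {
    stop("hard bounds must contain the plausible range", call. = FALSE)
  }
  if (!is.numeric(missingness_threshold) || missingness_threshold < 0 ||
      missingness_threshold > 1) {
    stop("missingness_threshold must be a fraction in [0, 1]", call. = FALSE)
  }
  structure(variables,
            missingness_threshold = missingness_threshold,
            class = c("sw_panel", class(tibble::tibble())))
}

#' Recognised intervention event codes
#'
#' Timed binary therapy events recorded alongside the dynamic panel:
#' antibiotics, vasopressors, glucocorticoids and mechanical ventilation.
#' @return Character vector of codes.
#' @export
intervention_codes <- function() {
  c("antibiotics", "vasopressors", "glucocorticoids", "mechanical_ventilation")
}

#' Window-estimation (CTWH) configuration
#'
#' Parameters of the continuous time-window histogram stage: the
#' inter-measurement interval quantile that sets the per-variable window
#' size, the correlation threshold and maximum lag for the window count,
#' and the grid step of the imputation lattice.
#'
#' @param quantile_q Quantile of pooled inter-observation intervals used as
#'   the window size (default 0.70).
#' @param r_threshold Pearson correlation above which a lagged window is
#'   considered temporally continuous with the reference window (default 0.6).
#' @param max_windows Maximum number of referenced windows (default 4).
#' @param grid_step_h Imputation grid step in hours (default 1).
#' @param min_pairs Minimum complete window pairs required to estimate a lag
#'   correlation; below it the window count falls back to 1 with a warning
#'   (default 10).
#' @param interval_pooling `"pooled"` pools all within-episode intervals
#'   across the cohort before taking the quantile; `"per_episode_median"`
#'   takes per-episode medians first.
#' @return A list of class `sw_ctwh_config`.
#' @export
ctwh_config <- function(quantile_q = 0.70, r_threshold = 0.6, max_windows = 4,
                        grid_step_h = 1.0, min_pairs = 10,
                        interval_pooling = c("pooled", "per_episode_median")) {
  interval_pooling <- match.arg(interval_pooling)
  if (!(quantile_q > 0 && quantile_q < 1)) {
    stop("quantile_q must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!(r_threshold > 0 && r_threshold < 1)) {
    stop("r_threshold must lie strictly in (0, 1)", call. = FALSE)
  }
  if (max_windows < 1) stop("max_windows must be >= 1", call. = FALSE)
  structure(list(quantile_q = quantile_q, r_threshold = r_threshold,
                 max_windows = as.integer(max_windows),
                 grid_step_h = grid_step_h, min_pairs = as.integer(min_pairs),
                 interval_pooling = interval_pooling),
            class = "sw_ctwh_config")
}

#' Read / write panel + window configuration as YAML
#'
#' A single YAML file carries the feature panel and the CTWH parameters so a
#' run is reproducible from one config artefact.
#'
#' @param path File path.
#' @return `read_panel_config()` returns `list(panel, ctwh)`.
#' @export
read_panel_config <- function(path) {
  raw <- yaml::read_yaml(path)
  panel <- feature_panel(
    tibble::as_tibble(lapply(as.data.frame(do.call(
      rbind, lapply(raw$panel$variables, as.data.frame)
    )), unlist)),
    missingness_threshold = raw$panel$missingness_threshold %||% 0.20
  )
  ctwh <- do.call(ctwh_config, raw$ctwh %||% list())
  list(panel = panel, ctwh = ctwh)
}

#' @rdname read_panel_config
#' @param panel A `sw_panel`.
#' @param ctwh A `sw_ctwh_config`.
#' @export
write_panel_config <- function(panel, ctwh, path) {
  out <- list(
    panel = list(
      missingness_threshold = attr(panel, "missingness_threshold"),
      variables = lapply(seq_len(nrow(panel)), function(i) as.list(panel[i, ]))
    ),
    ctwh = unclass(ctwh)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
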