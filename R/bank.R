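#' Gradient-boosting configuration
#'
#' Hyperparameters are chosen by k-fold cross-validation over a small grid,
#' with early stopping at 10 rounds; the final model is refit on all
#' training data at the selected settings and round count.
#'
#' @param learning_rates,max_depths Grid searched by CV.
#' @param n_rounds_max Maximum boosting rounds (default 200).
#' @param early_stopping_rounds Early-stopping patience in rounds
#'   (default 10).
#' @param cv_folds Cross-validation folds (default 5).
#' @param scale_pos_weight Positive-class weight (default 1; no reweighting).
#' @param seed Integer seed; training runs single-threaded for determinism.
#' @return A list of class `sw_boost_config`.
#' @export
boost_config <- function(learning_rates = c(0.05, 0.1, 0.3),
                         max_depths = c(3, 4, 6), n_rounds_max = 200,
                         early_stopping_rounds = 10, cv_folds = 5,
                         scale_pos_weight = 1, seed = 1) {
  stopifnot(early_stopping_rounds >= 1, cv_folds >= 2)
  structure(list(learning_rates = learning_rates, max_depths = max_depths,
                 n_rounds_max = n_rounds_max,
                 early_stopping_rounds = as.integer(early_stopping_rounds),
                 cv_folds = as.integer(cv_folds),
                 scale_pos_weight = scale_pos_weight,
                 seed = as.integer(seed)),
            class = "sw_boost_config")
}

# resolve a single grid or a per-horizon list of grids
.grids_for <- function(grids, horizon_h) {
  if (inherits(grids, "sw_grids")) return(grids)
  g <- grids[[as.character(horizon_h)]]
  if (is.null(g)) {
    stop("no grids available for horizon ", horizon_h, call. = FALSE)
  }
  g
}

.horizon_matrix <- function(dataset) {
  feats <- attr(dataset, "feature_names")
  x <- as.matrix(dataset[, feats, drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = dataset$label, feature_names = feats)
}

#' Train the gradient-boosted classifier
#'
#' @param x Feature matrix, or a tabular `sw_horizon` dataset (then `y` is
#'   taken from its `label` column).
#' @param y Binary labels (0/1); ignored when `x` is a `sw_horizon`.
#' @param config A `sw_boost_config`.
#' @return A `sw_booster`: the fitted xgboost model plus feature schema
#'   (names + hash) and a CV report (grid results, chosen settings,
#'   stopping round).
#' @export
train_boosted <- function(x, y = NULL, config = boost_config()) {
  if (inherits(x, "sw_horizon")) {
    hm <- .horizon_matrix(x)
    x <- hm$x; y <- hm$y
  }
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  set.seed(config$seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  grid <- expand.grid(eta = config$learning_rates,
                      max_depth = config$max_depths)
  grid$logloss <- NA_real_
  grid$best_round <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    set.seed(config$seed)
    cv <- xgboost::xgb.cv(
      params = list(objective = "binary:logistic", eta = grid$eta[i],
                    max_depth = grid$max_depth[i], nthread = 1,
                    scale_pos_weight = config$scale_pos_weight,
                    eval_metric = "logloss"),
      data = dtrain, nrounds = config$n_rounds_max,
      nfold = config$cv_folds, stratified = TRUE,
      early_stopping_rounds = config$early_stopping_rounds, verbose = 0)
    log <- cv$evaluation_log
    grid$best_round[i] <- which.min(log$test_logloss_mean)
    grid$logloss[i] <- min(log$test_logloss_mean)
  }
  best <- which.min(grid$logloss)
  set.seed(config$seed)
  model <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = grid$eta[best],
                  max_depth = grid$max_depth[best], nthread = 1,
                  scale_pos_weight = config$scale_pos_weight),
    data = dtrain, nrounds = grid$best_round[best], verbose = 0)
  schema <- colnames(x)
  structure(list(model = model, feature_names = schema,
                 schema_hash = .schema_hash(schema),
                 report = list(grid = tibble::as_tibble(grid),
                               eta = grid$eta[best],
                               max_depth = grid$max_depth[best],
                               n_rounds = grid$best_round[best],
                               cv_logloss = grid$logloss[best],
                               seed = config$seed)),
            class = "sw_booster")
}

.schema_hash <- function(feature_names) {
  # order-sensitive polynomial rolling hash of the schema string
  s <- paste(feature_names, collapse = "|")
  h <- 0
  for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 2147483647
  sprintf("%010d", h)
}

#' Predict probabilities from a trained booster
#'
#' @param object A `sw_booster`.
#' @param newdata Feature matrix or tabular `sw_horizon`; columns are
#'   checked against the training schema.
#' @param ... Unused.
#' @return Probabilities in `[0, 1]`.
#' @export
predict.sw_booster <- function(object, newdata, ...) {
  if (inherits(newdata, "sw_horizon")) newdata <- .horizon_matrix(newdata)$x
  if (!identical(colnames(newdata), object$feature_names)) {
    if (all(object$feature_names %in% colnames(newdata))) {
      newdata <- newdata[, object$feature_names, drop = FALSE]
    } else {
      stop("feature schema mismatch between model and data", call. = FALSE)
    }
  }
  stats::predict(object$model,
                 xgboost::xgb.DMatrix(newdata, nthread = 1))
}

#' Train the bank of horizon-specific models
#'
#' One model per forecast horizon. Variants:
#' * `"tabular_boosted"` — gradient boosting on windowed summary features;
#' * `"sequence_recurrent"` — the recurrent encoder's logistic head alone;
#' * `"hybrid_embedding"` — recurrent embeddings concatenated with static
#'   features, fed to the boosted classifier.
#'
#' @param cohort A `sw_cohort` (training split).
#' @param grids Either a named list of per-horizon `sw_grids` from
#'   [impute_horizons()] (strictly causal; recommended) or a single
#'   retrospective `sw_grids` covering at least `12 + max(horizons)` hours.
#' @param horizons Integer horizons (default `0:12`, i.e. 13 models).
#' @param variant Model variant (see above).
#' @param boost A `sw_boost_config`.
#' @param encoder_args List of arguments passed to
#'   [train_recurrent_encoder()] for the recurrent variants.
#' @return A `sw_bank`: per-horizon models with schema hashes and training
#'   reports.
#' @export
build_bank <- function(cohort, grids, horizons = 0:12,
                       variant = c("tabular_boosted", "sequence_recurrent",
                                   "hybrid_embedding"),
                       boost = boost_config(), encoder_args = list()) {
  variant <- match.arg(variant)
  models <- vector("list", length(horizons))
  names(models) <- as.character(horizons)
  for (i in seq_along(horizons)) {
    h <- horizons[i]
    g <- .grids_for(grids, h)
    if (variant == "tabular_boosted") {
      ds <- assemble_horizon(cohort, g, h, mode = "tabular")
      models[[i]] <- list(horizon_h = h, booster = train_boosted(ds, config = boost),
                          encoder = NULL)
    } else {
      sq <- assemble_horizon(cohort, g, h, mode = "sequence")
      enc <- do.call(train_recurrent_encoder,
                     c(list(seqdata = sq), encoder_args))
      if (variant == "sequence_recurrent") {
        models[[i]] <- list(horizon_h = h, booster = NULL, encoder = enc)
      } else {
        emb <- encode_sequences(enc, sq)
        static <- as.matrix(sq$static[, -1])
        xx <- cbind(emb, static)
        models[[i]] <- list(horizon_h = h,
                            booster = train_boosted(xx, sq$label,
                                                    config = boost),
                            encoder = enc)
      }
    }
  }
  structure(list(models = models, horizons = horizons, variant = variant),
            class = "sw_bank")
}

#' @export
print.sw_bank <- function(x, ...) {
  cat("<sw_bank> ", length(x$models), " horizon model(s) [",
      paste(range(x$horizons), collapse = "-"), " h], variant ",
      x$variant, "\n", sep = "")
  invisible(x)
}

#' Score a cohort with one horizon model
#'
#' @param bank A `sw_bank`.
#' @param cohort,grids Evaluation cohort and its imputed grids.
#' @param horizon_h Horizon to score.
#' @return Tibble `episode_id`, `label`, `horizon_h`, `score`.
#' @export
score_horizon <- function(bank, cohort, grids, horizon_h) {
  m <- bank$models[[as.character(horizon_h)]]
  if (is.null(m)) stop("no model for horizon ", horizon_h, call. = FALSE)
  grids <- .grids_for(grids, horizon_h)
  if (bank$variant == "tabular_boosted") {
    ds <- assemble_horizon(cohort, grids, horizon_h, mode = "tabular")
    score <- predict(m$booster, ds)
    ids <- ds$episode_id; lab <- ds$label
  } else {
    sq <- assemble_horizon(cohort, grids, horizon_h, mode = "sequence")
    if (bank$variant == "sequence_recurrent") {
      score <- predict_encoder(m$encoder, sq)
    } else {
      emb <- encode_sequences(m$encoder, sq)
      xx <- cbind(emb, as.matrix(sq$static[, -1]))
      score <- predict(m$booster, xx)
    }
    ids <- sq$episode_id; lab <- sq$label
  }
  tibble::tibble(episode_id = ids, label = lab, horizon_h = horizon_h,
                 score = as.numeric(score))
}

#' Risk trace: every applicable horizon model scored at a time point
#'
#' Scores an episode at wall-clock time `t_now` using only observations at
#' or before `t_now`: the trailing window grid is re-imputed with
#' `t_now` as reference, and each horizon model `T` in the bank emits the
#' probability that onset occurs `T` hours after `t_now`.
#'
#' @param bank A `sw_bank`.
#' @param cohort A `sw_cohort`.
#' @param episode_id Episode to score.
#' @param t_now Time in hours.
#' @param windows,hyper,config Imputation state as used at training time.
#' @return Tibble `episode_id`, `t_now`, `horizon_h`, `score`.
#' @export
predict_risk <- function(bank, cohort, episode_id, t_now, windows, hyper,
                         config = mgp_config()) {
  # censor: only observations at or before t_now are visible
  cut <- cohort
  keep <- cut$observations$episode_id != episode_id |
    cut$observations$time_h <= t_now
  cut$observations <- cut$observations[keep, ]
  sub <- cut
  sub$episodes <- sub$episodes[sub$episodes$episode_id == episode_id, ]
  sub$observations <- sub$observations[
    sub$observations$episode_id == episode_id, ]
  sub$interventions <- sub$interventions[
    sub$interventions$episode_id == episode_id, ]
  # every model reads the trailing window [t_now - 12, t_now]: impute once
  # at t_now, then present it to model T as the grid at T's own cutoff
  g0 <- impute_episode(cut, episode_id, windows, hyper, config,
                       lookback_h = 12, reference_time_h = t_now)
  purrr::map_dfr(bank$horizons, function(h) {
    shifted <- sub
    shifted$episodes$onset_time_h <-
      ifelse(shifted$episodes$label == "septic", t_now + h, NA_real_)
    shifted$episodes$anchor_time_h <-
      ifelse(shifted$episodes$label == "control", t_now + h, NA_real_)
    g <- structure(g0, windows = windows, hyper = hyper, config = config,
                   lookback_h = 12, horizon_h = as.integer(h),
                   class = c("sw_grids", class(tibble::tibble())))
    sc <- score_horizon(bank, shifted, g, h)
    tibble::tibble(episode_id = episode_id, t_now = t_now, horizon_h = h,
                   score = sc$score)
  }) |>
    dplyr::arrange(.data$horizon_h)
}
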