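#' Shapley feature attributions for a fitted model
#'
#' For gradient-boosted models the exact tree-path decomposition is used
#' (per-instance contributions plus base value reproduce the margin
#' exactly). For arbitrary prediction functions — e.g. the encoder-hybrid
#' pipeline — a sampling estimator over random feature permutations is
#' used, with missing features replaced by background draws; its local
#' accuracy holds in expectation with Monte-Carlo error shrinking as
#' `nsim` grows.
#'
#' @param model A `sw_booster`, or any function `f(matrix) -> numeric`.
#' @param features Feature matrix (or tabular `sw_horizon`) to explain.
#' @param background Background matrix for the sampling estimator
#'   (defaults to `features`).
#' @param nsim Permutations per instance for the sampling estimator
#'   (default 100).
#' @param seed Integer seed (sampling estimator only).
#' @return A `sw_attr` tibble — per feature: `mean_abs_shap`, `mean_shap`,
#'   `rank` — with the per-instance matrix in attribute `shap` and the
#'   per-instance base values in attribute `base`.
#' @export
shapley_attributions <- function(model, features, background = NULL,
                                 nsim = 100, seed = 1) {
  if (inherits(features, "sw_horizon")) {
    features <- .horizon_matrix(features)$x
  }
  if (inherits(model, "sw_booster")) {
    if (!identical(colnames(features), model$feature_names)) {
      if (all(model$feature_names %in% colnames(features))) {
        features <- features[, model$feature_names, drop = FALSE]
      } else {
        stop("feature schema mismatch between model and data",
             call. = FALSE)
      }
    }
    contrib <- stats::predict(model$model,
                              xgboost::xgb.DMatrix(features, nthread = 1),
                              predcontrib = TRUE)
    base <- contrib[, ncol(contrib)]
    shap <- contrib[, -ncol(contrib), drop = FALSE]
  } else if (is.function(model)) {
    background <- background %||% features
    shap <- .sampling_shap(model, features, background, nsim, seed)
    base <- rep(mean(model(background)), nrow(features))
  } else {
    stop("model must be a sw_booster or a prediction function",
         call. = FALSE)
  }
  out <- tibble::tibble(
    feature = colnames(shap),
    mean_abs_shap = colMeans(abs(shap)),
    mean_shap = colMeans(shap)
  ) |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_shap)) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(out, shap = shap, base = base,
            class = c("sw_attr", class(tibble::tibble())))
}

# permutation-sampling Shapley values for a black-box prediction function
.sampling_shap <- function(f, x, background, nsim, seed) {
  set.seed(seed)
  n <- nrow(x); d <- ncol(x)
  shap <- matrix(0, n, d, dimnames = list(NULL, colnames(x)))
  for (s in seq_len(nsim)) {
    perm <- sample.int(d)
    bg <- background[sample.int(nrow(background), n, replace = TRUE), ,
                     drop = FALSE]
    cur <- bg
    prev_val <- f(cur)
    for (j in perm) {
      cur[, j] <- x[, j]
      new_val <- f(cur)
      shap[, j] <- shap[, j] + (new_val - prev_val)
      prev_val <- new_val
    }
  }
  shap / nsim
}
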