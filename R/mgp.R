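#' Multivariate Gaussian-process imputation configuration
#'
#' @param kernel Temporal kernel: `"exponential"` (Ornstein-Uhlenbeck;
#'   default — physiologic signals are rough) or `"squared_exponential"`.
#' @param task_rank Rank of the low-rank cross-variable covariance
#'   (default 5).
#' @param noise_floor Lower bound on the observation noise variance on the
#'   standardized scale (default 1e-4).
#' @param jitter Initial diagonal jitter; escalates tenfold up to 1e-2
#'   before failing (default 1e-6).
#' @param max_opt_iter Iteration cap for the marginal-likelihood optimizer
#'   (default 50).
#' @param merge_weight_mode `"correlation"` scales the fixed weight by the
#'   windowed estimate's non-empty-window fraction; `"fixed"` uses
#'   `fixed_weight` as-is.
#' @param fixed_weight Base weight of the windowed (CTWH) estimate in the
#'   convex merge (default 0.5).
#' @param n_fit_episodes Episodes subsampled for hyperparameter fitting
#'   (default 10).
#' @return A list of class `sw_mgp_config`.
#' @export
mgp_config <- function(kernel = c("exponential", "squared_exponential"),
                       task_rank = 5, noise_floor = 1e-4, jitter = 1e-6,
                       max_opt_iter = 50,
                       merge_weight_mode = c("correlation", "fixed"),
                       fixed_weight = 0.5, n_fit_episodes = 10) {
  kernel <- match.arg(kernel)
  merge_weight_mode <- match.arg(merge_weight_mode)
  stopifnot(task_rank >= 1, jitter > 0, noise_floor > 0,
            fixed_weight >= 0, fixed_weight <= 1)
  structure(list(kernel = kernel, task_rank = as.integer(task_rank),
                 noise_floor = noise_floor, jitter = jitter,
                 max_opt_iter = as.integer(max_opt_iter),
                 merge_weight_mode = merge_weight_mode,
                 fixed_weight = fixed_weight,
                 n_fit_episodes = as.integer(n_fit_episodes)),
            class = "sw_mgp_config")
}

# temporal kernel on length-scale-mapped inputs u = t / l
.kern <- function(u1, u2, kernel) {
  d <- abs(outer(u1, u2, "-"))
  if (kernel == "exponential") exp(-d) else exp(-0.5 * d^2)
}

# full covariance between point sets: signal * B[v,v'] * k(u, u')
.mgp_cov <- function(u1, v1, u2, v2, B, s2, kernel) {
  s2 * B[cbind(rep(v1, times = length(v2)),
               rep(v2, each = length(v1)))] *
    .kern(u1, u2, kernel)
}

#' Population-level MGP hyperparameters
#'
#' Standardization moments come from the whole cohort. The cross-variable
#' (task) covariance is a rank-`task_rank` spectral approximation of the
#' empirical between-variable correlation of per-episode variable means,
#' completed with a diagonal. The scalar signal and noise variances are then
#' set by maximizing the summed log marginal likelihood over a subsample of
#' episodes (L-BFGS-B on log-variances). Per-variable length scales equal
#' each variable's estimated window size, coupling the imputation to the
#' windowing stage.
#'
#' @param cohort A `sw_cohort`.
#' @param windows A `sw_windows` from [fit_windows()].
#' @param config A `sw_mgp_config`.
#' @param seed Seed for the episode subsample (default 1).
#' @return A list of class `sw_mgp_hyper` with elements `mu`, `sd`,
#'   `median` (per-variable), `B`, `length_scale_h`, `s2`, `noise`,
#'   `kernel`.
#' @export
mgp_hyperparameters <- function(cohort, windows, config = mgp_config(),
                                seed = 1) {
  vars <- windows$variable
  obs <- cohort$observations[cohort$observations$variable %in% vars, ]
  stats_tbl <- obs |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(mu = mean(.data$value),
                     sd = stats::sd(.data$value),
                     med = stats::median(.data$value), .groups = "drop")
  stats_tbl <- stats_tbl[match(vars, stats_tbl$variable), ]
  sd_v <- pmax(stats_tbl$sd, 1e-8)

  # empirical task correlation from per-episode variable means
  em <- obs |>
    dplyr::group_by(.data$episode_id, .data$variable) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "m")
  em <- as.matrix(em[, vars[vars %in% names(em)], drop = FALSE])
  R <- suppressWarnings(stats::cor(em, use = "pairwise.complete.obs"))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  full <- matrix(0, length(vars), length(vars),
                 dimnames = list(vars, vars))
  diag(full) <- 1
  full[colnames(R), colnames(R)] <- R
  r <- min(config$task_rank, length(vars))
  eg <- eigen((full + t(full)) / 2, symmetric = TRUE)
  keep <- seq_len(r)
  lam <- pmax(eg$values[keep], 0)
  W <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam), r)
  d <- pmax(0.05, 1 - rowSums(W^2))
  B <- W %*% t(W) + diag(d)
  Dh <- 1 / sqrt(diag(B))
  B <- B * outer(Dh, Dh)          # renormalize to unit diagonal
  dimnames(B) <- list(vars, vars)

  ls_h <- stats::setNames(windows$window_size_h, vars)

  # episode subsample for the scalar-variance fit
  set.seed(seed)
  ids <- cohort$episodes$episode_id
  ids <- sample(ids, min(config$n_fit_episodes, length(ids)))
  refs <- reference_times(cohort)
  train <- lapply(ids, function(id) {
    .episode_span_obs(cohort, id, windows,
                      refs$reference_time_h[refs$episode_id == id])
  })
  train <- Filter(function(d) nrow(d) >= 3, train)

  nll <- function(par) {
    s2 <- exp(par[1]); noise <- exp(par[2]) + config$noise_floor
    total <- 0
    for (d in train) {
      u <- d$time_h / ls_h[d$variable]
      vi <- match(d$variable, vars)
      y <- (d$value - stats_tbl$mu[vi]) / sd_v[vi]
      K <- .mgp_cov(u, vi, u, vi, B, s2, config$kernel)
      diag(K) <- diag(K) + noise + config$jitter
      ch <- tryCatch(chol(K), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      alpha <- backsolve(ch, forwardsolve(t(ch), y))
      total <- total + 0.5 * sum(y * alpha) + sum(log(diag(ch)))
    }
    total
  }
  opt <- stats::optim(c(log(1), log(0.1)), nll, method = "L-BFGS-B",
                      control = list(maxit = config$max_opt_iter))
  structure(list(variables = vars, mu = stats::setNames(stats_tbl$mu, vars),
                 sd = stats::setNames(sd_v, vars),
                 median = stats::setNames(stats_tbl$med, vars),
                 B = B, length_scale_h = ls_h,
                 s2 = exp(opt$par[1]),
                 noise = exp(opt$par[2]) + config$noise_floor,
                 kernel = config$kernel),
            class = "sw_mgp_hyper")
}

# observations of one episode restricted to each variable's span before ref
.episode_span_obs <- function(cohort, episode_id, windows, reference_time_h) {
  obs <- cohort$observations[cohort$observations$episode_id == episode_id &
                               cohort$observations$variable %in%
                               windows$variable, ]
  span <- stats::setNames(windows$span_h, windows$variable)
  back <- reference_time_h - obs$time_h
  keep <- back >= 0 & back <= span[obs$variable]
  obs[keep, ]
}

#' Fit the multivariate GP posterior for one episode
#'
#' Conditions the population-level MGP (see [mgp_hyperparameters()]) on the
#' episode's observations, restricted per variable to the window-config
#' span before the reference time. Values are standardized per variable; a
#' zero-mean GP with low-rank task covariance and a per-variable
#' length-scale-mapped temporal kernel is used. When the covariance is
#' numerically singular the jitter escalates tenfold up to 1e-2 before
#' failing; with zero usable observations the returned state carries a
#' fallback flag (downstream cells get the population median).
#'
#' @param cohort A `sw_cohort`.
#' @param episode_id Episode to fit.
#' @param windows A `sw_windows`.
#' @param hyper A `sw_mgp_hyper`.
#' @param config A `sw_mgp_config`.
#' @param reference_time_h Override for the episode reference time
#'   (default: onset/anchor).
#' @return A list of class `sw_mgp_posterior`.
#' @export
fit_mgp <- function(cohort, episode_id, windows, hyper,
                    config = mgp_config(), reference_time_h = NULL) {
  refs <- reference_times(cohort)
  ref <- reference_time_h %||%
    refs$reference_time_h[refs$episode_id == episode_id]
  if (length(ref) != 1 || !is.finite(ref)) {
    stop("no reference time for episode '", episode_id, "'", call. = FALSE)
  }
  d <- .episode_span_obs(cohort, episode_id, windows, ref)
  if (nrow(d) == 0) {
    return(structure(list(episode_id = episode_id, reference_time_h = ref,
                          fallback = TRUE, hyper = hyper, config = config,
                          windows = windows),
                     class = "sw_mgp_posterior"))
  }
  vars <- hyper$variables
  vi <- match(d$variable, vars)
  u <- d$time_h / hyper$length_scale_h[d$variable]
  y <- (d$value - hyper$mu[d$variable]) / hyper$sd[d$variable]
  K <- .mgp_cov(u, vi, u, vi, hyper$B, hyper$s2, hyper$kernel)
  diag(K) <- diag(K) + hyper$noise
  jit <- config$jitter
  ch <- NULL
  while (is.null(ch) && jit <= 1e-2) {
    ch <- tryCatch(chol(K + diag(jit, nrow(K))), error = function(e) NULL)
    if (is.null(ch)) jit <- jit * 10
  }
  if (is.null(ch)) {
    stop("singular covariance after jitter escalation for episode '",
         episode_id, "'", call. = FALSE)
  }
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  structure(list(episode_id = episode_id, reference_time_h = ref,
                 fallback = FALSE, times = d$time_h, u = u, vi = vi,
                 variables = d$variable, chol = ch, alpha = alpha,
                 hyper = hyper, config = config, windows = windows),
            class = "sw_mgp_posterior")
}

#' Posterior mean and uncertainty of a fitted episode MGP
#'
#' @param object A `sw_mgp_posterior` from [fit_mgp()].
#' @param times Query times in hours.
#' @param variable Single variable code.
#' @param ... Unused.
#' @return List with `mean` and `sd` on the original variable scale.
#' @export
predict.sw_mgp_posterior <- function(object, times, variable, ...) {
  pr <- .mgp_predict(object, times, variable)
  hyper <- object$hyper
  list(mean = pr$mean * hyper$sd[[variable]] + hyper$mu[[variable]],
       sd = pr$sd * hyper$sd[[variable]])
}

# posterior mean/sd of the latent function at (times, variable), z-scale
.mgp_predict <- function(post, times, variable) {
  hyper <- post$hyper
  vq <- match(variable, hyper$variables)
  uq <- times / hyper$length_scale_h[variable]
  prior_var <- hyper$s2 * diag(hyper$B)[vq]
  if (isTRUE(post$fallback)) {
    return(list(mean = rep(0, length(times)), sd = sqrt(prior_var)))
  }
  Kx <- hyper$s2 *
    matrix(hyper$B[vq, post$vi], nrow = length(uq), ncol = length(post$u),
           byrow = TRUE) *
    .kern(uq, post$u, hyper$kernel)
  mean_std <- as.numeric(Kx %*% post$alpha)
  Vh <- forwardsolve(t(post$chol), t(Kx))
  var_std <- pmax(0, prior_var - colSums(Vh^2))
  list(mean = mean_std, sd = sqrt(var_std))
}

#' Correlation-weighted windowed (CTWH) estimate at a time point
#'
#' Averages the per-window means of the `N` referenced windows ending at
#' `t`, weighting window `k` by its fitted lag correlation (`r_0 = 1`,
#' negative correlations clipped to zero). The returned `weight` is the
#' fraction of referenced windows that contained any observation; with all
#' windows empty the value is undefined (`NA`) and the weight 0.
#'
#' @param cohort A `sw_cohort`.
#' @param episode_id Episode id.
#' @param variable Panel variable code.
#' @param windows A `sw_windows` containing the variable.
#' @param t Time (hours) at which to estimate.
#' @return List with `value` and `weight`.
#' @export
ctwh_estimate <- function(cohort, episode_id, variable, windows, t) {
  row <- windows[windows$variable == variable, ]
  if (nrow(row) != 1) {
    stop("variable '", variable, "' has no window configuration",
         call. = FALSE)
  }
  obs <- cohort$observations[cohort$observations$episode_id == episode_id &
                               cohort$observations$variable == variable, ]
  res <- .ctwh_estimate_vec(obs$time_h, obs$value, row$window_size_h,
                            row$n_windows, row$lag_r[[1]], t)
  list(value = res$value[1], weight = res$weight[1])
}

# vectorized windowed estimate over several query times
.ctwh_estimate_vec <- function(obs_t, obs_v, W, N, lag_r, times) {
  wts <- c(1, pmax(0, lag_r))[seq_len(N)]
  wts[!is.finite(wts)] <- 0
  m <- matrix(NA_real_, length(times), N)
  for (k in seq_len(N)) {
    for (i in seq_along(times)) {
      inw <- obs_t >= times[i] - k * W & obs_t < times[i] - (k - 1) * W
      if (any(inw)) m[i, k] <- mean(obs_v[inw])
    }
  }
  nonempty <- is.finite(m)
  wmat <- matrix(wts, length(times), N, byrow = TRUE) * nonempty
  wsum <- rowSums(wmat)
  value <- rowSums(wmat * ifelse(nonempty, m, 0)) / ifelse(wsum > 0, wsum, NA)
  list(value = ifelse(wsum > 0, value, NA_real_),
       weight = rowMeans(nonempty))
}

#' Merge the GP and windowed estimates for one grid cell
#'
#' Convex combination `lambda * ctwh + (1 - lambda) * mgp` with
#' `lambda = ctwh_weight * fixed_weight` in `"correlation"` mode or
#' `lambda = fixed_weight` in `"fixed"` mode. Falls back to whichever
#' source is defined; with both undefined the caller substitutes the
#' population median.
#'
#' @param mgp_value GP posterior mean (or `NA`).
#' @param ctwh_value Windowed estimate (or `NA`).
#' @param ctwh_weight Non-empty-window fraction from [ctwh_estimate()].
#' @param config A `sw_mgp_config`.
#' @return List with `value`, `lambda`, `source` (one of `"ctwh_merge"`,
#'   `"mgp"`, `"ctwh"`, `"undefined"`).
#' @export
merge_estimates <- function(mgp_value, ctwh_value, ctwh_weight,
                            config = mgp_config()) {
  mgp_ok <- is.finite(mgp_value)
  ctwh_ok <- is.finite(ctwh_value) && ctwh_weight > 0
  if (!mgp_ok && !ctwh_ok) {
    return(list(value = NA_real_, lambda = NA_real_, source = "undefined"))
  }
  if (!mgp_ok) return(list(value = ctwh_value, lambda = 1, source = "ctwh"))
  if (!ctwh_ok) return(list(value = mgp_value, lambda = 0, source = "mgp"))
  lambda <- if (config$merge_weight_mode == "correlation") {
    ctwh_weight * config$fixed_weight
  } else {
    config$fixed_weight
  }
  list(value = lambda * ctwh_value + (1 - lambda) * mgp_value,
       lambda = lambda, source = "ctwh_merge")
}

#' Impute one episode onto a regular hourly grid
#'
#' @param cohort A `sw_cohort`.
#' @param episode_id Episode id.
#' @param windows A `sw_windows`.
#' @param hyper A `sw_mgp_hyper`.
#' @param config A `sw_mgp_config`.
#' @param lookback_h Grid depth in hours before the reference time
#'   (default 24, so every 0-12 h horizon has a full trailing 12 h window).
#' @param reference_time_h Optional reference-time override.
#' @return Tibble `episode_id`, `time_h`, `rel_time_h`, `variable`,
#'   `value`, `sd`, `source` with source flags `observed`, `ctwh_merge`,
#'   `mgp`, `ctwh`, `out_of_span`, `median_fallback`.
#' @export
impute_episode <- function(cohort, episode_id, windows, hyper,
                           config = mgp_config(), lookback_h = 24,
                           reference_time_h = NULL) {
  post <- fit_mgp(cohort, episode_id, windows, hyper, config,
                  reference_time_h = reference_time_h)
  ref <- post$reference_time_h
  grid <- seq(ref - lookback_h, ref, by = 1)
  ep_obs <- cohort$observations[
    cohort$observations$episode_id == episode_id, ]
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    v <- windows$variable[i]
    span <- windows$span_h[i]
    back <- ref - grid
    in_span <- back <= span
    value <- rep(hyper$median[v], length(grid))
    sdv <- rep(NA_real_, length(grid))
    src <- rep("out_of_span", length(grid))
    if (any(in_span) && !isTRUE(post$fallback)) {
      pr <- .mgp_predict(post, grid[in_span], v)
      mgp_val <- pr$mean * hyper$sd[v] + hyper$mu[v]
      sd_val <- pr$sd * hyper$sd[v]
      vo0 <- ep_obs[ep_obs$variable == v, ]
      cw <- .ctwh_estimate_vec(vo0$time_h, vo0$value, windows$window_size_h[i],
                               windows$n_windows[i], windows$lag_r[[i]],
                               grid[in_span])
      merged <- mapply(function(mv, cv, cwgt) {
        m <- merge_estimates(mv, cv, cwgt, config)
        c(m$value,
          match(m$source, c("ctwh_merge", "mgp", "ctwh", "undefined")))
      }, mgp_val, cw$value, cw$weight)
      val_in <- merged[1, ]
      src_in <- c("ctwh_merge", "mgp", "ctwh", "undefined")[merged[2, ]]
      und <- src_in == "undefined"
      val_in[und] <- hyper$median[v]
      src_in[und] <- "median_fallback"
      value[in_span] <- val_in
      sdv[in_span] <- sd_val
      src[in_span] <- src_in
    } else if (any(in_span)) {
      src[in_span] <- "median_fallback"
      sdv[in_span] <- sqrt(hyper$s2 * diag(hyper$B)[match(v, hyper$variables)]) *
        hyper$sd[v]
    }
    vo <- ep_obs[ep_obs$variable == v, ]
    if (nrow(vo) > 0) {
      near <- vapply(grid, function(t) {
        any(abs(vo$time_h - t) <= 0.5) }, logical(1))
      src[near & in_span & src != "median_fallback"] <- "observed"
    }
    out[[i]] <- tibble::tibble(episode_id = episode_id, time_h = grid,
                               rel_time_h = grid - ref, variable = v,
                               value = value, sd = sdv, source = src)
  }
  dplyr::bind_rows(out)
}

#' Impute every episode in a cohort
#'
#' Runs [mgp_hyperparameters()] once (population level) and
#' [impute_episode()] per episode.
#'
#' @inheritParams impute_episode
#' @param hyper Optional precomputed `sw_mgp_hyper`.
#' @param seed Seed for hyperparameter episode subsampling.
#' @return A `sw_grids` tibble with attributes `windows`, `hyper`,
#'   `config`, `lookback_h`.
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_spec(n_episodes = 12, seed = 7))
#' windows <- fit_windows(cohort)
#' grids <- impute_cohort(cohort, windows)
#' }
impute_cohort <- function(cohort, windows, config = mgp_config(),
                          hyper = NULL, lookback_h = 24, seed = 1) {
  hyper <- hyper %||% mgp_hyperparameters(cohort, windows, config,
                                          seed = seed)
  ids <- cohort$episodes$episode_id
  grids <- purrr::map_dfr(ids, function(id) {
    impute_episode(cohort, id, windows, hyper, config,
                   lookback_h = lookback_h)
  })
  structure(grids, windows = windows, hyper = hyper, config = config,
            lookback_h = lookback_h, horizon_h = 0L,
            class = c("sw_grids", class(tibble::tibble())))
}

#' Impute strictly causal per-horizon grids
#'
#' For forecast horizon `T` the grid of each episode is re-imputed with the
#' horizon cutoff (`reference - T`) as its reference time, so only
#' observations at or before the cutoff condition the posterior — the
#' causality the horizon models require. [impute_cohort()] by contrast
#' smooths each episode once, retrospectively, around its reference time;
#' use that for visualization, and these grids for training and
#' evaluation.
#'
#' @inheritParams impute_cohort
#' @param horizons Integer horizons (default `0:12`).
#' @return Named list of `sw_grids` (one per horizon, lookback 12 h, each
#'   tagged with its horizon).
#' @export
impute_horizons <- function(cohort, windows, config = mgp_config(),
                            hyper = NULL, horizons = 0:12, seed = 1) {
  hyper <- hyper %||% mgp_hyperparameters(cohort, windows, config,
                                          seed = seed)
  refs <- reference_times(cohort)
  ids <- cohort$episodes$episode_id
  # pre-split each episode into a one-episode cohort to keep inner loops
  # free of whole-cohort scans
  minis <- lapply(ids, function(id) {
    m <- cohort
    m$episodes <- m$episodes[m$episodes$episode_id == id, ]
    m$observations <- m$observations[m$observations$episode_id == id, ]
    m$interventions <- m$interventions[
      m$interventions$episode_id == id, ]
    m
  })
  names(minis) <- ids
  out <- lapply(horizons, function(h) {
    g <- purrr::map_dfr(seq_along(ids), function(i) {
      ref <- refs$reference_time_h[refs$episode_id == ids[i]]
      impute_episode(minis[[i]], ids[i], windows, hyper, config,
                     lookback_h = 12, reference_time_h = ref - h)
    })
    structure(g, windows = windows, hyper = hyper, config = config,
              lookback_h = 12, horizon_h = as.integer(h),
              class = c("sw_grids", class(tibble::tibble())))
  })
  names(out) <- as.character(horizons)
  out
}
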