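# Gated recurrent unit encoder, implemented directly with base matrix ops.
# Full-batch Adam, binary cross-entropy on a logistic head over the final
# hidden state, manual backpropagation through time. Desk-scale by design:
# hundreds of episodes x 13 timesteps x ~30 variables.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.gru_init <- function(d_in, hidden, n_layers, seed) {
  set.seed(seed)
  layers <- vector("list", n_layers)
  d <- d_in
  for (l in seq_len(n_layers)) {
    s_w <- sqrt(1 / d)
    s_u <- sqrt(1 / hidden)
    layers[[l]] <- list(
      Wz = matrix(stats::rnorm(d * hidden, 0, s_w), d, hidden),
      Wr = matrix(stats::rnorm(d * hidden, 0, s_w), d, hidden),
      Wn = matrix(stats::rnorm(d * hidden, 0, s_w), d, hidden),
      Uz = matrix(stats::rnorm(hidden * hidden, 0, s_u), hidden, hidden),
      Ur = matrix(stats::rnorm(hidden * hidden, 0, s_u), hidden, hidden),
      Un = matrix(stats::rnorm(hidden * hidden, 0, s_u), hidden, hidden),
      bz = rep(0, hidden), br = rep(0, hidden), bn = rep(0, hidden)
    )
    d <- hidden
  }
  list(layers = layers,
       w_out = stats::rnorm(hidden, 0, sqrt(1 / hidden)),
       b_out = 0)
}

# forward pass; returns caches for backprop and the final hidden state
.gru_forward <- function(params, x) {
  n <- dim(x)[1]; Tn <- dim(x)[2]
  caches <- vector("list", length(params$layers))
  inp <- lapply(seq_len(Tn), function(t) x[, t, , drop = TRUE])
  inp <- lapply(inp, function(m) if (is.null(dim(m))) matrix(m, n) else m)
  for (l in seq_along(params$layers)) {
    p <- params$layers[[l]]
    hidden <- length(p$bz)
    h <- matrix(0, n, hidden)
    cache <- vector("list", Tn)
    out <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      X <- inp[[t]]
      z <- .sigmoid(sweep(X %*% p$Wz + h %*% p$Uz, 2, p$bz, "+"))
      r <- .sigmoid(sweep(X %*% p$Wr + h %*% p$Ur, 2, p$br, "+"))
      rh <- r * h
      nn <- tanh(sweep(X %*% p$Wn + rh %*% p$Un, 2, p$bn, "+"))
      h_new <- (1 - z) * nn + z * h
      cache[[t]] <- list(X = X, h_prev = h, z = z, r = r, n = nn, rh = rh)
      h <- h_new
      out[[t]] <- h
    }
    caches[[l]] <- cache
    inp <- out
  }
  list(h_final = inp[[length(inp)]], caches = caches, seq_out = inp)
}

.gru_backward <- function(params, fw, dh_final) {
  n_layers <- length(params$layers)
  Tn <- length(fw$caches[[1]])
  grads <- lapply(params$layers, function(p) lapply(p, function(m) m * 0))
  # gradient arriving at each layer's output sequence
  dseq <- lapply(seq_len(Tn), function(t) dh_final * 0)
  dseq[[Tn]] <- dh_final
  for (l in rev(seq_len(n_layers))) {
    p <- params$layers[[l]]
    cache <- fw$caches[[l]]
    g <- grads[[l]]
    dh <- dseq[[Tn]] * 0
    dx_seq <- vector("list", Tn)
    for (t in rev(seq_len(Tn))) {
      dh <- dh + dseq[[t]]
      cc <- cache[[t]]
      dz <- dh * (cc$h_prev - cc$n)
      dn <- dh * (1 - cc$z)
      dan <- dn * (1 - cc$n^2)
      daz <- dz * cc$z * (1 - cc$z)
      drh <- dan %*% t(p$Un)
      dr <- drh * cc$h_prev
      dar <- dr * cc$r * (1 - cc$r)
      g$Wz <- g$Wz + t(cc$X) %*% daz
      g$Wr <- g$Wr + t(cc$X) %*% dar
      g$Wn <- g$Wn + t(cc$X) %*% dan
      g$Uz <- g$Uz + t(cc$h_prev) %*% daz
      g$Ur <- g$Ur + t(cc$h_prev) %*% dar
      g$Un <- g$Un + t(cc$rh) %*% dan
      g$bz <- g$bz + colSums(daz)
      g$br <- g$br + colSums(dar)
      g$bn <- g$bn + colSums(dan)
      dx_seq[[t]] <- daz %*% t(p$Wz) + dar %*% t(p$Wr) + dan %*% t(p$Wn)
      dh <- dh * cc$z + drh * cc$r + daz %*% t(p$Uz) + dar %*% t(p$Ur)
    }
    grads[[l]] <- g
    dseq <- dx_seq
  }
  grads
}

.flatten_params <- function(params) {
  c(unlist(lapply(params$layers, unlist), use.names = FALSE),
    params$w_out, params$b_out)
}

#' Train the recurrent sequence encoder
#'
#' A stacked gated-recurrent-unit network (default two layers of 64 hidden
#' units) with a logistic output head, trained full-batch with Adam on
#' binary cross-entropy. Early stopping monitors the loss on a stratified
#' 20% holdout with the given patience; the returned weights are those of
#' the best epoch. Inputs are standardized per variable (moments stored for
#' prediction). Training is deterministic given the seed.
#'
#' @param seqdata A `sw_horizon_seq` from
#'   `assemble_horizon(..., mode = "sequence")`.
#' @param hidden_units Hidden units per layer (default 64).
#' @param n_layers Number of stacked layers (default 2).
#' @param max_epochs Maximum training epochs (default 100).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param learning_rate Adam step size (default 0.01).
#' @param holdout Fraction held out for early stopping (default 0.2).
#' @param seed Integer seed.
#' @return A `sw_encoder` with weights, standardization moments and a
#'   training report (`epochs_run`, `best_epoch`, `train_loss`,
#'   `val_loss`, `train_accuracy`).
#' @export
train_recurrent_encoder <- function(seqdata, hidden_units = 64, n_layers = 2,
                                    max_epochs = 100, patience = 10,
                                    learning_rate = 0.01, holdout = 0.2,
                                    seed = 1) {
  x <- seqdata$x
  y <- seqdata$label
  if (length(unique(y)) < 2) {
    stop("training split needs both classes", call. = FALSE)
  }
  d_in <- dim(x)[3]
  center <- apply(x, 3, mean)
  scale <- pmax(apply(x, 3, stats::sd), 1e-8)
  for (j in seq_len(d_in)) x[, , j] <- (x[, , j] - center[j]) / scale[j]

  set.seed(seed)
  n <- dim(x)[1]
  val_idx <- integer()
  for (cl in unique(y)) {
    idx <- which(y == cl)
    val_idx <- c(val_idx, sample(idx, max(1, round(holdout * length(idx)))))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  params <- .gru_init(d_in, hidden_units, n_layers, seed)

  adam_m <- rapply(params, function(v) v * 0, how = "replace")
  adam_v <- rapply(params, function(v) v * 0, how = "replace")
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0

  bce <- function(p, yy) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(yy * log(p) + (1 - yy) * log(1 - p))
  }
  predict_probs <- function(pp, xx) {
    fw <- .gru_forward(pp, xx)
    as.numeric(.sigmoid(fw$h_final %*% pp$w_out + pp$b_out))
  }

  best <- list(loss = Inf, params = params, epoch = 0)
  history <- numeric(0)
  wait <- 0
  x_tr <- x[tr_idx, , , drop = FALSE]
  y_tr <- y[tr_idx]
  x_val <- x[val_idx, , , drop = FALSE]
  y_val <- y[val_idx]

  for (epoch in seq_len(max_epochs)) {
    fw <- .gru_forward(params, x_tr)
    logits <- as.numeric(fw$h_final %*% params$w_out + params$b_out)
    p <- .sigmoid(logits)
    dlogit <- (p - y_tr) / length(y_tr)
    d_wout <- as.numeric(t(fw$h_final) %*% dlogit)
    d_bout <- sum(dlogit)
    dh_final <- outer(dlogit, params$w_out)
    grads <- .gru_backward(params, fw, dh_final)
    gall <- list(layers = grads, w_out = d_wout, b_out = d_bout)

    step <- step + 1
    upd <- function(p, m, v, g) {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      mh <- m / (1 - b1^step); vh <- v / (1 - b2^step)
      list(p = p - learning_rate * mh / (sqrt(vh) + eps), m = m, v = v)
    }
    for (l in seq_along(params$layers)) {
      for (nm in names(params$layers[[l]])) {
        r <- upd(params$layers[[l]][[nm]], adam_m$layers[[l]][[nm]],
                 adam_v$layers[[l]][[nm]], gall$layers[[l]][[nm]])
        params$layers[[l]][[nm]] <- r$p
        adam_m$layers[[l]][[nm]] <- r$m
        adam_v$layers[[l]][[nm]] <- r$v
      }
    }
    r <- upd(params$w_out, adam_m$w_out, adam_v$w_out, gall$w_out)
    params$w_out <- r$p; adam_m$w_out <- r$m; adam_v$w_out <- r$v
    r <- upd(params$b_out, adam_m$b_out, adam_v$b_out, gall$b_out)
    params$b_out <- r$p; adam_m$b_out <- r$m; adam_v$b_out <- r$v

    val_loss <- bce(predict_probs(params, x_val), y_val)
    if (!is.finite(val_loss)) {
      stop("non-finite validation loss at epoch ", epoch, call. = FALSE)
    }
    history <- c(history, val_loss)
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  p_tr <- predict_probs(best$params, x_tr)
  structure(list(
    params = best$params, center = center, scale = scale,
    hidden_units = hidden_units, n_layers = n_layers,
    variables = dimnames(seqdata$x)[[3]],
    report = list(epochs_run = length(history), best_epoch = best$epoch,
                  val_loss = best$loss,
                  train_loss = bce(p_tr, y_tr),
                  train_accuracy = mean((p_tr >= 0.5) == y_tr),
                  val_history = history, seed = seed)
  ), class = "sw_encoder")
}

#' Encode sequences into embeddings
#'
#' @param encoder A `sw_encoder`.
#' @param seqdata A `sw_horizon_seq`.
#' @return Matrix (episodes x hidden_units) of final-layer hidden states,
#'   with episode ids as row names.
#' @export
encode_sequences <- function(encoder, seqdata) {
  x <- seqdata$x
  for (j in seq_len(dim(x)[3])) {
    x[, , j] <- (x[, , j] - encoder$center[j]) / encoder$scale[j]
  }
  fw <- .gru_forward(encoder$params, x)
  emb <- fw$h_final
  rownames(emb) <- seqdata$episode_id
  colnames(emb) <- paste0("emb_", seq_len(ncol(emb)))
  emb
}

#' Predict sepsis probability with the encoder's logistic head
#'
#' @inheritParams encode_sequences
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_encoder <- function(encoder, seqdata) {
  emb <- encode_sequences(encoder, seqdata)
  as.numeric(.sigmoid(emb %*% encoder$params$w_out + encoder$params$b_out))
}
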