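#' Network training configuration
#'
#' Hyperparameters of the three-layer feedforward injury network. The
#' defaults follow the study settings: at most 10,000 training epochs, a
#' learning rate of 0.3, and training stops once the epoch mean squared
#' error, measured on the AIS ordinal-code scale, reaches 0.01.
#'
#' @param n_hidden Hidden units (default 8).
#' @param learning_rate Gradient step size (default 0.3).
#' @param max_epochs Maximum training epochs (default 10000).
#' @param target_error Mean-squared-error stopping threshold, measured
#'   on the AIS ordinal-code scale — the units the network predicts
#'   (default 0.01).
#' @param seed Integer seed for weight initialization.
#' @return A list of class `net_config`.
#' @export
net_config <- function(n_hidden = 8L, learning_rate = 0.3,
                       max_epochs = 10000L, target_error = 0.01,
                       seed = 1L) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  if (max_epochs < 1L) stop("`max_epochs` must be at least 1")
  if (target_error <= 0) stop("`target_error` must be positive")
  structure(
    list(
      n_hidden = as.integer(n_hidden),
      learning_rate = learning_rate,
      max_epochs = as.integer(max_epochs),
      target_error = target_error,
      seed = as.integer(seed)
    ),
    class = "net_config"
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# min-max scaler with a zero-range guard
fit_scaler <- function(x) {
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant feature maps to 0, not NaN
  list(lo = lo, rng = rng)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$lo, "-"), 2L, scaler$rng, "/")
}

features_from_conditions <- function(data) {
  required <- c("delta_v", "belted", "deploy_time")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  cbind(
    delta_v = as.numeric(data$delta_v),
    belted = as.numeric(data$belted),
    deploy_time = as.numeric(data$deploy_time)
  )
}

#' Train the head/chest AIS prediction network
#'
#' Fits a three-layer feedforward network (3 inputs, one sigmoid hidden
#' layer, 2 sigmoid outputs) mapping the crash condition — delta-v, belt
#' state, airbag deployment time — to head and chest AIS severity. The
#' inputs are min-max scaled to `[0, 1]`; the ordinal AIS codes 1..5 are
#' scaled to `[0, 1]` targets so each output is a scalar ordinal
#' regression. Training is classic incremental backpropagation on the
#' squared error: one pass per epoch over the rows in a seeded random
#' order, updating after each row, until the epoch mean squared error —
#' reported on the AIS-code scale, the units the network predicts —
#' reaches the target error, or the epoch cap is hit. Deterministic
#' given the config seed.
#'
#' @param data Data frame with columns `delta_v`, `belted`,
#'   `deploy_time`, `head_ais`, `chest_ais` (ordinal codes 1..5), as
#'   produced by [generate_training_set()].
#' @param config A [net_config()].
#' @return An object of class `ais_net`: scaler parameters, weight
#'   matrices `W1` (3 x h), `W2` (h x 2), biases `b1`, `b2`, the config,
#'   and a training log (data frame of epoch and MSE for the logged
#'   epochs plus the final one).
#' @export
train_ais_net <- function(data, config = net_config()) {
  stopifnot(inherits(config, "net_config"))
  X_raw <- features_from_conditions(data)
  if (!all(c("head_ais", "chest_ais") %in% names(data))) {
    stop("missing column(s): head_ais, chest_ais")
  }
  if (nrow(unique(as.data.frame(X_raw))) < 2L) {
    stop("need at least 2 distinct training conditions")
  }
  Tmat <- cbind(
    head = (ais_code(data$head_ais) - 1) / 4,
    chest = (ais_code(data$chest_ais) - 1) / 4
  )
  scaler <- fit_scaler(X_raw)
  X <- apply_scaler(X_raw, scaler)

  n <- nrow(X)
  h <- config$n_hidden
  set.seed(config$seed)
  W1 <- matrix(runif(3L * h, -0.5, 0.5), nrow = 3L)
  b1 <- runif(h, -0.5, 0.5)
  W2 <- matrix(runif(h * 2L, -0.5, 0.5), nrow = h)
  b2 <- runif(2L, -0.5, 0.5)
  lr <- config$learning_rate

  log_epochs <- integer(0)
  log_errors <- numeric(0)
  final_mse <- NA_real_
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    for (i in ord) {
      xi <- X[i, ]
      hid <- sigmoid(drop(xi %*% W1) + b1)
      out <- sigmoid(drop(hid %*% W2) + b2)
      err <- out - Tmat[i, ]
      delta_out <- err * out * (1 - out)
      delta_hid <- (W2 %*% delta_out)[, 1L] * hid * (1 - hid)
      W2 <- W2 - lr * tcrossprod(hid, delta_out)
      b2 <- b2 - lr * delta_out
      W1 <- W1 - lr * tcrossprod(xi, delta_hid)
      b1 <- b1 - lr * delta_hid
    }
    H <- sigmoid(sweep(X %*% W1, 2L, b1, "+"))
    Y <- sigmoid(sweep(H %*% W2, 2L, b2, "+"))
    # epoch MSE on the AIS-code scale (targets span 4 code units)
    mse <- mean((4 * (Y - Tmat))^2)
    if (!is.finite(mse)) stop("training diverged: non-finite loss")
    if (epoch == 1L || epoch %% 100L == 0L || mse <= config$target_error) {
      log_epochs <- c(log_epochs, epoch)
      log_errors <- c(log_errors, mse)
    }
    final_mse <- mse
    if (mse <= config$target_error) break
  }
  if (log_epochs[length(log_epochs)] != epoch) {
    log_epochs <- c(log_epochs, epoch)
    log_errors <- c(log_errors, final_mse)
  }

  structure(
    list(
      scaler = scaler,
      W1 = unname(W1), b1 = unname(b1),
      W2 = unname(W2), b2 = unname(b2),
      config = config,
      training_log = data.frame(epoch = log_epochs, mse = log_errors)
    ),
    class = "ais_net"
  )
}

#' @export
print.ais_net <- function(x, ...) {
  tl <- x$training_log
  cat(sprintf(
    "<ais_net> 3-%d-2 sigmoid network; stopped at epoch %d, MSE %.4g\n",
    ncol(x$W1), tl$epoch[nrow(tl)], tl$mse[nrow(tl)]
  ))
  invisible(x)
}

#' Predict head and chest AIS for crash conditions
#'
#' Forward pass of a trained [train_ais_net()] model. The continuous
#' sigmoid outputs in `[0, 1]` are returned as severity scores; bands
#' are obtained by unscaling to the ordinal axis (`score * 4 + 1`),
#' rounding to the nearest code with exact halves rounded upward
#' (severity-conservative) and clamping to 1..5.
#'
#' @param model A trained `ais_net`.
#' @param newdata Data frame with columns `delta_v`, `belted`,
#'   `deploy_time`.
#' @return A data frame with columns `head_score`, `chest_score` (both
#'   in `[0, 1]`), `head_ais`, `chest_ais` (ordinal codes 1..5).
#' @export
predict_ais <- function(model, newdata) {
  if (!inherits(model, "ais_net") || is.null(model$W1)) {
    stop("`model` must be a trained ais_net")
  }
  X <- apply_scaler(features_from_conditions(newdata), model$scaler)
  H <- sigmoid(sweep(X %*% model$W1, 2L, model$b1, "+"))
  Y <- sigmoid(sweep(H %*% model$W2, 2L, model$b2, "+"))
  to_band <- function(score) {
    pmin(pmax(floor(score * 4 + 1 + 0.5), 1L), 5L)  # half-up rounding
  }
  data.frame(
    head_score = Y[, 1L],
    chest_score = Y[, 2L],
    head_ais = as.integer(to_band(Y[, 1L])),
    chest_ais = as.integer(to_band(Y[, 2L]))
  )
}
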