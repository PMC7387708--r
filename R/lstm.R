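#' Configuration of the LSTM sequence-regression baseline
#'
#' One LSTM layer over sliding windows of (presented n-level, block
#' accuracy) pairs, topped by a dense affine map to the next block's
#' (n-level, accuracy). Width 32 gives the reference architecture:
#' 4u(u + input + 1) = 4480 recurrent parameters and 2u + 2 = 66 dense
#' parameters at u = 32.
#'
#' @param units Recurrent width (>= 1).
#' @param window Sliding-window length (>= 2).
#' @param epochs,batch_size,learning_rate Training hyperparameters (Adam).
#' @param seed Seed for weight initialization and batch shuffling; the same
#'   seed and data give identical predictions.
#' @return An object of class `lstm_config` (input and output dims are
#'   fixed at 2).
#' @export
lstm_config <- function(units = 32, window = 20, epochs = 60,
                        batch_size = 32, learning_rate = 0.01, seed = 1) {
  stopifnot(units >= 1, window >= 2, epochs >= 1, batch_size >= 1,
            learning_rate > 0)
  structure(list(units = as.integer(units), window = as.integer(window),
                 input_dim = 2L, output_dim = 2L,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = seed),
            class = "lstm_config")
}

#' Sliding-window dataset for the LSTM baseline
#'
#' Builds causal windows per participant: each input is `window`
#' consecutive (n-level, accuracy) pairs and the target is the pair at the
#' step immediately after the window. Windows never span participant
#' boundaries; a participant with fewer than `window + 1` usable blocks
#' contributes none (with a message). N-levels are standardized by the
#' cohort's mean and standard deviation (stored for inverse transforms);
#' accuracies stay in `[0, 1]`.
#'
#' @param cohort An [nback_cohort()].
#' @param config An [lstm_config()].
#' @param scaler Optional precomputed scaler (use the training scaler when
#'   windowing a test cohort).
#' @return An object of class `lstm_dataset` with `inputs`
#'   (n x window x 2 array), `targets` (n x 2), `index` (participant and
#'   target block of each window) and `scaler`.
#' @export
make_windows <- function(cohort, config, scaler = NULL) {
  if (inherits(cohort, "participant_sequence")) cohort <- list(cohort)
  if (!length(cohort)) stop("cohort must be non-empty", call. = FALSE)
  series <- lapply(cohort, function(s) {
    b <- fit_blocks(s)
    list(id = s$participant_id, z = b$z, y = b$y_frac, t = b$t)
  })
  if (is.null(scaler)) {
    allz <- unlist(lapply(series, `[[`, "z"))
    sdz <- stats::sd(allz)
    scaler <- list(mu = mean(allz), sd = if (is.na(sdz) || sdz == 0) 1
                   else sdz)
  }
  w <- config$window
  ins <- list(); tgt <- list(); idx <- list()
  for (s in series) {
    T_ <- length(s$z)
    n_win <- max(0L, T_ - w)
    if (n_win == 0L) {
      message(sprintf("participant %s: %d blocks < window + 1, skipped",
                      s$id, T_))
      next
    }
    zs <- (s$z - scaler$mu) / scaler$sd
    for (k in seq_len(n_win)) {
      ins[[length(ins) + 1]] <- cbind(zs[k:(k + w - 1)],
                                      s$y[k:(k + w - 1)])
      tgt[[length(tgt) + 1]] <- c(zs[k + w], s$y[k + w])
      idx[[length(idx) + 1]] <- data.frame(participant_id = s$id,
                                           t_target = s$t[k + w])
    }
  }
  if (!length(ins)) stop("no windows could be formed", call. = FALSE)
  inputs <- array(0, dim = c(length(ins), w, 2))
  for (k in seq_along(ins)) inputs[k, , ] <- ins[[k]]
  structure(list(inputs = inputs,
                 targets = do.call(rbind, tgt),
                 index = do.call(rbind, idx),
                 scaler = scaler),
            class = "lstm_dataset")
}

#' Build (initialize) the LSTM baseline model
#'
#' @param config An [lstm_config()].
#' @return An object of class `lstm_model` carrying the weight matrices and
#'   `param_counts` (`recurrent` = 4u(u + 3), `dense` = 2u + 2 for the
#'   2-dimensional input/output).
#' @examples
#' build_model(lstm_config(units = 32))$param_counts
#' @export
build_model <- function(config) {
  u <- config$units
  di <- config$input_dim; do_ <- config$output_dim
  local_seed(config$seed, {
    r <- 1 / sqrt(u)
    W_x <- matrix(stats::runif(4 * u * di, -r, r), 4 * u, di)
    W_h <- matrix(stats::runif(4 * u * u, -r, r), 4 * u, u)
    b <- numeric(4 * u)
    b[(u + 1):(2 * u)] <- 1  # forget-gate bias
    W_d <- matrix(stats::runif(do_ * u, -r, r), do_, u)
    b_d <- numeric(do_)
    structure(list(config = config, W_x = W_x, W_h = W_h, b = b,
                   W_d = W_d, b_d = b_d,
                   param_counts = list(
                     recurrent = as.integer(4 * u * (u + di + 1)),
                     dense = as.integer(do_ * u + do_))),
              class = "lstm_model")
  })
}

sigm <- function(x) 1 / (1 + exp(-x))

# Forward pass over a batch: X is B x T x 2. Returns the output (B x 2)
# and, when keep = TRUE, the per-step activations needed by backprop.
lstm_forward <- function(model, X, keep = FALSE) {
  u <- model$config$units
  B <- dim(X)[1]; T_ <- dim(X)[2]
  H <- matrix(0, B, u); C <- matrix(0, B, u)
  cache <- if (keep) vector("list", T_)
  for (t in seq_len(T_)) {
    Xt <- X[, t, , drop = FALSE]
    dim(Xt) <- c(B, dim(X)[3])
    Z <- Xt %*% t(model$W_x) + H %*% t(model$W_h) +
      matrix(model$b, B, 4 * u, byrow = TRUE)
    i <- sigm(Z[, 1:u, drop = FALSE])
    f <- sigm(Z[, (u + 1):(2 * u), drop = FALSE])
    g <- tanh(Z[, (2 * u + 1):(3 * u), drop = FALSE])
    o <- sigm(Z[, (3 * u + 1):(4 * u), drop = FALSE])
    C_prev <- C
    C <- f * C_prev + i * g
    tC <- tanh(C)
    if (keep) cache[[t]] <- list(Xt = Xt, H_prev = H, C_prev = C_prev,
                                 i = i, f = f, g = g, o = o, tC = tC)
    H <- o * tC
  }
  Y <- H %*% t(model$W_d) + matrix(model$b_d, B, length(model$b_d),
                                   byrow = TRUE)
  list(Y = Y, H = H, cache = cache)
}

# Mean-squared-error loss and gradients for a batch (backprop through
# time). Returns loss and a list of gradients matching the weight slots.
lstm_loss_grad <- function(model, X, target) {
  u <- model$config$units
  B <- dim(X)[1]; T_ <- dim(X)[2]
  fw <- lstm_forward(model, X, keep = TRUE)
  err <- fw$Y - target
  loss <- mean(err^2)
  dY <- 2 * err / length(err)
  gW_d <- t(dY) %*% fw$H
  gb_d <- colSums(dY)
  dH <- dY %*% model$W_d
  dC <- matrix(0, B, u)
  gW_x <- matrix(0, nrow(model$W_x), ncol(model$W_x))
  gW_h <- matrix(0, nrow(model$W_h), ncol(model$W_h))
  gb <- numeric(length(model$b))
  for (t in rev(seq_len(T_))) {
    ch <- fw$cache[[t]]
    dO <- dH * ch$tC
    dC <- dC + dH * ch$o * (1 - ch$tC^2)
    dI <- dC * ch$g
    dG <- dC * ch$i
    dF <- dC * ch$C_prev
    dC <- dC * ch$f
    dZ <- cbind(dI * ch$i * (1 - ch$i),
                dF * ch$f * (1 - ch$f),
                dG * (1 - ch$g^2),
                dO * ch$o * (1 - ch$o))
    gW_x <- gW_x + t(dZ) %*% ch$Xt
    gW_h <- gW_h + t(dZ) %*% ch$H_prev
    gb <- gb + colSums(dZ)
    dH <- dZ %*% model$W_h
  }
  list(loss = loss,
       grads = list(W_x = gW_x, W_h = gW_h, b = gb, W_d = gW_d, b_d = gb_d))
}

#' Train the LSTM baseline on a windowed dataset
#'
#' Minimizes mean squared error over both outputs with Adam, seeded batch
#' shuffling, deterministic given the configuration seed. Aborts with a
#' diagnostic if the loss goes non-finite.
#'
#' @param dataset An [make_windows()] dataset.
#' @param config An [lstm_config()].
#' @param model Optional pre-built [build_model()] model (e.g. to continue
#'   training).
#' @return An object of class `lstm_fit`: the trained `model`, the
#'   `scaler`, and `loss_trace` (mean training loss per epoch).
#' @export
train_lstm <- function(dataset, config, model = NULL) {
  stopifnot(inherits(dataset, "lstm_dataset"))
  if (is.null(model)) model <- build_model(config)
  n <- dim(dataset$inputs)[1]
  slots <- c("W_x", "W_h", "b", "W_d", "b_d")
  mom <- lapply(model[slots], function(w) w * 0)
  vel <- mom
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  loss_trace <- numeric(config$epochs)
  local_seed(config$seed + 1, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        X <- dataset$inputs[idx, , , drop = FALSE]
        tg <- dataset$targets[idx, , drop = FALSE]
        lg <- lstm_loss_grad(model, X, tg)
        if (!is.finite(lg$loss)) {
          stop(sprintf("divergent loss at epoch %d (non-finite)", ep),
               call. = FALSE)
        }
        losses <- c(losses, lg$loss)
        step <- step + 1
        for (s in slots) {
          mom[[s]] <- b1 * mom[[s]] + (1 - b1) * lg$grads[[s]]
          vel[[s]] <- b2 * vel[[s]] + (1 - b2) * lg$grads[[s]]^2
          mhat <- mom[[s]] / (1 - b1^step)
          vhat <- vel[[s]] / (1 - b2^step)
          model[[s]] <- model[[s]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      loss_trace[ep] <- mean(losses)
    }
  })
  structure(list(model = model, config = config, scaler = dataset$scaler,
                 loss_trace = loss_trace),
            class = "lstm_fit")
}

#' Train the baseline and return aligned predictions
#'
#' Wrapper composing [train_lstm()] with causal prediction on the same
#' windows: the prediction for block `t` uses only blocks before `t`.
#'
#' @param dataset An [make_windows()] dataset.
#' @param config An [lstm_config()].
#' @return A list with `fit` (the `lstm_fit`) and `predictions`, a
#'   data.frame of `participant_id`, `t` (target block), predicted and
#'   observed n-level and accuracy.
#' @export
train_and_predict <- function(dataset, config) {
  fit <- train_lstm(dataset, config)
  fw <- lstm_forward(fit$model, dataset$inputs)
  sc <- dataset$scaler
  preds <- data.frame(participant_id = dataset$index$participant_id,
                      t = dataset$index$t_target,
                      pred_z = fw$Y[, 1] * sc$sd + sc$mu,
                      pred_acc = fw$Y[, 2],
                      obs_z = dataset$targets[, 1] * sc$sd + sc$mu,
                      obs_acc = dataset$targets[, 2])
  list(fit = fit, predictions = preds)
}

#' @export
print.lstm_fit <- function(x, ...) {
  pc <- x$model$param_counts
  cat(sprintf(
    "LSTM baseline: %d units, window %d (%d + %d parameters), %d epochs, final loss %.5f\n",
    x$config$units, x$config$window, pc$recurrent, pc$dense,
    length(x$loss_trace), x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' @export
predict_blocks.lstm_fit <- function(object, seq, ...) {
  b <- fit_blocks(seq)
  out <- data.frame(t = b$t, pred_acc = NA_real_, obs_acc = b$y_frac,
                    pred_z = NA_real_, obs_z = b$z)
  w <- object$config$window
  if (nrow(b) > w) {
    ds <- make_windows(nback_cohort(list(seq)), object$config,
                       scaler = object$scaler)
    fw <- lstm_forward(object$model, ds$inputs)
    pos <- match(ds$index$t_target, b$t)
    out$pred_acc[pos] <- fw$Y[, 2]
    out$pred_z[pos] <- fw$Y[, 1] * object$scaler$sd + object$scaler$mu
  }
  out
}

#' Serialize a trained LSTM baseline to JSON
#'
#' @param fit An `lstm_fit`.
#' @param path Output path.
#' @export
write_lstm_model <- function(fit, path) {
  stopifnot(inherits(fit, "lstm_fit"))
  m <- fit$model
  obj <- list(type = "lstm", config = unclass(fit$config),
              scaler = fit$scaler,
              weights = list(W_x = m$W_x, W_h = m$W_h, b = m$b,
                             W_d = m$W_d, b_d = m$b_d),
              loss_trace = fit$loss_trace)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trained LSTM baseline from JSON
#'
#' @param path Path written by [write_lstm_model()].
#' @return An `lstm_fit`.
#' @export
read_lstm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$type, "lstm"))
  cfg <- do.call(lstm_config, obj$config[c("units", "window", "epochs",
                                           "batch_size", "learning_rate",
                                           "seed")])
  model <- build_model(cfg)
  model$W_x <- as.matrix(obj$weights$W_x)
  model$W_h <- as.matrix(obj$weights$W_h)
  model$b <- as.numeric(obj$weights$b)
  model$W_d <- as.matrix(obj$weights$W_d)
  model$b_d <- as.numeric(obj$weights$b_d)
  structure(list(model = model, config = cfg, scaler = obj$scaler,
                 loss_trace = obj$loss_trace),
            class = "lstm_fit")
}
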