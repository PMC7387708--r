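#' Parameters of the continuous-state skill tracker
#'
#' Linear-Gaussian dynamics on the two-dimensional state (skill,
#' discrimination rho) driven by a three-component control input, with the
#' nonlinear item-characteristic-curve observation handled by an unscented
#' Kalman filter.
#'
#' @param A 2 x 2 state-transition matrix.
#' @param B 2 x 3 control-input matrix; the control vector is
#'   `(z_t, y_{t-1}, 1)` — current challenge, previous performance, bias —
#'   with `y_0 = 0.5` for the first block.
#' @param Q 2 x 2 process covariance (symmetric PSD).
#' @param R Observation variance (scalar > 0).
#' @param x0 Initial state mean `(skill, rho)`.
#' @param V0 2 x 2 initial state covariance (symmetric PSD).
#' @return An object of class `ukf_params`.
#' @export
ukf_params <- function(A = diag(2),
                       B = matrix(0, 2, 3),
                       Q = diag(c(0.05, 0.005)),
                       R = 0.04,
                       x0 = c(2, 1.6),
                       V0 = diag(c(1, 0.25))) {
  A <- as.matrix(A); B <- as.matrix(B); Q <- as.matrix(Q); V0 <- as.matrix(V0)
  stopifnot(identical(dim(A), c(2L, 2L)), identical(dim(B), c(2L, 3L)),
            identical(dim(Q), c(2L, 2L)), identical(dim(V0), c(2L, 2L)),
            length(x0) == 2, length(R) == 1)
  if (R <= 0) stop("R must be > 0", call. = FALSE)
  check_psd(Q, "Q"); check_psd(V0, "V0")
  structure(list(A = A, B = B, Q = Q, R = as.numeric(R),
                 x0 = as.numeric(x0), V0 = V0),
            class = "ukf_params")
}

check_psd <- function(M, name) {
  if (max(abs(M - t(M))) > 1e-8) stop(name, " must be symmetric",
                                      call. = FALSE)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop(name, " must be positive semidefinite",
                            call. = FALSE)
  invisible(M)
}

#' @export
print.ukf_params <- function(x, ...) {
  cat("Unscented Kalman tracker parameters (state = skill, rho)\n")
  cat("  A:\n"); print(round(x$A, 4))
  cat("  B:\n"); print(round(x$B, 4))
  cat(sprintf("  Q diag: %s | R: %.4g | x0: (%.3g, %.3g)\n",
              paste(round(diag(x$Q), 4), collapse = ", "), x$R,
              x$x0[1], x$x0[2]))
  invisible(x)
}

#' Unscented-transform constants
#'
#' Merwe scaled sigma points for the 2-dimensional state.
#'
#' @param alpha_ut Spread of the sigma points (default 0.5).
#' @param beta_ut Prior-distribution constant (2 is optimal for Gaussians).
#' @param kappa Secondary scaling (default 0).
#' @return A list with the sigma-point weights.
#' @export
ut_config <- function(alpha_ut = 0.5, beta_ut = 2, kappa = 0) {
  n <- 2
  lambda <- alpha_ut^2 * (n + kappa) - n
  if (n + lambda <= 0) stop("n + lambda must be positive", call. = FALSE)
  wm <- c(lambda / (n + lambda), rep(1 / (2 * (n + lambda)), 2 * n))
  wc <- wm
  wc[1] <- wc[1] + 1 - alpha_ut^2 + beta_ut
  list(alpha_ut = alpha_ut, beta_ut = beta_ut, kappa = kappa,
       lambda = lambda, n = n, wm = wm, wc = wc)
}

#' Observation function of the continuous tracker
#'
#' The item characteristic curve evaluated at the state's skill component,
#' with the state's discrimination component clamped at 0.05 (preventing
#' sign flips), guessing floor 0 and ceiling 1.
#'
#' @param state Length-2 state vector `(skill, rho)` or a 2-row matrix of
#'   sigma points (columns = points).
#' @param z Presented n-level.
#' @return Predicted accuracy in `(0, 1)`.
#' @export
ukf_observe <- function(state, z) {
  if (is.matrix(state)) {
    skill <- state[1, ]; rho <- pmax(state[2, ], 0.05)
  } else {
    skill <- state[1]; rho <- max(state[2], 0.05)
  }
  1 / (1 + exp(-rho * (skill - z)))
}

# Sigma points of N(m, P): 2 x 5 matrix, first column the mean.
# Analytic lower Cholesky of the 2 x 2 scaled covariance, with an eigen
# fallback for indefinite input.
sigma_points <- function(m, P, ut) {
  c_ <- ut$n + ut$lambda
  p11 <- c_ * P[1, 1]; p21 <- c_ * P[2, 1]; p22 <- c_ * P[2, 2]
  if (p11 > 0 && (d22 <- p22 - p21^2 / p11) >= 0) {
    l11 <- sqrt(p11); l21 <- p21 / l11; l22 <- sqrt(d22)
  } else {
    es <- eigen(c_ * (P + t(P)) / 2, symmetric = TRUE)
    S <- es$vectors %*% (sqrt(pmax(es$values, 1e-12)) * t(es$vectors))
    l11 <- S[1, 1]; l21 <- S[2, 1]; l22 <- S[2, 2]
    # not triangular, but any square root of the covariance is valid
    m2 <- c(m[1] + S[1, 2], m[2] + S[2, 2])
    return(matrix(c(m, m[1] + l11, m[2] + l21, m2[1], m2[2],
                    m[1] - l11, m[2] - l21, 2 * m[1] - m2[1],
                    2 * m[2] - m2[2]), 2, 5))
  }
  matrix(c(m, m[1] + l11, m[2] + l21, m[1], m[2] + l22,
           m[1] - l11, m[2] - l21, m[1], m[2] - l22), 2, 5)
}

fix_psd <- function(P, floor = 1e-9) {
  P <- (P + t(P)) / 2
  # cheap 2 x 2 PSD check; eigenvalue flooring only when violated
  if (P[1, 1] >= floor && P[2, 2] >= floor &&
      P[1, 1] * P[2, 2] - P[1, 2]^2 >= 0) {
    return(P)
  }
  es <- eigen(P, symmetric = TRUE)
  P <- es$vectors %*% (pmax(es$values, floor) * t(es$vectors))
  (P + t(P)) / 2
}

control_inputs <- function(blocks) {
  T_ <- nrow(blocks)
  y_prev <- c(0.5, blocks$y_frac[-T_])
  y_prev[is.na(y_prev)] <- 0.5
  rbind(blocks$z, y_prev, 1)  # 3 x T
}

#' Unscented Kalman filtering of a training sequence
#'
#' Exact linear prediction (the dynamics are linear) followed by an
#' unscented measurement update through the nonlinear observation
#' function, for every block. The first block's prior is `N(x0, V0)`.
#' Also returns the one-step-ahead predicted accuracy (sigma points of the
#' prior pushed through the observation) and the Gaussian innovation
#' log-likelihood. Covariances are symmetrized and eigenvalue-floored at
#' 1e-9 if an update leaves them indefinite.
#'
#' @param seq A [participant_sequence()].
#' @param params A [ukf_params()] object.
#' @param ut A [ut_config()] list.
#' @param obs_fn Observation function `(state_matrix, z) -> accuracy`;
#'   defaults to [ukf_observe()]. Exposed so linear observations can be
#'   substituted (in which case the filter reduces to the exact Kalman
#'   filter).
#' @return A list with `mean` (T x 2 filtered means), `cov` (T x 2 x 2),
#'   `loglik`, `pred_acc`, and `blocks`.
#' @export
ukf_filter <- function(seq, params, ut = ut_config(), obs_fn = ukf_observe) {
  blocks <- fit_blocks(seq)
  T_ <- nrow(blocks)
  U <- control_inputs(blocks)
  out <- ukf_forward(blocks$y_frac, blocks$z, U, params, ut, obs_fn)
  list(mean = out$m_filt, cov = out$P_filt, loglik = out$loglik,
       pred_acc = out$pred_acc, blocks = blocks)
}

# Core recursion, shared by the filter and the smoother. Returns filtered
# and one-step-predicted moments.
ukf_forward <- function(y, z, U, params, ut, obs_fn = ukf_observe) {
  T_ <- length(y)
  A <- params$A; B <- params$B; Q <- params$Q; R <- params$R
  m_filt <- matrix(0, T_, 2)
  P_filt <- array(0, dim = c(T_, 2, 2))
  m_pred <- matrix(0, T_, 2)
  P_pred <- array(0, dim = c(T_, 2, 2))
  pred_acc <- numeric(T_)
  loglik <- 0
  for (t in seq_len(T_)) {
    if (t == 1) {
      m <- params$x0; P <- params$V0
    } else {
      m <- as.numeric(A %*% m_filt[t - 1, ] + B %*% U[, t])
      P <- A %*% P_filt[t - 1, , ] %*% t(A) + Q
    }
    m_pred[t, ] <- m; P_pred[t, , ] <- P
    X <- sigma_points(m, P, ut)
    g <- obs_fn(X, z[t])
    yhat <- sum(ut$wm * g)
    pred_acc[t] <- yhat
    dg <- g - yhat
    S <- sum(ut$wc * dg^2) + R
    if (S <= 0) S <- R
    C <- (X - m) %*% (ut$wc * dg)  # 2 x 1 cross-covariance
    if (!is.na(y[t])) {
      K <- C / S
      m <- m + as.numeric(K) * (y[t] - yhat)
      P <- P - K %*% t(K) * S
      P <- fix_psd(P)
      loglik <- loglik + stats::dnorm(y[t], yhat, sqrt(S), log = TRUE)
    }
    m_filt[t, ] <- m
    P_filt[t, , ] <- P
  }
  list(m_filt = m_filt, P_filt = P_filt, m_pred = m_pred, P_pred = P_pred,
       pred_acc = pred_acc, loglik = loglik)
}

# Rauch-Tung-Striebel smoother (exact for the linear dynamics). Returns
# smoothed moments and the lag-one covariances needed by EM.
ukf_smooth <- function(fwd, params) {
  T_ <- nrow(fwd$m_filt)
  A <- params$A
  ms <- fwd$m_filt
  Ps <- fwd$P_filt
  C_lag <- array(0, dim = c(T_, 2, 2))  # Cov(x_t, x_{t-1} | all y)
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      Pp <- fwd$P_pred[t + 1, , ]
      det_p <- Pp[1, 1] * Pp[2, 2] - Pp[1, 2] * Pp[2, 1]
      Pp_inv <- matrix(c(Pp[2, 2], -Pp[2, 1], -Pp[1, 2], Pp[1, 1]),
                       2, 2) / det_p
      G <- fwd$P_filt[t, , ] %*% t(A) %*% Pp_inv
      ms[t, ] <- fwd$m_filt[t, ] +
        as.numeric(G %*% (ms[t + 1, ] - fwd$m_pred[t + 1, ]))
      Ps[t, , ] <- fix_psd(fwd$P_filt[t, , ] +
                             G %*% (Ps[t + 1, , ] - Pp) %*% t(G))
      C_lag[t + 1, , ] <- Ps[t + 1, , ] %*% t(G)
    }
  }
  list(mean = ms, cov = Ps, C_lag = C_lag)
}

#' EM control settings for the continuous tracker
#'
#' @param max_iter Maximum EM iterations.
#' @param tol Stopping threshold on the log-likelihood increase.
#' @param seed Seed (reserved for stochastic initialization schemes).
#' @return A list.
#' @export
ukf_em_control <- function(max_iter = 30, tol = 0.001, seed = 1) {
  list(max_iter = max_iter, tol = tol, seed = seed)
}

#' Fit the continuous tracker by (approximate) EM
#'
#' E-step: unscented Rauch-Tung-Striebel smoother per participant (the
#' smoother itself is exact because the dynamics are linear; the
#' approximation enters through the unscented measurement updates).
#' M-step: closed-form generalized-least-squares update of `[A B]`
#' jointly, `Q` from smoothed residual second moments, `x0`/`V0` from the
#' pooled smoothed first-block moments, and `R` from
#' sigma-point-propagated observation residuals. Because the E-step is
#' approximate, the log-likelihood trace is only approximately monotone.
#'
#' @param cohort An [nback_cohort()].
#' @param init A [ukf_params()] starting point.
#' @param control A [ukf_em_control()] list.
#' @param ut A [ut_config()] list.
#' @param obs_fn Observation function (see [ukf_filter()]).
#' @return An object of class `ukf_fit`: `params`, `loglik_trace`,
#'   `converged`, `n_iterations`, `ut`.
#' @export
ukf_em_fit <- function(cohort, init = ukf_params(),
                       control = ukf_em_control(), ut = ut_config(),
                       obs_fn = ukf_observe) {
  if (inherits(cohort, "participant_sequence")) cohort <- list(cohort)
  if (!length(cohort)) stop("cohort must be non-empty", call. = FALSE)
  data <- lapply(cohort, function(s) {
    if (inherits(s, "participant_sequence")) {
      b <- fit_blocks(s)
      list(y = b$y_frac, z = b$z, U = control_inputs(b))
    } else {
      # raw series (list with y, z, optional U): linear-case diagnostics
      stopifnot(is.list(s), !is.null(s$y), !is.null(s$z))
      if (!is.null(s$U)) {
        list(y = s$y, z = s$z, U = s$U)
      } else {
        T_ <- length(s$y)
        y_prev <- c(0.5, s$y[-T_])
        list(y = s$y, z = s$z, U = rbind(s$z, y_prev, 1))
      }
    }
  })
  params <- init
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(control$max_iter)) {
    Sxw <- matrix(0, 2, 5); Sww <- matrix(0, 5, 5); Sxx <- matrix(0, 2, 2)
    n_dyn <- 0
    sum_R <- 0; n_obs <- 0
    s1_list <- list(); S1_list <- list()
    ll <- 0
    for (d in data) {
      fwd <- ukf_forward(d$y, d$z, d$U, params, ut, obs_fn)
      ll <- ll + fwd$loglik
      sm <- ukf_smooth(fwd, params)
      T_ <- length(d$y)
      s1_list[[length(s1_list) + 1]] <- sm$mean[1, ]
      S1_list[[length(S1_list) + 1]] <- sm$cov[1, , ]
      if (T_ > 1) {
        for (t in 2:T_) {
          st <- sm$mean[t, ]; st1 <- sm$mean[t - 1, ]
          St <- sm$cov[t, , ]; St1 <- sm$cov[t - 1, , ]
          Ct <- sm$C_lag[t, , ]          # Cov(x_t, x_{t-1})
          u <- d$U[, t]
          Exx1 <- Ct + st %*% t(st1)     # E[x_t x_{t-1}']
          Exw <- cbind(Exx1, st %*% t(u))
          Eww <- rbind(cbind(St1 + st1 %*% t(st1), st1 %*% t(u)),
                       cbind(u %*% t(st1), u %*% t(u)))
          Sxw <- Sxw + Exw
          Sww <- Sww + Eww
          Sxx <- Sxx + St + st %*% t(st)
          n_dyn <- n_dyn + 1
        }
      }
      for (t in seq_len(T_)) {
        if (is.na(d$y[t])) next
        X <- sigma_points(sm$mean[t, ], sm$cov[t, , ], ut)
        g <- obs_fn(X, d$z[t])
        yhat <- sum(ut$wm * g)
        var_g <- max(sum(ut$wc * (g - yhat)^2), 0)
        sum_R <- sum_R + (d$y[t] - yhat)^2 + var_g
        n_obs <- n_obs + 1
      }
    }
    trace <- c(trace, ll)
    if (iter > 1 && (ll - trace[iter - 1]) < control$tol) {
      converged <- TRUE
      break
    }
    # M-step
    Theta <- Sxw %*% solve(Sww + diag(1e-8, 5))
    A_new <- Theta[, 1:2, drop = FALSE]
    B_new <- Theta[, 3:5, drop = FALSE]
    Q_new <- fix_psd((Sxx - Theta %*% t(Sxw)) / max(n_dyn, 1))
    x0_new <- Reduce(`+`, s1_list) / length(s1_list)
    V0_new <- Reduce(`+`, lapply(seq_along(s1_list), function(i) {
      dmu <- s1_list[[i]] - x0_new
      S1_list[[i]] + dmu %*% t(dmu)
    })) / length(s1_list)
    params <- ukf_params(A = A_new, B = B_new, Q = Q_new,
                         R = max(sum_R / max(n_obs, 1), 1e-6),
                         x0 = x0_new, V0 = fix_psd(V0_new))
  }
  structure(list(params = params, loglik_trace = trace,
                 converged = converged, n_iterations = length(trace),
                 ut = ut, obs_fn = obs_fn),
            class = "ukf_fit")
}

#' @export
print.ukf_fit <- function(x, ...) {
  cat(sprintf("UKF tracker fit: %d EM iterations, %sconverged, loglik %.3f\n",
              x$n_iterations, if (x$converged) "" else "NOT ",
              max(x$loglik_trace)))
  print(x$params)
  invisible(x)
}

#' @export
predict_blocks.ukf_fit <- function(object, seq, ...) {
  ff <- ukf_filter(seq, object$params, ut = object$ut,
                   obs_fn = object$obs_fn)
  data.frame(t = ff$blocks$t, pred_acc = ff$pred_acc,
             obs_acc = ff$blocks$y_frac)
}

#' One-step-ahead accuracy prediction of the continuous tracker
#'
#' Propagates a Gaussian belief through the linear dynamics, then pushes
#' sigma points through the observation function and returns their
#' weighted mean.
#'
#' @param belief_prev A list with `mean` (length 2) and `cov` (2 x 2).
#' @param u_next Control vector `(z_next, y_prev, 1)`.
#' @param z_next Next presented n-level.
#' @param params A [ukf_params()] object.
#' @param ut A [ut_config()] list.
#' @param obs_fn Observation function.
#' @return Expected accuracy fraction.
#' @export
ukf_predict_accuracy <- function(belief_prev, u_next, z_next, params,
                                 ut = ut_config(), obs_fn = ukf_observe) {
  m <- as.numeric(params$A %*% belief_prev$mean + params$B %*% u_next)
  P <- params$A %*% belief_prev$cov %*% t(params$A) + params$Q
  X <- sigma_points(m, P, ut)
  sum(ut$wm * obs_fn(X, z_next))
}

#' Write a fitted continuous tracker to JSON
#'
#' @param fit A `ukf_fit` object.
#' @param path Output path.
#' @export
write_ukf_model <- function(fit, path) {
  stopifnot(inherits(fit, "ukf_fit"))
  p <- fit$params
  obj <- list(type = "ukf",
              A = p$A, B = p$B, Q = p$Q, R = p$R, x0 = p$x0, V0 = p$V0,
              ut = fit$ut[c("alpha_ut", "beta_ut", "kappa")],
              fit = list(n_iterations = fit$n_iterations,
                         converged = fit$converged,
                         loglik_trace = fit$loglik_trace))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted continuous tracker from JSON
#'
#' @param path Path written by [write_ukf_model()].
#' @return A `ukf_fit` object.
#' @export
read_ukf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$type, "ukf"))
  params <- ukf_params(A = matrix(unlist(obj$A), 2, 2),
                       B = matrix(unlist(obj$B), 2, 3),
                       Q = matrix(unlist(obj$Q), 2, 2), R = obj$R,
                       x0 = unlist(obj$x0),
                       V0 = matrix(unlist(obj$V0), 2, 2))
  structure(list(params = params,
                 loglik_trace = obj$fit$loglik_trace,
                 converged = obj$fit$converged,
                 n_iterations = obj$fit$n_iterations,
                 ut = ut_config(obj$ut$alpha_ut, obj$ut$beta_ut,
                                obj$ut$kappa),
                 obs_fn = ukf_observe),
            class = "ukf_fit")
}
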