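# Linear observation used by the exact-Kalman cross-checks.
H_lin <- c(1, 0.8)
obs_lin <- function(X, z) {
  if (is.matrix(X)) as.numeric(H_lin %*% X) - 0.05 * z
  else sum(H_lin * X) - 0.05 * z
}

sim_linear_seq <- function(T_, A, B, Q, R, x0, V0) {
  y <- numeric(T_); z <- numeric(T_); U <- matrix(0, 3, T_)
  xx <- x0 + t(chol(V0)) %*% rnorm(2)
  states <- matrix(0, T_, 2)
  for (t in seq_len(T_)) {
    z[t] <- 2 + (t %% 5)
    U[, t] <- c(z[t], sin(t / 3), 1)
    if (t > 1) xx <- A %*% xx + B %*% U[, t] + t(chol(Q)) %*% rnorm(2)
    states[t, ] <- xx
    y[t] <- obs_lin(as.numeric(xx), z[t]) + rnorm(1, 0, sqrt(R))
  }
  list(y = y, z = z, U = U, states = states)
}

test_that("the observation function is the shared ICC with a clamped slope", {
  expect_equal(ukf_observe(c(5, 1.6), 5), 0.5)
  expect_equal(ukf_observe(c(7, 1.6), 5),
               icc(7, 5, irt_params(rho = 1.6, c = 0, d = 1, alpha = 1)))
  # slope clamp prevents sign flips
  expect_equal(ukf_observe(c(7, -3), 5), ukf_observe(c(7, 0.05), 5))
  v <- ukf_observe(rbind(seq(-5, 15, 2), rep(1.6, 11)), 5)
  expect_true(all(v > 0 & v < 1))
})

test_that("with a linear observation the UKF equals the exact Kalman filter", {
  params <- ukf_params(A = matrix(c(0.95, 0.02, 0, 0.98), 2, 2),
                       B = matrix(c(0.03, 0, 0.15, 0.1, 0.05, 0.03), 2, 3),
                       Q = diag(c(0.02, 0.02)), R = 0.01,
                       x0 = c(3, 1.5), V0 = diag(c(0.2, 0.05)))
  s <- local_seed_test(23, sim_linear_seq(20, params$A, params$B, params$Q,
                                          params$R, params$x0, params$V0))
  fwd <- skilltrackr:::ukf_forward(s$y, s$z, s$U, params, ut_config(),
                                   obs_fn = obs_lin)
  or <- kalman_oracle(s$y, s$z, s$U, params, matrix(H_lin, 1, 2),
                      function(z) -0.05 * z)
  expect_equal(fwd$m_filt, or$mean, tolerance = 1e-8)
  expect_equal(fwd$loglik, or$loglik, tolerance = 1e-8)
})

test_that("an uninformative observation leaves the prior propagation unchanged", {
  params <- ukf_params(A = diag(c(0.97, 0.99)),
                       B = matrix(c(0.02, 0, 0.1, 0.01, 0.03, 0), 2, 3),
                       Q = diag(c(0.03, 0.01)), R = 1e12,
                       x0 = c(2, 1.6), V0 = diag(c(0.5, 0.1)))
  s <- make_seq(z = c(2, 3, 3, 4, 4, 5), tp = c(8, 7, 9, 6, 8, 7),
                fn = c(2, 3, 1, 4, 2, 3), fp = c(1, 0, 1, 2, 0, 1))
  ff <- ukf_filter(s, params)
  U <- skilltrackr:::control_inputs(ff$blocks)
  m <- params$x0
  for (t in 1:6) {
    if (t > 1) m <- as.numeric(params$A %*% m + params$B %*% U[, t])
    expect_equal(ff$mean[t, ], m, tolerance = 1e-6)
  }
})

test_that("filtered covariances stay symmetric positive semidefinite", {
  params <- ukf_params()
  co <- toy_cohort(n = 3, T_ = 16, seed = 91)
  for (s in co) {
    ff <- ukf_filter(s, params)
    for (t in seq_len(nrow(ff$mean))) {
      P <- ff$cov[t, , ]
      expect_equal(P, t(P), tolerance = 1e-10)
      expect_gte(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-9)
    }
  }
})

test_that("filtering reduces skill error relative to prior prediction", {
  # generative nonlinear model: skill drifts, accuracy = ICC(skill) + noise
  A <- diag(c(1, 1)); Q <- diag(c(0.04, 1e-6)); R <- 0.01
  x0 <- c(3, 1.6); V0 <- diag(c(1, 1e-6))
  gen_seq <- function(T_) {
    y <- numeric(T_); z <- numeric(T_)
    xx <- x0 + c(rnorm(1, 0, 1), 0)
    states <- matrix(0, T_, 2)
    for (t in seq_len(T_)) {
      z[t] <- max(1, round(xx[1]))
      if (t > 1) xx <- xx + c(rnorm(1, 0, sqrt(Q[1, 1])), 0)
      states[t, ] <- xx
      y[t] <- min(max(ukf_observe(xx, z[t]) + rnorm(1, 0, sqrt(R)),
                      0.001), 0.999)
    }
    list(y = y, z = z, states = states)
  }
  params <- ukf_params(A = A, B = matrix(0, 2, 3), Q = Q, R = R,
                       x0 = x0, V0 = diag(c(1, 1e-6)))
  err_filt <- err_prior <- numeric(0)
  local_seed_test(29, {
    for (i in 1:30) {
      s <- gen_seq(40)
      T_ <- length(s$y)
      y_prev <- c(0.5, s$y[-T_])
      fwd <- skilltrackr:::ukf_forward(s$y, s$z, rbind(s$z, y_prev, 1),
                                       params, ut_config())
      err_filt <- c(err_filt, fwd$m_filt[, 1] - s$states[, 1])
      err_prior <- c(err_prior, fwd$m_pred[, 1] - s$states[, 1])
    }
  })
  expect_lt(sqrt(mean(err_filt^2)), sqrt(mean(err_prior^2)))
})

test_that("EM on the exactly-linear special case recovers the dynamics", {
  A <- matrix(c(0.95, 0.02, 0, 0.98), 2, 2)
  B <- matrix(c(0.03, 0, 0.15, 0.1, 0.05, 0.03), 2, 3)
  Q <- diag(c(0.02, 0.02)); R <- 0.01
  x0 <- c(3, 1.5); V0 <- diag(c(0.2, 0.05))
  cohort <- local_seed_test(17, lapply(1:60, function(i) {
    sim_linear_seq(60, A, B, Q, R, x0, V0)
  }))
  fit <- ukf_em_fit(cohort,
                    init = ukf_params(A = diag(2) * 0.9,
                                      Q = diag(c(0.05, 0.05)), R = 0.05,
                                      x0 = c(2, 1), V0 = diag(c(0.5, 0.5))),
                    control = ukf_em_control(max_iter = 60),
                    obs_fn = obs_lin)
  expect_lt(max(abs(fit$params$A - A)), 0.05)
  # exact E-step here: the trace is monotone
  expect_true(all(diff(fit$loglik_trace) >= -1e-4))
  expect_gt(fit$params$R, 0)
  expect_gte(min(eigen(fit$params$Q, symmetric = TRUE,
                       only.values = TRUE)$values), 0)
})

test_that("EM on training data keeps an approximately monotone likelihood", {
  co <- toy_cohort(n = 5, T_ = 14, seed = 37)
  fit <- ukf_em_fit(co, control = ukf_em_control(max_iter = 12))
  expect_true(all(diff(fit$loglik_trace) >= -1e-4))
  expect_gt(fit$params$R, 0)
  expect_gte(min(eigen(fit$params$Q, symmetric = TRUE,
                       only.values = TRUE)$values), 0)
})

test_that("one-step accuracy prediction matches Monte-Carlo propagation", {
  params <- ukf_params(A = diag(c(0.98, 1)),
                       B = matrix(c(0.01, 0, 0.05, 0.01, 0.02, 0), 2, 3),
                       Q = diag(c(0.05, 0.002)), R = 0.02,
                       x0 = c(4, 1.6), V0 = diag(c(0.3, 0.02)))
  bel <- list(mean = c(4.2, 1.5), cov = matrix(c(0.3, 0.05, 0.05, 0.04),
                                               2, 2))
  u <- c(5, 0.7, 1)
  pred <- ukf_predict_accuracy(bel, u, 5, params)
  mc <- local_seed_test(41, {
    L <- t(chol(bel$cov))
    xs <- bel$mean + L %*% matrix(rnorm(2e5), 2)
    xp <- params$A %*% xs + as.numeric(params$B %*% u) +
      t(chol(params$Q)) %*% matrix(rnorm(2e5), 2)
    mean(ukf_observe(xp, 5))
  })
  expect_lt(abs(pred - mc), 0.01)
  # deterministic limits
  bel0 <- list(mean = c(5, 1.6), cov = diag(c(1e-12, 1e-12)))
  p0 <- ukf_params(A = diag(2), B = matrix(0, 2, 3),
                   Q = diag(c(1e-12, 1e-12)), R = 0.01, x0 = c(5, 1.6),
                   V0 = diag(2))
  expect_equal(ukf_predict_accuracy(bel0, c(5, 0.5, 1), 5, p0), 0.5,
               tolerance = 1e-6)
})

test_that("continuous estimates settle between adjacent levels under oscillation", {
  # presented level alternates 8/9: good performance at 8, poor at 9
  T_ <- 40
  z <- rep(c(8, 9), T_ / 2)
  tp <- ifelse(z == 8, 11, 4)
  fn <- ifelse(z == 8, 1, 8)
  s <- make_seq(z = z, tp = tp, fn = fn, fp = rep(0, T_))
  params <- ukf_params(A = diag(2), B = matrix(0, 2, 3),
                       Q = diag(c(0.05, 1e-6)), R = 0.02,
                       x0 = c(5, 1.6), V0 = diag(c(2, 1e-6)))
  ff <- ukf_filter(s, params)
  late <- ff$mean[21:T_, 1]
  expect_gte(mean(late > 8 & late < 9), 0.5)
})

test_that("fitted continuous trackers round-trip through JSON", {
  co <- toy_cohort(n = 3, T_ = 12, seed = 53)
  fit <- ukf_em_fit(co, control = ukf_em_control(max_iter = 4))
  path <- tempfile(fileext = ".json")
  write_ukf_model(fit, path)
  back <- read_ukf_model(path)
  expect_equal(back$params$A, fit$params$A, tolerance = 1e-12)
  expect_equal(back$params$B, fit$params$B, tolerance = 1e-12)
  expect_equal(back$params$R, fit$params$R, tolerance = 1e-12)
  ff1 <- ukf_filter(co[[1]], fit$params)
  ff2 <- ukf_filter(co[[1]], back$params)
  expect_equal(ff1$loglik, ff2$loglik, tolerance = 1e-10)
  unlink(path)
})
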