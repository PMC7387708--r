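# Independent oracles and fixture builders used across the suite.

# Build a participant sequence directly from per-block counts.
make_seq <- function(z, tp, fn, fp, n_trials = 40, id = "T01",
                     session = NULL) {
  T_ <- length(z)
  if (is.null(session)) session <- rep(1L, T_)
  blocks <- data.frame(t = seq_len(T_), session = session, z = z,
                       n_trials = n_trials, n_targets = tp + fn,
                       tp = tp, fn = fn, fp = fp)
  participant_sequence(id, blocks)
}

# Beta-binomial mass by adaptive quadrature of the integral form:
# Bin(y; m, ahat) averaged over ahat ~ Beta(alpha*a, alpha*(1-a)).
# The integral is split at the beta mean and each half is transformed by a
# power substitution that cancels the endpoint pole of the beta density
# (present whenever a shape parameter is below 1), leaving bounded
# integrands that adaptive quadrature handles at high accuracy.
bb_quadrature <- function(y, m, x, z, params) {
  a <- icc(x, z, params)
  a <- min(max(a, 1e-6), 1 - 1e-6)
  a1 <- params$alpha * a
  a2 <- params$alpha * (1 - a)
  K <- exp(-lbeta(a1, a2))
  c_ <- a
  left <- stats::integrate(function(u) {
    ah <- c_ * u^(1 / a1)
    stats::dbinom(y, m, ah) * (1 - ah)^(a2 - 1)
  }, 0, 1, rel.tol = 1e-11, abs.tol = 0)$value * K * c_^a1 / a1
  right <- stats::integrate(function(s) {
    ah <- 1 - (1 - c_) * s^(1 / a2)
    stats::dbinom(y, m, ah) * ah^(a1 - 1)
  }, 0, 1, rel.tol = 1e-11, abs.tol = 0)$value * K * (1 - c_)^a2 / a2
  left + right
}

# Exhaustive path-sum oracle for the input-output HMM: joint probability of
# every latent path, computed from transition_row and emission_log_prob
# alone (never from the forward recursions it checks).
enumerate_paths <- function(seq, model, irt) {
  b <- seq$blocks
  T_ <- nrow(b)
  N <- model$N
  paths <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  logp <- numeric(nrow(paths))
  for (i in seq_len(nrow(paths))) {
    x <- paths[i, ]
    lp <- log(model$pi[x[1]]) +
      emission_log_prob(b$y_succ[1], b$n_targets[1], x[1], b$z[1], irt)
    if (T_ > 1) {
      for (t in 2:T_) {
        tr <- transition_row(model, x[t - 1], b$z[t - 1], b$y_frac[t - 1])
        lp <- lp + log(tr[x[t]]) +
          emission_log_prob(b$y_succ[t], b$n_targets[t], x[t], b$z[t], irt)
      }
    }
    logp[i] <- lp
  }
  list(paths = paths, logp = logp)
}

oracle_loglik <- function(seq, model, irt) {
  en <- enumerate_paths(seq, model, irt)
  mx <- max(en$logp)
  mx + log(sum(exp(en$logp - mx)))
}

# Filtered belief at time t from prefix enumeration.
oracle_filtered <- function(seq, model, irt, t) {
  sub <- seq
  sub$blocks <- seq$blocks[1:t, , drop = FALSE]
  en <- enumerate_paths(sub, model, irt)
  p <- exp(en$logp - max(en$logp))
  bel <- tapply(p, en$paths[, t], sum)
  out <- numeric(model$N)
  out[as.integer(names(bel))] <- bel
  out / sum(out)
}

# Smoothed marginal / pairwise posteriors from full-path enumeration.
oracle_smoothed <- function(seq, model, irt) {
  en <- enumerate_paths(seq, model, irt)
  T_ <- ncol(en$paths)
  N <- model$N
  p <- exp(en$logp - max(en$logp))
  p <- p / sum(p)
  gamma <- matrix(0, T_, N)
  for (t in seq_len(T_)) {
    g <- tapply(p, en$paths[, t], sum)
    gamma[t, as.integer(names(g))] <- g
  }
  xi <- array(0, dim = c(max(T_ - 1, 0), N, N))
  if (T_ > 1) {
    for (t in 1:(T_ - 1)) {
      for (i in seq_len(nrow(en$paths))) {
        xi[t, en$paths[i, t], en$paths[i, t + 1]] <-
          xi[t, en$paths[i, t], en$paths[i, t + 1]] + p[i]
      }
    }
  }
  list(gamma = gamma, xi = xi)
}

# Exact Kalman filter for linear observation y = H x + r0 + noise, with the
# package's linear prediction step. Independent closed-form recursion.
kalman_oracle <- function(y, z, U, params, H, r0_fun) {
  T_ <- length(y)
  A <- params$A; B <- params$B; Q <- params$Q; R <- params$R
  m <- params$x0; P <- params$V0
  means <- matrix(0, T_, 2); lls <- numeric(T_)
  for (t in seq_len(T_)) {
    if (t > 1) {
      m <- as.numeric(A %*% m + B %*% U[, t])
      P <- A %*% P %*% t(A) + Q
    }
    yhat <- as.numeric(H %*% m) + r0_fun(z[t])
    S <- as.numeric(H %*% P %*% t(H)) + R
    K <- P %*% t(H) / S
    m <- m + as.numeric(K) * (y[t] - yhat)
    P <- P - K %*% H %*% P
    means[t, ] <- m
    lls[t] <- stats::dnorm(y[t], yhat, sqrt(S), log = TRUE)
  }
  list(mean = means, loglik = sum(lls))
}

# A small deterministic-ish fixture cohort for evaluation tests.
toy_cohort <- function(n = 4, T_ = 12, seed = 11) {
  simulate_cohort(n, session_plan(n_sessions = 2, blocks_per_session = T_ / 2),
                  participant_profile("steady_learner"),
                  algorithm_spec("blockwise_85_70"), seed = seed)
}

# Seeded evaluation that restores the caller's RNG state.
local_seed_test <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
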