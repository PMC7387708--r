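#' EM control settings for the hidden Markov skill tracker
#'
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence threshold on the per-iteration increase of the
#'   total log-likelihood (default 0.001).
#' @param n_restarts Number of seeded random restarts; the fit with the best
#'   final log-likelihood is kept. Restart 1 always starts from the supplied
#'   (or default) parameters. Model-2 defaults to 5 restarts when `NULL`.
#' @param seed Seed controlling restart perturbations.
#' @param optim_maxit Iteration cap for the numerical M-step optimizer.
#' @param verbose Print per-iteration log-likelihoods.
#' @return A list of class `em_control`.
#' @export
em_control <- function(max_iter = 100, tol = 0.001, n_restarts = NULL,
                       seed = 1, optim_maxit = 100, verbose = FALSE) {
  structure(list(max_iter = max_iter, tol = tol, n_restarts = n_restarts,
                 seed = seed, optim_maxit = optim_maxit, verbose = verbose),
            class = "em_control")
}

# ---- internal: per-sequence preparation -----------------------------------

# Log-emission matrix (T x N) and transition-driving contexts for one
# participant. Emissions depend only on the IRT parameters, so they are
# computed once per EM run, not per iteration.
prep_sequence <- function(seq, model, irt) {
  b <- fit_blocks(seq)
  T_ <- nrow(b)
  N <- model$N
  logE <- matrix(0, T_, N)
  for (x in seq_len(N)) {
    logE[, x] <- emission_log_prob(b$y_succ, b$n_targets, x, b$z, irt)
  }
  ctx <- if (T_ > 1) {
    transition_context(model, b$z[-T_], b$y_frac[-T_])
  } else {
    integer(0)
  }
  list(blocks = b, logE = logE, ctx = ctx, T_ = T_)
}

# Transition matrices for each unique context id.
context_matrices <- function(model, ctx_ids) {
  if (inherits(model, "transition_model1")) {
    return(list(`1` = transition_matrix(model)))
  }
  out <- vector("list", length(ctx_ids))
  names(out) <- as.character(ctx_ids)
  for (i in seq_along(ctx_ids)) {
    dc <- decode_context(ctx_ids[i])
    out[[i]] <- transition_matrix(model, z_prev = dc$z, bin = dc$bin)
  }
  out
}

# ---- filtering / smoothing -------------------------------------------------

#' Forward filtering of the belief state
#'
#' Runs the scaled forward recursion of the input-output HMM: the belief at
#' block `t` is the posterior over latent skill given observations
#' `1..t`; the transition into block `t` is driven by the previous block's
#' presented n-level and accuracy (model-2) or is homogeneous (model-1).
#' Also returns the one-step-ahead predicted accuracy for every block (the
#' predictive prior pushed through the item characteristic curve), which is
#' the quantity scored by the evaluation harness.
#'
#' @param seq A [participant_sequence()].
#' @param model A transition model.
#' @param irt An [irt_params()] object.
#' @return A list with `belief` (T x N matrix of filtered posteriors),
#'   `loglik` (total observed-data log-likelihood), `pred_acc` (length-T
#'   one-step-ahead expected accuracies; block 1 uses the initial
#'   distribution), and `blocks` (the scored blocks).
#' @export
forward_filter <- function(seq, model, irt) {
  prep <- prep_sequence(seq, model, irt)
  fwd <- forward_pass(prep, model, irt)
  list(belief = fwd$alpha, loglik = fwd$loglik, pred_acc = fwd$pred_acc,
       blocks = prep$blocks)
}

forward_pass <- function(prep, model, irt, Mlist = NULL) {
  N <- model$N
  T_ <- prep$T_
  if (is.null(Mlist)) Mlist <- context_matrices(model, unique(prep$ctx))
  icc_grid <- outer(seq_len(N), prep$blocks$z,
                    function(x, z) icc(x, z, irt))  # N x T
  alpha <- matrix(0, T_, N)
  cs <- numeric(T_)
  mx <- numeric(T_)
  pred_acc <- numeric(T_)
  prior <- model$pi
  loglik <- 0
  for (t in seq_len(T_)) {
    if (t > 1) {
      M <- Mlist[[as.character(prep$ctx[t - 1])]]
      prior <- as.numeric(alpha[t - 1, ] %*% M)
    }
    pred_acc[t] <- sum(prior * icc_grid[, t])
    mx[t] <- max(prep$logE[t, ])
    e <- exp(prep$logE[t, ] - mx[t])
    un <- prior * e
    cs[t] <- sum(un)
    if (cs[t] <= 0 || !is.finite(cs[t])) {
      stop(sprintf(
        "numerical degeneracy: emission underflow at block %d (t = %d)",
        prep$blocks$t[t], t), call. = FALSE)
    }
    alpha[t, ] <- un / cs[t]
    loglik <- loglik + log(cs[t]) + mx[t]
  }
  list(alpha = alpha, cs = cs, mx = mx, loglik = loglik,
       pred_acc = pred_acc, Mlist = Mlist)
}

#' Forward-backward smoothing
#'
#' Computes the smoothed marginals `gamma[t, ]` = p(x_t | all observations)
#' and the pairwise posteriors `xi[t, , ]` = p(x_t, x_{t+1} | all
#' observations), honoring the time-varying transition matrices of the
#' history-driven model.
#'
#' @inheritParams forward_filter
#' @return A list with `gamma` (T x N), `xi` ((T-1) x N x N array) and
#'   `loglik`.
#' @export
forward_backward <- function(seq, model, irt) {
  prep <- prep_sequence(seq, model, irt)
  fwd <- forward_pass(prep, model, irt)
  N <- model$N
  T_ <- prep$T_
  beta <- matrix(0, T_, N)
  beta[T_, ] <- 1
  xi <- if (T_ > 1) array(0, dim = c(T_ - 1, N, N)) else
    array(0, dim = c(0, N, N))
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      M <- fwd$Mlist[[as.character(prep$ctx[t])]]
      w <- exp(prep$logE[t + 1, ] - fwd$mx[t + 1]) * beta[t + 1, ] /
        fwd$cs[t + 1]
      beta[t, ] <- as.numeric(M %*% w)
      xi[t, , ] <- (fwd$alpha[t, ] %o% w) * M
    }
  }
  gamma <- fwd$alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi = xi, loglik = fwd$loglik)
}

# ---- tied-parameter M-step -------------------------------------------------

# Row groups: one group per (context, origin state) with its candidate tied
# cells. `cell` is a G x 3 matrix of tied-parameter indices (NA where the
# move is masked or out of range), aligned with dskill in (-1, 0, +1).
build_row_groups <- function(model, ctx_ids) {
  N <- model$N
  m2 <- inherits(model, "transition_model2")
  G <- length(ctx_ids) * N
  cell <- matrix(NA_integer_, G, 3)
  gctx <- integer(G)
  gx <- integer(G)
  g <- 0L
  for (ci in seq_along(ctx_ids)) {
    dc <- if (m2) decode_context(ctx_ids[ci])
    for (x in seq_len(N)) {
      g <- g + 1L
      gctx[g] <- ci
      gx[g] <- x
      for (j in 1:3) {
        dskill <- j - 2L
        xp <- x + dskill
        if (xp < 1 || xp > N) next
        if (m2) {
          dchal <- dc$z - xp
          if (abs(dchal) > 2) next
          cell[g, j] <- j + (dchal + 2L) * 3L + (dc$bin - 1L) * 15L
        } else {
          cell[g, j] <- j
        }
      }
    }
  }
  list(cell = cell, gctx = gctx, gx = gx)
}

# Maximize the expected complete-data transition log-likelihood over the
# tied log-propensities, warm-started at theta0 (GEM step). counts is an
# n_ctx x N x 3 array of expected transition counts.
m_step_transitions <- function(counts, groups, theta0, optim_maxit = 100) {
  cnt <- matrix(0, nrow(groups$cell), 3)
  for (j in 1:3) {
    cnt[, j] <- counts[cbind(groups$gctx, groups$gx, j)]
  }
  cnt[is.na(groups$cell)] <- 0
  keep <- rowSums(cnt) > 0 & rowSums(!is.na(groups$cell)) > 1
  cellk <- groups$cell[keep, , drop = FALSE]
  cntk <- cnt[keep, , drop = FALSE]
  if (!nrow(cellk)) return(theta0)
  rowtot <- rowSums(cntk)
  valid <- !is.na(cellk)
  touched <- sort(unique(cellk[valid]))
  flat_cell <- cellk[valid]
  flat_row <- row(cellk)[valid]

  negll <- function(theta) {
    W <- matrix(-Inf, nrow(cellk), 3)
    W[valid] <- theta[flat_cell]
    mxw <- apply(W, 1, max)
    logZ <- mxw + log(rowSums(exp(W - mxw)))
    -sum(cntk[valid] * (W[valid] - logZ[flat_row]))
  }
  grad <- function(theta) {
    W <- matrix(-Inf, nrow(cellk), 3)
    W[valid] <- theta[flat_cell]
    mxw <- apply(W, 1, max)
    P <- exp(W - mxw)
    P <- P / rowSums(P)
    contrib <- -(cntk[valid] - rowtot[flat_row] * P[valid])
    g <- numeric(length(theta))
    agg <- rowsum(contrib, flat_cell)
    g[as.integer(rownames(agg))] <- agg[, 1]
    g
  }
  res <- stats::optim(theta0, negll, grad, method = "L-BFGS-B",
                      lower = -30, upper = 30,
                      control = list(maxit = optim_maxit))
  theta <- res$par
  # untouched cells keep their previous value; recentre touched ones only
  # jointly (likelihood is invariant to a common shift within each row's
  # cells, so no recentring is strictly needed; keep values bounded).
  theta
}

# ---- EM driver -------------------------------------------------------------

#' Fit the input-output HMM by Baum-Welch EM with tied parameters
#'
#' The E-step pools expected transition counts across all participants into
#' the tied cells (3 for model-1, up to 150 for model-2) using the scaled
#' forward-backward recursions with time-varying transition matrices. The
#' M-step maximizes the expected complete-data log-likelihood of the
#' masked-and-renormalized rows numerically (L-BFGS-B over tied
#' log-propensities, warm-started — a generalized-EM step, so the
#' log-likelihood never decreases), and updates the initial distribution
#' from the pooled first-block smoothed marginals. Iteration stops when the
#' log-likelihood increase drops below `control$tol` (default 0.001) or
#' `control$max_iter` is reached. The item-response parameters are held
#' fixed; see [grid_search_irt()] for their outer optimization.
#'
#' @param cohort An [nback_cohort()] (or list of sequences).
#' @param model_kind `"model1"` (3 tied probabilities) or `"model2"`
#'   (150 tied propensities driven by previous accuracy bin and challenge
#'   gap).
#' @param irt An [irt_params()] object (fixed during EM).
#' @param control An [em_control()] list.
#' @param N Number of latent skill states.
#' @param init Optional transition model to start from.
#' @return An object of class `hmm_fit` with elements `model` (fitted
#'   transition model), `irt`, `model_kind`, `loglik_trace`, `converged`,
#'   `n_iterations`.
#' @export
em_fit <- function(cohort, model_kind = c("model1", "model2"),
                   irt = irt_params(), control = em_control(), N = 10,
                   init = NULL) {
  model_kind <- match.arg(model_kind)
  if (inherits(cohort, "participant_sequence")) cohort <- list(cohort)
  if (!length(cohort)) stop("cohort must be non-empty", call. = FALSE)
  n_restarts <- control$n_restarts
  if (is.null(n_restarts)) n_restarts <- if (model_kind == "model2") 5 else 1

  base_model <- if (!is.null(init)) init else
    if (model_kind == "model1") transition_model1(0.1, 0.8, 0.1, N = N) else
      transition_model2(N = N)
  preps <- lapply(cohort, prep_sequence, model = base_model, irt = irt)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    model_r <- if (r == 1) base_model else
      local_seed(control$seed + r, perturb_model(base_model))
    fit <- em_run(preps, model_r, irt, control)
    if (is.null(best) || max(fit$loglik_trace) > max(best$loglik_trace)) {
      best <- fit
    }
  }
  best$model_kind <- model_kind
  best$irt <- irt
  best$N <- base_model$N
  class(best) <- "hmm_fit"
  best
}

perturb_model <- function(model) {
  if (inherits(model, "transition_model1")) {
    th <- log(model$q) + stats::rnorm(3, 0, 0.5)
    q <- exp(th) / sum(exp(th))
    transition_model1(q[1], q[2], q[3], N = model$N, pi = model$pi)
  } else {
    q <- model$q * exp(stats::rnorm(length(model$q), 0, 0.5))
    transition_model2(q = array(q, dim = dim(model$q)), N = model$N,
                      pi = model$pi)
  }
}

em_run <- function(preps, model, irt, control) {
  N <- model$N
  all_ctx <- sort(unique(unlist(lapply(preps, `[[`, "ctx"))))
  if (!length(all_ctx)) all_ctx <- 1L
  groups <- build_row_groups(model, all_ctx)
  ctx_pos <- function(ctx) match(ctx, all_ctx)
  trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(control$max_iter)) {
    Mlist <- context_matrices(model, all_ctx)
    counts <- array(0, dim = c(length(all_ctx), N, 3))
    pi_acc <- numeric(N)
    ll <- 0
    for (p in preps) {
      fwd <- forward_pass(p, model, irt, Mlist = Mlist)
      ll <- ll + fwd$loglik
      T_ <- p$T_
      if (T_ == 1) {
        pi_acc <- pi_acc + fwd$alpha[1, ]
        next
      }
      beta_next <- rep(1, N)
      ci_seq <- ctx_pos(p$ctx)
      gamma1 <- NULL
      for (t in (T_ - 1):1) {
        ci <- ci_seq[t]
        M <- Mlist[[as.character(p$ctx[t])]]
        w <- exp(p$logE[t + 1, ] - fwd$mx[t + 1]) * beta_next / fwd$cs[t + 1]
        a <- fwd$alpha[t, ]
        counts[ci, , 2] <- counts[ci, , 2] + a * diag(M) * w
        if (N > 1) {
          iu <- seq_len(N - 1)
          counts[ci, iu, 3] <- counts[ci, iu, 3] +
            a[iu] * M[cbind(iu, iu + 1)] * w[iu + 1]
          counts[ci, iu + 1, 1] <- counts[ci, iu + 1, 1] +
            a[iu + 1] * M[cbind(iu + 1, iu)] * w[iu]
        }
        beta_next <- as.numeric(M %*% w)
      }
      g1 <- fwd$alpha[1, ] * beta_next
      pi_acc <- pi_acc + g1 / sum(g1)
    }
    if (!is.finite(ll)) {
      stop("non-finite log-likelihood during EM", call. = FALSE)
    }
    trace <- c(trace, ll)
    if (control$verbose) message(sprintf("iter %d: loglik %.6f", iter, ll))
    if (iter > 1 && (ll - trace[iter - 1]) < control$tol) {
      converged <- TRUE
      break
    }
    # M-step
    theta0 <- if (inherits(model, "transition_model1")) log(model$q) else
      log(pmax(as.numeric(model$q), 1e-12))
    theta <- m_step_transitions(counts, groups, theta0,
                                optim_maxit = control$optim_maxit)
    pi_new <- pi_acc / sum(pi_acc)
    if (inherits(model, "transition_model1")) {
      q <- exp(theta) / sum(exp(theta))
      model <- transition_model1(q[1], q[2], q[3], N = N, pi = pi_new)
    } else {
      q <- exp(theta - max(theta))
      model <- transition_model2(q = array(q, dim = c(3, 5, 10)), N = N,
                                 pi = pi_new)
    }
  }
  list(model = model, loglik_trace = trace, converged = converged,
       n_iterations = length(trace))
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf(
    "Input-output HMM fit (%s, N = %d): %d EM iterations, %sconverged\n",
    x$model_kind, x$N, x$n_iterations, if (x$converged) "" else "NOT "))
  cat(sprintf("  final log-likelihood: %.3f\n", max(x$loglik_trace)))
  print(x$model)
  print(x$irt)
  invisible(x)
}

#' Total cohort log-likelihood under a fitted model
#'
#' @param cohort An [nback_cohort()].
#' @param model A transition model.
#' @param irt An [irt_params()] object.
#' @return Sum of per-participant observed-data log-likelihoods.
#' @export
loglik_cohort <- function(cohort, model, irt) {
  sum(vapply(cohort, function(s) forward_filter(s, model, irt)$loglik,
             numeric(1)))
}

#' Grid search over the item-response hyperparameters
#'
#' Runs [em_fit()] for every grid cell of `(rho, c, d, alpha)` and returns
#' the cell with the highest score: training log-likelihood by default, or
#' held-out log-likelihood when `score = "holdout"` (a seeded
#' participant-level 80:20 split of the cohort).
#'
#' @param cohort An [nback_cohort()].
#' @param model_kind `"model1"` or `"model2"`.
#' @param grid A data.frame with columns `rho`, `c`, `d`, `alpha`; defaults
#'   to [default_irt_grid()].
#' @param control An [em_control()].
#' @param N Number of skill states.
#' @param score `"train"` or `"holdout"`.
#' @param seed Seed for the holdout split.
#' @return A list with `best_fit` (the winning `hmm_fit`), `best_irt`, and
#'   `table` (the grid with a `loglik` column, one row per cell).
#' @export
grid_search_irt <- function(cohort, model_kind = "model1",
                            grid = default_irt_grid(),
                            control = em_control(), N = 10,
                            score = c("train", "holdout"), seed = 1) {
  score <- match.arg(score)
  if (!nrow(grid)) stop("grid must be non-empty", call. = FALSE)
  if (score == "holdout") {
    sp <- split_cohort(cohort, mode = "fraction_80_20", seed = seed)
    train <- sp$train; heldout <- sp$test
  } else {
    train <- cohort; heldout <- NULL
  }
  lls <- numeric(nrow(grid))
  fits <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    irt <- irt_params(grid$rho[i], grid$c[i], grid$d[i], grid$alpha[i])
    fit <- em_fit(train, model_kind, irt = irt, control = control, N = N)
    fits[[i]] <- fit
    lls[i] <- if (score == "train") max(fit$loglik_trace) else
      loglik_cohort(heldout, fit$model, irt)
  }
  best <- which.max(lls)
  grid$loglik <- lls
  list(best_fit = fits[[best]], best_irt = fits[[best]]$irt, table = grid)
}

#' Default hyperparameter grid for the 4PL observation model
#'
#' @return A data.frame covering rho 1.0-2.5 (step 0.1), c in {0, 0.05,
#'   0.1}, d in {0.9, 0.95, 1.0}, alpha in {1, 3, 5, 8, 11.56, 20}.
#' @export
default_irt_grid <- function() {
  expand.grid(rho = seq(1.0, 2.5, by = 0.1), c = c(0, 0.05, 0.1),
              d = c(0.9, 0.95, 1.0), alpha = c(1, 3, 5, 8, 11.56, 20),
              KEEP.OUT.ATTRS = FALSE)
}

#' One-step-ahead expected block accuracy
#'
#' Propagates a filtered belief through the transition driven by the
#' previous block's observables, then takes the expectation of the item
#' characteristic curve at the next presented level. With `belief_prev =
#' NULL` the initial distribution is used directly (block 1).
#'
#' @param belief_prev Filtered belief over skill states after the previous
#'   block (length-N probability vector), or `NULL` for the first block.
#' @param y_prev Previous block accuracy fraction.
#' @param z_prev Previous presented n-level.
#' @param z_next Next presented n-level.
#' @param m_next Number of targets in the next block (unused by the
#'   expectation — the beta-binomial is mean-preserving — but kept for
#'   interface symmetry).
#' @param model A transition model.
#' @param irt An [irt_params()] object.
#' @return Expected accuracy fraction, inside `(c, d)`.
#' @export
predict_accuracy <- function(belief_prev, y_prev, z_prev, z_next,
                             m_next = NULL, model, irt) {
  N <- model$N
  if (is.null(belief_prev)) {
    prior <- model$pi
  } else {
    stopifnot(length(belief_prev) == N)
    prior <- numeric(N)
    for (x in seq_len(N)) {
      if (belief_prev[x] > 0) {
        prior <- prior +
          belief_prev[x] * transition_row(model, x, z_prev, y_prev)
      }
    }
  }
  sum(prior * icc(seq_len(N), z_next, irt))
}

#' Point estimate of the skill trajectory
#'
#' Argmax of the filtered belief at every block; ties break toward the
#' lower skill level (conservative placement).
#'
#' @inheritParams forward_filter
#' @return Integer vector of skill states, one per scored block.
#' @export
skill_trajectory <- function(seq, model, irt) {
  bel <- forward_filter(seq, model, irt)$belief
  apply(bel, 1, which.max)
}

# ---- serialization ---------------------------------------------------------

#' Write a fitted HMM to JSON
#'
#' @param fit An `hmm_fit` object.
#' @param path Output path.
#' @export
write_hmm_model <- function(fit, path) {
  stopifnot(inherits(fit, "hmm_fit"))
  obj <- list(type = "hmm", model_kind = fit$model_kind, N = fit$N,
              q = as.numeric(fit$model$q), pi = fit$model$pi,
              irt = unclass(fit$irt),
              fit = list(n_iterations = fit$n_iterations,
                         converged = fit$converged,
                         loglik_trace = fit$loglik_trace))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted HMM from JSON
#'
#' @param path Path written by [write_hmm_model()].
#' @return An `hmm_fit` object.
#' @export
read_hmm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$type, "hmm"))
  irt <- irt_params(obj$irt$rho, obj$irt$c, obj$irt$d, obj$irt$alpha)
  model <- if (obj$model_kind == "model1") {
    transition_model1(obj$q[1], obj$q[2], obj$q[3], N = obj$N, pi = obj$pi)
  } else {
    transition_model2(q = array(obj$q, dim = c(3, 5, 10)), N = obj$N,
                      pi = obj$pi)
  }
  structure(list(model = model, irt = irt, model_kind = obj$model_kind,
                 N = obj$N, loglik_trace = obj$fit$loglik_trace,
                 converged = obj$fit$converged,
                 n_iterations = obj$fit$n_iterations),
            class = "hmm_fit")
}
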