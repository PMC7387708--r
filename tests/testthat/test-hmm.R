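irt_toy <- irt_params(rho = 1.6, c = 0, d = 1, alpha = 11.56)

toy_seq <- function() {
  make_seq(z = c(2, 3, 3, 2), tp = c(8, 4, 7, 10), fn = c(2, 6, 4, 2),
           fp = c(1, 2, 0, 1))
}

test_that("single-block filtering is Bayes rule on the prior", {
  m <- transition_model1(0.1, 0.8, 0.1, N = 3, pi = c(0.5, 0.3, 0.2))
  s <- make_seq(z = 2, tp = 7, fn = 3, fp = 1)
  ff <- forward_filter(s, m, irt_toy)
  lik <- exp(emission_log_prob(s$blocks$y_succ, s$blocks$n_targets, 1:3, 2,
                               irt_toy))
  post <- m$pi * lik / sum(m$pi * lik)
  expect_equal(as.numeric(ff$belief[1, ]), post, tolerance = 1e-12)
  expect_equal(ff$loglik, log(sum(m$pi * lik)), tolerance = 1e-12)
})

test_that("filtering matches exhaustive path enumeration (both model kinds)", {
  s <- toy_seq()
  models <- list(
    transition_model1(0.15, 0.7, 0.15, N = 3, pi = c(0.6, 0.3, 0.1)),
    {
      set.seed(7)
      transition_model2(q = array(runif(150, 0.2, 2), dim = c(3, 5, 10)),
                        N = 3, pi = c(0.6, 0.3, 0.1))
    })
  for (m in models) {
    ff <- forward_filter(s, m, irt_toy)
    expect_equal(ff$loglik, oracle_loglik(s, m, irt_toy), tolerance = 1e-9)
    for (t in 1:4) {
      expect_equal(as.numeric(ff$belief[t, ]),
                   oracle_filtered(s, m, irt_toy, t), tolerance = 1e-9)
    }
  }
})

test_that("uninformative emissions let the belief evolve by transitions alone", {
  # c = d - eps makes the ICC nearly flat: likelihood carries no information
  flat <- irt_params(rho = 1.6, c = 0.699999, d = 0.7, alpha = 5)
  m <- transition_model1(0.2, 0.6, 0.2, N = 4, pi = c(1, 0, 0, 0))
  s <- make_seq(z = c(2, 2, 2), tp = c(6, 7, 5), fn = c(4, 3, 5),
                fp = c(0, 0, 0))
  ff <- forward_filter(s, m, flat)
  bel <- m$pi
  M <- skilltrackr:::transition_matrix(m)
  for (t in 1:3) {
    expect_equal(as.numeric(ff$belief[t, ]), bel, tolerance = 1e-4)
    bel <- as.numeric(bel %*% M)
  }
})

test_that("smoothing matches enumeration and is self-consistent", {
  s <- toy_seq()
  set.seed(13)
  m2 <- transition_model2(q = array(runif(150, 0.2, 2), dim = c(3, 5, 10)),
                          N = 3, pi = c(0.5, 0.3, 0.2))
  for (m in list(transition_model1(0.1, 0.8, 0.1, N = 3), m2)) {
    fb <- forward_backward(s, m, irt_toy)
    or <- oracle_smoothed(s, m, irt_toy)
    expect_equal(fb$gamma, or$gamma, tolerance = 1e-9)
    expect_equal(fb$xi, or$xi, tolerance = 1e-9)
    # gamma_T equals the final filtered belief
    ff <- forward_filter(s, m, irt_toy)
    expect_equal(fb$gamma[4, ], as.numeric(ff$belief[4, ]),
                 tolerance = 1e-10)
    # per-t normalization and xi -> gamma marginalization
    expect_equal(rowSums(fb$gamma), rep(1, 4), tolerance = 1e-10)
    for (t in 1:3) {
      expect_equal(rowSums(fb$xi[t, , ]), fb$gamma[t, ], tolerance = 1e-10)
      expect_equal(colSums(fb$xi[t, , ]), fb$gamma[t + 1, ],
                   tolerance = 1e-10)
    }
  }
})

test_that("one EM iteration never decreases the cohort log-likelihood", {
  co <- toy_cohort(n = 6, T_ = 12, seed = 21)
  for (kind in c("model1", "model2")) {
    fit <- em_fit(co, kind, irt = irt_toy,
                  control = em_control(max_iter = 8, n_restarts = 1))
    expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  }
})

test_that("model-1 EM recovers generating transition probabilities", {
  gen <- transition_model1(0.05, 0.9, 0.05, N = 10)
  prof <- participant_profile("hmm_generative", transition = gen,
                              start_skill = 2, irt = irt_toy, fp_rate = 0)
  co <- simulate_cohort(60, session_plan(n_sessions = 6,
                                         blocks_per_session = 10),
                        prof, algorithm_spec("blockwise_85_70"), seed = 31)
  fit <- em_fit(co, "model1", irt = irt_toy,
                control = em_control(max_iter = 40, n_restarts = 1))
  expect_equal(unname(fit$model$q), c(0.05, 0.9, 0.05), tolerance = 0.035)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
})

test_that("belief support spreads by at most one level per step", {
  m <- transition_model1(0.3, 0.4, 0.3, N = 8,
                         pi = c(0, 0, 1, 0, 0, 0, 0, 0))
  s <- make_seq(z = c(3, 3, 3, 3), tp = c(7, 8, 6, 9), fn = c(3, 2, 4, 1),
                fp = c(0, 1, 0, 0))
  ff <- forward_filter(s, m, irt_toy)
  for (t in 1:4) {
    support <- which(ff$belief[t, ] > 1e-12)
    expect_true(all(abs(support - 3) <= t))
  }
})

test_that("skill trajectory is the filtered argmax with low-tie preference", {
  m <- transition_model1(0, 1, 0, N = 5, pi = c(0, 0, 1, 0, 0))
  s <- make_seq(z = c(3, 3), tp = c(7, 8), fn = c(3, 2), fp = c(0, 0))
  expect_equal(skill_trajectory(s, m, irt_toy), c(3, 3))
  # strong emissions track simulated truth on most blocks
  sharp <- irt_params(rho = 5, c = 0, d = 1, alpha = 50)
  gen <- transition_model1(0.05, 0.9, 0.05, N = 10)
  prof <- participant_profile("hmm_generative", transition = gen,
                              start_skill = 3, irt = sharp, fp_rate = 0)
  co <- simulate_cohort(5, session_plan(n_sessions = 5,
                                        blocks_per_session = 8),
                        prof, algorithm_spec("blockwise_85_70"), seed = 41)
  hits <- unlist(lapply(co, function(s) {
    skill_trajectory(s, gen, sharp) == s$true_skill
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("one-step-ahead accuracy prediction matches the path-sum oracle", {
  s <- toy_seq()
  m <- transition_model1(0.15, 0.7, 0.15, N = 3, pi = c(0.6, 0.3, 0.1))
  ff <- forward_filter(s, m, irt_toy)
  b <- s$blocks
  for (t in 2:4) {
    pred <- predict_accuracy(ff$belief[t - 1, ], b$y_frac[t - 1],
                             b$z[t - 1], b$z[t], model = m, irt = irt_toy)
    # oracle: filtered belief from enumeration, propagated by hand
    bel <- oracle_filtered(s, m, irt_toy, t - 1)
    prior <- numeric(3)
    for (x in 1:3) {
      prior <- prior + bel[x] *
        transition_row(m, x, b$z[t - 1], b$y_frac[t - 1])
    }
    expect_equal(pred, sum(prior * icc(1:3, b$z[t], irt_toy)),
                 tolerance = 1e-9)
    expect_equal(pred, ff$pred_acc[t], tolerance = 1e-9)
  }
  # point mass at x = z_next with identity transitions: ICC midpoint
  ident <- transition_model1(0, 1, 0, N = 5)
  expect_equal(predict_accuracy(c(0, 0, 1, 0, 0), 0.5, 3, 3,
                                model = ident, irt = irt_toy), 0.5)
  # convex combination of ICC values stays inside (c, d)
  pc <- irt_params(rho = 1.2, c = 0.1, d = 0.9, alpha = 5)
  val <- predict_accuracy(rep(0.2, 5), 0.3, 2, 4, model = ident, irt = pc)
  expect_true(val > 0.1 && val < 0.9)
})

test_that("a one-cell grid search reduces to a plain EM fit", {
  co <- toy_cohort(n = 4, T_ = 10, seed = 51)
  grid <- data.frame(rho = 1.6, c = 0, d = 1, alpha = 11.56)
  gs <- grid_search_irt(co, "model1", grid = grid,
                        control = em_control(max_iter = 10, n_restarts = 1))
  fit <- em_fit(co, "model1", irt = irt_toy,
                control = em_control(max_iter = 10, n_restarts = 1))
  expect_equal(gs$best_fit$model$q, fit$model$q, tolerance = 1e-12)
  expect_equal(nrow(gs$table), 1L)
  expect_error(grid_search_irt(co, "model1", grid = grid[0, ]), "non-empty")
})

test_that("grid search recovers the generating hyperparameter cell", {
  grid <- expand.grid(rho = c(1.2, 1.6, 2.0), c = 0, d = 1,
                      alpha = c(3, 11.56), KEEP.OUT.ATTRS = FALSE)
  gen <- transition_model1(0.05, 0.9, 0.05, N = 10)
  hit <- logical(6)
  for (r in 1:6) {
    prof <- participant_profile("hmm_generative", transition = gen,
                                start_skill = 2, irt = irt_toy, fp_rate = 0)
    co <- simulate_cohort(20, session_plan(n_sessions = 4,
                                           blocks_per_session = 10),
                          prof, algorithm_spec("blockwise_85_70"),
                          seed = 60 + r)
    gs <- grid_search_irt(co, "model1", grid = grid,
                          control = em_control(max_iter = 15,
                                               n_restarts = 1))
    best <- gs$table[which.max(gs$table$loglik), ]
    # generating cell or an immediate grid neighbor
    hit[r] <- abs(match(best$rho, c(1.2, 1.6, 2.0)) - 2) <= 1 &&
      best$alpha == 11.56
  }
  expect_gte(sum(hit), 5)
})

test_that("grid search reports one log-likelihood per cell", {
  co <- toy_cohort(n = 4, T_ = 10, seed = 71)
  grid <- expand.grid(rho = c(1.4, 1.8), c = 0, d = 1, alpha = c(5, 11.56),
                      KEEP.OUT.ATTRS = FALSE)
  gs <- grid_search_irt(co, "model1", grid = grid,
                        control = em_control(max_iter = 5, n_restarts = 1),
                        score = "holdout", seed = 3)
  expect_equal(nrow(gs$table), 4L)
  expect_true(all(is.finite(gs$table$loglik)))
})

test_that("fitted HMMs round-trip through JSON", {
  co <- toy_cohort(n = 4, T_ = 10, seed = 81)
  for (kind in c("model1", "model2")) {
    fit <- em_fit(co, kind, irt = irt_toy,
                  control = em_control(max_iter = 5, n_restarts = 1))
    path <- tempfile(fileext = ".json")
    write_hmm_model(fit, path)
    back <- read_hmm_model(path)
    expect_equal(back$model$q, fit$model$q, tolerance = 1e-12)
    expect_equal(back$model$pi, fit$model$pi, tolerance = 1e-12)
    expect_equal(unclass(back$irt), unclass(fit$irt))
    s <- co[[1]]
    expect_equal(forward_filter(s, back$model, back$irt)$loglik,
                 forward_filter(s, fit$model, fit$irt)$loglik,
                 tolerance = 1e-10)
    unlink(path)
  }
})
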