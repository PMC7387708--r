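#' Split a cohort into training and test sets
#'
#' The fraction split is participant-level (one participant's blocks are
#' never divided), seeded, 80:20 by participant count with the remainder
#' going to the training set. The condition split assigns participants by
#' their recorded condition label.
#'
#' @param cohort An [nback_cohort()].
#' @param mode `"fraction_80_20"` or `"by_condition"`.
#' @param seed Seed for the random fraction split.
#' @param test_condition For `by_condition`: the condition label(s) forming
#'   the test set; everything else trains.
#' @return A list with `train` and `test` cohorts.
#' @export
split_cohort <- function(cohort, mode = c("fraction_80_20", "by_condition"),
                         seed = 1, test_condition = NULL) {
  mode <- match.arg(mode)
  n <- length(cohort)
  if (n < 2) stop("cohort must have at least 2 participants", call. = FALSE)
  if (mode == "fraction_80_20") {
    n_test <- max(1L, floor(n * 0.2))
    test_idx <- local_seed(seed, sample.int(n, n_test))
  } else {
    if (is.null(test_condition)) {
      stop("by_condition splits need `test_condition`", call. = FALSE)
    }
    conds <- vapply(cohort, function(s) s$condition %||% NA_character_,
                    character(1))
    test_idx <- which(conds %in% test_condition)
    if (!length(test_idx) || length(test_idx) == n) {
      stop("condition split leaves an empty train or test set",
           call. = FALSE)
    }
  }
  list(train = cohort[-test_idx], test = cohort[test_idx])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-step-ahead block predictions from a fitted model
#'
#' Generic: every fitted tracker (`hmm_fit`, `ukf_fit`, `lstm_fit`) returns
#' its causal one-step-ahead predicted accuracy (and, where the model
#' predicts it, n-level) for each block of a sequence.
#'
#' @param object A fitted model.
#' @param seq A [participant_sequence()].
#' @param ... Method-specific arguments.
#' @return A data.frame with columns `t`, `pred_acc`, `obs_acc` (rows with
#'   `NA` predictions are unscored, e.g. the warm-up window of the LSTM).
#' @export
predict_blocks <- function(object, seq, ...) UseMethod("predict_blocks")

#' @export
predict_blocks.hmm_fit <- function(object, seq, ...) {
  ff <- forward_filter(seq, object$model, object$irt)
  data.frame(t = ff$blocks$t, pred_acc = ff$pred_acc,
             obs_acc = ff$blocks$y_frac)
}

#' Score a model's one-step-ahead accuracy predictions
#'
#' Per-block squared error between predicted and observed block accuracy
#' (both fractions), summarized as the per-participant mean squared error
#' and the pooled root-mean-square error in percent (RMSE x 100, pooled
#' over all scored blocks). Blocks with undefined accuracy or without a
#' prediction are excluded and counted.
#'
#' @param model_handle A fitted model with a [predict_blocks()] method.
#' @param test_cohort An [nback_cohort()].
#' @param include_first_block Score the first block (predicted from the
#'   initial distribution / initial state)? Default `TRUE`.
#' @return An `evaluation_report`: `per_participant_mse`,
#'   `pooled_rmse_pct`, `n_blocks_scored`, `n_blocks_excluded`, `model` and
#'   `split` descriptors.
#' @export
score_model <- function(model_handle, test_cohort,
                        include_first_block = TRUE) {
  if (inherits(test_cohort, "participant_sequence")) {
    test_cohort <- nback_cohort(list(test_cohort))
  }
  sq_err <- list(); excluded <- 0L
  for (s in test_cohort) {
    pb <- predict_blocks(model_handle, s)
    if (!include_first_block) pb <- pb[-1, , drop = FALSE]
    ok <- !is.na(pb$pred_acc) & !is.na(pb$obs_acc)
    excluded <- excluded + sum(!ok)
    sq_err[[s$participant_id]] <- (pb$pred_acc[ok] - pb$obs_acc[ok])^2
  }
  n_scored <- sum(lengths(sq_err))
  if (n_scored == 0L) stop("no scorable blocks", call. = FALSE)
  per_mse <- vapply(sq_err, function(e) if (length(e)) mean(e) else NA_real_,
                    numeric(1))
  pooled <- sqrt(mean(unlist(sq_err)))
  structure(list(per_participant_mse = per_mse,
                 pooled_rmse_pct = 100 * pooled,
                 n_blocks_scored = n_scored,
                 n_blocks_excluded = excluded,
                 model = model_descriptor(model_handle),
                 split = sprintf("%d participants scored",
                                 length(test_cohort))),
            class = "evaluation_report")
}

model_descriptor <- function(m) {
  if (inherits(m, "hmm_fit")) paste0("iohmm-", m$model_kind)
  else if (inherits(m, "ukf_fit")) "ukf"
  else if (inherits(m, "lstm_fit")) "lstm"
  else class(m)[1]
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation of %s (%s)\n", x$model, x$split))
  cat(sprintf("  pooled test RMSE: %.2f%% over %d blocks (%d excluded)\n",
              x$pooled_rmse_pct, x$n_blocks_scored, x$n_blocks_excluded))
  cat(sprintf("  per-participant MSE: median %.4f, range %.4f-%.4f\n",
              stats::median(x$per_participant_mse),
              min(x$per_participant_mse), max(x$per_participant_mse)))
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fit and compare the trackers on one dataset
#'
#' Convenience harness: fits HMM model-1, HMM model-2, and optionally the
#' UKF and LSTM baselines on the training cohort and scores each on the
#' test cohort.
#'
#' @param train,test [nback_cohort()] objects.
#' @param irt An [irt_params()] object for the HMMs.
#' @param control An [em_control()].
#' @param N Number of skill states.
#' @param include Character vector of models to run; any of `"hmm1"`,
#'   `"hmm2"`, `"ukf"`, `"lstm"`.
#' @param seed Seed forwarded to the stochastic fitters.
#' @return A data.frame with one row per model: `model`,
#'   `pooled_rmse_pct`, `n_blocks_scored`.
#' @export
compare_models <- function(train, test, irt = irt_params(),
                           control = em_control(), N = 10,
                           include = c("hmm1", "hmm2"), seed = 1) {
  rows <- list()
  if ("hmm1" %in% include) {
    f <- em_fit(train, "model1", irt = irt, control = control, N = N)
    rows$hmm1 <- score_model(f, test)
  }
  if ("hmm2" %in% include) {
    f <- em_fit(train, "model2", irt = irt, control = control, N = N)
    rows$hmm2 <- score_model(f, test)
  }
  if ("ukf" %in% include) {
    f <- ukf_em_fit(train, control = ukf_em_control(seed = seed))
    rows$ukf <- score_model(f, test)
  }
  if ("lstm" %in% include) {
    cfg <- lstm_config(seed = seed)
    ds <- make_windows(train, cfg)
    f <- train_lstm(ds, cfg)
    rows$lstm <- score_model(f, test)
  }
  data.frame(model = names(rows),
             pooled_rmse_pct = vapply(rows, `[[`, numeric(1),
                                      "pooled_rmse_pct"),
             n_blocks_scored = vapply(rows, `[[`, numeric(1),
                                      "n_blocks_scored"),
             row.names = NULL)
}
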