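#' Item-response parameters of the block-accuracy observation model
#'
#' Bundles the static parameters of the four-parameter logistic (4PL) item
#' characteristic curve together with the beta concentration that governs
#' block-to-block overdispersion.
#'
#' @param rho Discrimination (slope) of the logistic curve; must be positive.
#'   Larger values make block accuracy a sharper function of the gap between
#'   skill and presented n-level.
#' @param c Guessing floor: the accuracy approached when the task is far too
#'   hard. In `[0, 1)`.
#' @param d Carelessness ceiling: the accuracy approached when the task is far
#'   too easy. In `(c, 1]`.
#' @param alpha Concentration of the per-block realized-ability beta
#'   distribution; must be positive. Small values mean strong within-block
#'   coupling (overdispersion); as `alpha` grows the emission approaches a
#'   plain binomial.
#'
#' @return An object of class `irt_params`.
#' @examples
#' irt_params(rho = 1.6, c = 0, d = 1, alpha = 11.56)
#' @export
irt_params <- function(rho = 1.6, c = 0, d = 1, alpha = 11.56) {
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho),
            is.numeric(c), length(c) == 1L,
            is.numeric(d), length(d) == 1L,
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (rho <= 0) stop("`rho` must be > 0", call. = FALSE)
  if (c < 0 || c >= 1) stop("`c` must be in [0, 1)", call. = FALSE)
  if (d <= c || d > 1) stop("`d` must be in (c, 1]", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  structure(list(rho = rho, c = c, d = d, alpha = alpha),
            class = "irt_params")
}

#' @export
print.irt_params <- function(x, ...) {
  cat(sprintf("4PL IRT parameters: rho = %g, c = %g, d = %g, alpha = %g\n",
              x$rho, x$c, x$d, x$alpha))
  invisible(x)
}

#' Block accuracy from trial outcome counts
#'
#' Performance metric for one training block: hits over hits plus misses plus
#' false alarms, `tp / (tp + fn + fp)`. Correct rejections do not enter.
#'
#' @param counts A [trial_counts()] object, or a list/data.frame with numeric
#'   fields `tp`, `fn`, `fp` (vectorized).
#' @return Accuracy fraction(s) in `[0, 1]`; `NA` where the denominator is
#'   zero (no targets presented and no false alarms), in which case a warning
#'   of class `skilltrackr_undefined_accuracy` is signalled.
#' @examples
#' acc_block(trial_counts(tp = 8, fn = 1, fp = 1, n_trials = 30, n_targets = 9))
#' @export
acc_block <- function(counts) {
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp
  denom <- tp + fn + fp
  out <- ifelse(denom > 0, tp / denom, NA_real_)
  if (anyNA(out)) {
    warning(condition_message_undefined(sum(is.na(out))))
  }
  out
}

condition_message_undefined <- function(n) {
  structure(
    class = c("skilltrackr_undefined_accuracy", "warning", "condition"),
    list(message = sprintf(
      "%d block(s) have tp + fn + fp = 0; accuracy undefined (NA)", n),
      call = NULL))
}

#' Item characteristic curve (4PL logistic)
#'
#' Probability of a correct response to a single trial at presented n-level
#' `z` for a participant with latent skill `x`:
#' `c + (d - c) / (1 + exp(-rho * (x - z)))`. Strictly increasing in `x`,
#' strictly decreasing in `z`, bounded in `(c, d)`.
#'
#' @param x Latent skill (may be fractional; vectorized).
#' @param z Presented n-level (vectorized).
#' @param params An [irt_params()] object.
#' @return Probability of a correct trial response.
#' @examples
#' icc(4, 4, irt_params())          # midpoint: (c + d) / 2
#' icc(1:10, 5, irt_params())
#' @export
icc <- function(x, z, params) {
  stopifnot(inherits(params, "irt_params"))
  params$c + (params$d - params$c) / (1 + exp(-params$rho * (x - z)))
}

#' Beta-binomial emission log-probability of a block success count
#'
#' Marginal log-probability of observing `y_succ` effective successes out of
#' `m` targets, for latent skill `x` at presented level `z`. The per-block
#' realized ability is beta-distributed with mean `a = icc(x, z, params)` and
#' concentration `alpha`; marginalizing it out of the binomial trial model
#' yields the beta-binomial mass
#' `choose(m, y) * B(y + alpha*a, m - y + alpha*(1-a)) / B(alpha*a, alpha*(1-a))`,
#' evaluated entirely through `lchoose`/`lbeta` (log-gamma), never the raw
#' gamma function. `a` is clamped to `[1e-6, 1 - 1e-6]` so the beta
#' parameters stay positive when `c = 0` or `d = 1`.
#'
#' @param y_succ Effective success count(s), integer in `[0, m]`.
#' @param m Number of targets in the block (>= 1).
#' @param x Latent skill (vectorized; recycled against `y_succ`).
#' @param z Presented n-level.
#' @param params An [irt_params()] object.
#' @return Log-probability (vectorized over the longest argument).
#' @examples
#' p <- exp(emission_log_prob(0:10, 10, x = 4, z = 5, irt_params()))
#' sum(p)  # normalizes to 1
#' @export
emission_log_prob <- function(y_succ, m, x, z, params) {
  stopifnot(inherits(params, "irt_params"))
  if (any(m < 1)) stop("`m` must be >= 1", call. = FALSE)
  if (any(y_succ < 0) || any(y_succ > m)) {
    stop("`y_succ` must lie in [0, m]", call. = FALSE)
  }
  a <- icc(x, z, params)
  a <- pmin(pmax(a, 1e-6), 1 - 1e-6)
  al <- params$alpha
  lchoose(m, y_succ) +
    lbeta(y_succ + al * a, m - y_succ + al * (1 - a)) -
    lbeta(al * a, al * (1 - a))
}

#' Discretize a block accuracy into one of ten bins
#'
#' Bin `k` covers `[(k-1)/10, k/10)`; the top bin is closed so an accuracy of
#' exactly 1 falls in bin 10. Used as the performance tag of the
#' history-driven transition model.
#'
#' @param y_frac Accuracy fraction(s) in `[0, 1]`.
#' @return Integer bin index in `1..10`.
#' @examples
#' bin_accuracy(c(0, 0.85, 1))
#' @export
bin_accuracy <- function(y_frac) {
  if (any(!is.finite(y_frac)) || any(y_frac < 0) || any(y_frac > 1)) {
    stop("`y_frac` must be finite and in [0, 1]", call. = FALSE)
  }
  as.integer(pmin(floor(y_frac * 10) + 1, 10))
}
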