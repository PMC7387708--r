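#' Homogeneous tied transition model (model-1)
#'
#' Latent skill moves by at most one level per block; the three tied
#' probabilities of moving down one level, staying, and moving up one level
#' are shared by every state and every block. Rows at the boundary states
#' (1 and `N`) are renormalized over the feasible neighbors.
#'
#' @param q_down,q_stay,q_up Transition probabilities; must sum to 1.
#' @param N Number of discrete skill states (default 10).
#' @param pi Initial distribution over skill states; default uniform.
#' @return An object of class `transition_model1`.
#' @examples
#' transition_model1(0.05, 0.9, 0.05)
#' @export
transition_model1 <- function(q_down = 0.1, q_stay = 0.8, q_up = 0.1,
                              N = 10, pi = NULL) {
  q <- c(q_down, q_stay, q_up)
  if (any(q < 0) || abs(sum(q) - 1) > 1e-12) {
    stop("q_down + q_stay + q_up must equal 1, all >= 0", call. = FALSE)
  }
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  if (is.null(pi)) pi <- rep(1 / N, N)
  check_pi(pi, N)
  structure(list(q = q, pi = pi, N = as.integer(N)),
            class = c("transition_model1", "skill_transition_model"))
}

#' History-driven tied transition tensor (model-2)
#'
#' Transition propensities indexed by the skill change `dskill = x' - x` in
#' `{-1, 0, +1}`, the challenge tag `dchal = z_prev - x'` in `{-2..2}`, and
#' the accuracy bin of the previous block in `1..10`: 3 x 5 x 10 = 150 tied
#' parameters. Entries are non-negative propensities; each realized row is
#' masked by adjacency and `|z_prev - x'| <= 2`, then renormalized. If a
#' row's every candidate is masked, it degenerates to a self-transition.
#'
#' @param q 3 x 5 x 10 array of non-negative propensities (default all 1,
#'   i.e. uniform over feasible moves).
#' @param N Number of skill states (default 10).
#' @param pi Initial distribution; default uniform.
#' @return An object of class `transition_model2`.
#' @export
transition_model2 <- function(q = NULL, N = 10, pi = NULL) {
  if (is.null(q)) q <- array(1, dim = c(3, 5, 10))
  q <- as.array(q)
  if (!identical(dim(q), c(3L, 5L, 10L))) {
    stop("q must be a 3 x 5 x 10 array", call. = FALSE)
  }
  if (any(q < 0) || any(!is.finite(q))) {
    stop("q entries must be finite and non-negative", call. = FALSE)
  }
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  if (is.null(pi)) pi <- rep(1 / N, N)
  check_pi(pi, N)
  dimnames(q) <- list(dskill = c("-1", "0", "+1"),
                      dchal = c("-2", "-1", "0", "+1", "+2"),
                      bin = as.character(1:10))
  structure(list(q = q, pi = pi, N = as.integer(N)),
            class = c("transition_model2", "skill_transition_model"))
}

check_pi <- function(pi, N) {
  if (length(pi) != N || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be a length-N distribution", call. = FALSE)
  }
  invisible(pi)
}

#' @export
print.transition_model1 <- function(x, ...) {
  cat(sprintf("Tied skill transition model-1 (N = %d states, 3 parameters)\n",
              x$N))
  cat(sprintf("  P(down) = %.4f  P(stay) = %.4f  P(up) = %.4f\n",
              x$q[1], x$q[2], x$q[3]))
  invisible(x)
}

#' @export
print.transition_model2 <- function(x, ...) {
  cat(sprintf(
    "History-driven skill transition model-2 (N = %d states, %d tied parameters)\n",
    x$N, length(x$q)))
  invisible(x)
}

#' Number of tied transition parameters
#'
#' @param model A transition model.
#' @return Integer count: 3 for model-1, 150 for model-2.
#' @export
n_transition_parameters <- function(model) {
  length(model$q)
}

#' One-step transition distribution from a given state
#'
#' Builds the distribution of the next latent skill given the previous skill
#' and, for model-2, the previous block's presented level and accuracy.
#' Support is restricted to `{x_prev - 1, x_prev, x_prev + 1}` intersected
#' with `{1..N}`; model-2 additionally zeroes candidates with
#' `|z_prev - x'| > 2`. The surviving entries are renormalized; a fully
#' masked model-2 row falls back to staying at `x_prev`.
#'
#' @param model A [transition_model1()] or [transition_model2()].
#' @param x_prev Previous latent skill state in `1..N`.
#' @param z_prev Presented n-level of the previous block (ignored by
#'   model-1).
#' @param y_prev_frac Accuracy of the previous block in `[0, 1]` (ignored by
#'   model-1).
#' @return Length-`N` probability vector over the next skill state.
#' @examples
#' m <- transition_model1(0.1, 0.8, 0.1, N = 5)
#' transition_row(m, x_prev = 1)  # boundary row, renormalized over {1, 2}
#' @export
transition_row <- function(model, x_prev, z_prev = NULL, y_prev_frac = NULL) {
  N <- model$N
  if (length(x_prev) != 1L || x_prev < 1 || x_prev > N ||
      x_prev != round(x_prev)) {
    stop("x_prev must be a single state in 1..N", call. = FALSE)
  }
  row <- numeric(N)
  cand <- intersect((x_prev - 1):(x_prev + 1), seq_len(N))
  if (inherits(model, "transition_model1")) {
    w <- model$q[cand - x_prev + 2L]
  } else {
    if (is.null(z_prev) || is.null(y_prev_frac)) {
      stop("model-2 transition rows need z_prev and y_prev_frac",
           call. = FALSE)
    }
    bin <- bin_accuracy(y_prev_frac)
    dchal <- z_prev - cand
    ok <- abs(dchal) <= 2
    w <- numeric(length(cand))
    if (any(ok)) {
      idx <- cbind(cand[ok] - x_prev + 2L, dchal[ok] + 3L, bin)
      w[ok] <- model$q[idx]
    }
  }
  s <- sum(w)
  if (s <= 0) {
    row[x_prev] <- 1  # all candidates masked: stay put
    return(row)
  }
  row[cand] <- w / s
  row
}

# Full N x N transition matrix for a given (z_prev, bin) context.
# For model-1 the context arguments are ignored.
transition_matrix <- function(model, z_prev = NULL, bin = NULL) {
  N <- model$N
  M <- matrix(0, N, N)
  if (inherits(model, "transition_model1")) {
    for (x in seq_len(N)) {
      cand <- intersect((x - 1):(x + 1), seq_len(N))
      w <- model$q[cand - x + 2L]
      M[x, cand] <- w / sum(w)
    }
  } else {
    for (x in seq_len(N)) {
      cand <- intersect((x - 1):(x + 1), seq_len(N))
      dchal <- z_prev - cand
      ok <- abs(dchal) <= 2
      w <- numeric(length(cand))
      if (any(ok)) {
        idx <- cbind(cand[ok] - x + 2L, dchal[ok] + 3L, bin)
        w[ok] <- model$q[idx]
      }
      s <- sum(w)
      if (s <= 0) M[x, x] <- 1 else M[x, cand] <- w / s
    }
  }
  M
}

# Context id for the transition driving inputs of a block: model-1 has a
# single context; model-2 contexts are keyed by (clamped z_prev, accuracy
# bin). z_prev is clamped to 1..(N+3): every z beyond N+2 masks all
# feasible candidates (dchal > 2), so those rows behave identically.
transition_context <- function(model, z_prev, y_frac_prev) {
  if (inherits(model, "transition_model1")) {
    rep(1L, length(z_prev))
  } else {
    zc <- pmin(pmax(as.integer(z_prev), 1L), model$N + 3L)
    (zc - 1L) * 10L + bin_accuracy(y_frac_prev)
  }
}

# Decode a context id back to (z_prev, bin) for model-2.
decode_context <- function(ctx) {
  bin <- ((ctx - 1L) %% 10L) + 1L
  z <- ((ctx - 1L) %/% 10L) + 1L
  list(z = z, bin = bin)
}
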