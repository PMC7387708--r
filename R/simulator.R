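#' Adaptive progression algorithm specification
#'
#' The seven progression rules used across the two training studies:
#' three within-block staircases (level changes on runs of consecutive hits
#' or errors during play), three between-block mini-block rules (level
#' changes on the error total of each 40-trial block, with the reset variant
#' restarting every session at 2-back), and the blockwise 85/70 rule of the
#' first study (level up on block accuracy above 0.85, down below 0.70).
#' Errors count both misses and false alarms.
#'
#' @param name One of `"staircase_classic"`, `"staircase_moderate"`,
#'   `"staircase_difficult"`, `"miniblock_moderate"`,
#'   `"miniblock_difficult"`, `"miniblock_reset"`, `"blockwise_85_70"`.
#' @param consecutive_blocks For `blockwise_85_70`: how many consecutive
#'   qualifying blocks are needed before a level change (default 1).
#' @return An object of class `algorithm_spec`.
#' @examples
#' algorithm_spec("miniblock_reset")
#' @export
algorithm_spec <- function(name, consecutive_blocks = 1) {
  specs <- list(
    staircase_classic   = list(up = 3, down = 2, structure = "within"),
    staircase_moderate  = list(up = 3, down = 3, structure = "within"),
    staircase_difficult = list(up = 6, down = 2, structure = "within"),
    miniblock_moderate  = list(up_errors_below = 6, down_errors_above = 8,
                               structure = "between", reset = FALSE),
    miniblock_difficult = list(up_errors_below = 3, down_errors_above = 6,
                               structure = "between", reset = FALSE),
    miniblock_reset     = list(up_errors_below = 3, down_errors_above = 6,
                               structure = "between", reset = TRUE,
                               reset_level = 2),
    blockwise_85_70     = list(up_acc = 0.85, down_acc = 0.70,
                               structure = "blockwise",
                               consecutive_blocks = consecutive_blocks)
  )
  if (!name %in% names(specs)) {
    stop("unknown progression algorithm: ", name, call. = FALSE)
  }
  structure(c(list(name = name), specs[[name]]), class = "algorithm_spec")
}

#' Fresh adaptive-algorithm state
#'
#' @param alg An [algorithm_spec()].
#' @param level Starting n-level.
#' @return State list carrying the current level and the counters the rule
#'   needs (consecutive hit/error runs for staircases, consecutive
#'   qualifying blocks for the blockwise rule).
#' @export
algorithm_state <- function(alg, level = 2) {
  list(level = as.integer(level), hits = 0L, errors = 0L, streak = 0L)
}

#' Advance an adaptive progression algorithm one step
#'
#' For within-block staircases, `outcome` is a single trial event: `"hit"`
#' (collected target), `"error"` (miss or false alarm) or `"none"`
#' (correctly ignored non-target). Hit/error counters are consecutive: each
#' resets on the opposing event and both reset on a level change. For the
#' between-block rules, `outcome` is a list with `errors` (block error
#' total) and, for the blockwise rule, `acc` (block accuracy). The n-level
#' is floored at 1 and capped at `max_level`.
#'
#' @param alg An [algorithm_spec()].
#' @param state State from [algorithm_state()] or a previous call.
#' @param outcome Trial event string (staircases) or block summary list.
#' @param session_start Logical: is this the first block of a session?
#'   (Mini-block reset restarts at 2-back there.)
#' @param max_level Upper cap on the n-level.
#' @return Updated state; `state$level` is the level for the next trial or
#'   block.
#' @examples
#' alg <- algorithm_spec("miniblock_moderate")
#' st <- algorithm_state(alg, level = 3)
#' step_algorithm(alg, st, outcome = list(errors = 5))$level  # promoted
#' @export
step_algorithm <- function(alg, state, outcome, session_start = FALSE,
                           max_level = 10) {
  lvl <- state$level
  if (alg$structure == "within") {
    stopifnot(is.character(outcome))
    if (outcome == "hit") {
      state$hits <- state$hits + 1L
      state$errors <- 0L
    } else if (outcome == "error") {
      state$errors <- state$errors + 1L
      state$hits <- 0L
    }
    if (state$hits >= alg$up) {
      lvl <- lvl + 1L
      state$hits <- 0L; state$errors <- 0L
    } else if (state$errors >= alg$down) {
      lvl <- lvl - 1L
      state$hits <- 0L; state$errors <- 0L
    }
  } else if (alg$structure == "between") {
    if (isTRUE(session_start)) {
      if (isTRUE(alg$reset)) state$level <- clamp_level(alg$reset_level,
                                                        max_level)
      return(state)
    }
    err <- outcome$errors
    if (err < alg$up_errors_below) lvl <- lvl + 1L
    else if (err > alg$down_errors_above) lvl <- lvl - 1L
  } else {  # blockwise accuracy thresholds
    acc <- outcome$acc
    if (!is.na(acc) && acc > alg$up_acc) {
      state$streak <- max(state$streak, 0L) + 1L
    } else if (!is.na(acc) && acc < alg$down_acc) {
      state$streak <- min(state$streak, 0L) - 1L
    } else {
      state$streak <- 0L
    }
    if (state$streak >= alg$consecutive_blocks) {
      lvl <- lvl + 1L; state$streak <- 0L
    } else if (-state$streak >= alg$consecutive_blocks) {
      lvl <- lvl - 1L; state$streak <- 0L
    }
  }
  state$level <- clamp_level(lvl, max_level)
  state
}

clamp_level <- function(lvl, max_level) {
  as.integer(min(max(lvl, 1L), max_level))
}

#' Session plan for simulated training
#'
#' Defaults follow the training studies being emulated: 18 sessions (the
#' studies ran 16-20), 40-trial blocks, 30% targets, and 8 blocks per
#' 20-minute session (blocks last 2-3 minutes).
#'
#' @param n_sessions Number of training sessions.
#' @param blocks_per_session Blocks per session.
#' @param trials_per_block Trials per block.
#' @param target_rate Probability a trial is a target.
#' @return An object of class `session_plan`.
#' @export
session_plan <- function(n_sessions = 18, blocks_per_session = 8,
                         trials_per_block = 40, target_rate = 0.30) {
  stopifnot(n_sessions >= 1, blocks_per_session >= 1, trials_per_block >= 1,
            target_rate > 0, target_rate < 1)
  structure(list(n_sessions = n_sessions,
                 blocks_per_session = blocks_per_session,
                 trials_per_block = trials_per_block,
                 target_rate = target_rate),
            class = "session_plan")
}

#' Simulated participant profile
#'
#' Archetypes mirror the performance patterns seen in real training
#' cohorts: `steady_learner` ramps up at a typical rate to a plateau;
#' `non_learner` stays at the starting skill; `oscillator` learns quickly
#' then bounces around an asymptote; `hmm_generative` evolves its skill by
#' an explicit transition model (for parameter-recovery studies).
#'
#' @param archetype One of `"steady_learner"`, `"non_learner"`,
#'   `"oscillator"`, `"hmm_generative"`.
#' @param start_skill Initial latent skill.
#' @param learn_rate Per-block probability of gaining one skill level
#'   (until `plateau`).
#' @param plateau Skill ceiling for the learner archetypes.
#' @param lapse_prob Per-block probability of losing one skill level.
#' @param osc_rate Per-block probability the oscillator moves (plus or
#'   minus one around the plateau) once it has reached it.
#' @param transition A transition model (required for `hmm_generative`).
#' @param irt An [irt_params()] object driving block performance.
#' @param fp_rate Per-non-target false-alarm probability.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(archetype = c("steady_learner", "non_learner",
                                              "oscillator", "hmm_generative"),
                                start_skill = 2, learn_rate = 0.03,
                                plateau = 6, lapse_prob = 0.005,
                                osc_rate = 0.3, transition = NULL,
                                irt = irt_params(), fp_rate = 0.05) {
  archetype <- match.arg(archetype)
  if (archetype == "hmm_generative" && is.null(transition)) {
    stop("hmm_generative profiles need a transition model", call. = FALSE)
  }
  stopifnot(fp_rate >= 0, fp_rate <= 1, learn_rate >= 0, learn_rate <= 1,
            lapse_prob >= 0, lapse_prob <= 1)
  structure(list(archetype = archetype, start_skill = start_skill,
                 learn_rate = learn_rate, plateau = plateau,
                 lapse_prob = lapse_prob, osc_rate = osc_rate,
                 transition = transition, irt = irt, fp_rate = fp_rate),
            class = "participant_profile")
}

#' Simulate one constant-level block
#'
#' Generative model of a block at fixed presented level `z`: the number of
#' targets is binomial at the plan's target rate; the realized per-block
#' ability is a beta draw with mean `icc(skill, z)` and concentration
#' `alpha`; hits are binomial in the realized ability; false alarms are
#' binomial at the profile's false-alarm rate over non-target trials.
#'
#' @param skill True latent skill.
#' @param z Presented n-level.
#' @param plan A [session_plan()].
#' @param profile A [participant_profile()].
#' @return A list with `tp`, `fn`, `fp`, `n_trials`, `n_targets`, and
#'   `y_frac` (realized block accuracy; `NA` when undefined). Uses the
#'   current RNG stream.
#' @export
simulate_block <- function(skill, z, plan, profile) {
  n <- plan$trials_per_block
  m <- stats::rbinom(1, n, plan$target_rate)
  a <- icc(skill, z, profile$irt)
  a <- pmin(pmax(a, 1e-6), 1 - 1e-6)
  al <- profile$irt$alpha
  tp <- if (m > 0) {
    a_hat <- stats::rbeta(1, al * a, al * (1 - a))
    stats::rbinom(1, m, a_hat)
  } else 0L
  fp <- stats::rbinom(1, n - m, profile$fp_rate)
  fn <- m - tp
  denom <- tp + fn + fp
  list(tp = tp, fn = fn, fp = fp, n_trials = n, n_targets = m,
       y_frac = if (denom > 0) tp / denom else NA_real_)
}

# Trial-by-trial simulation of one block under a within-block staircase.
# The realized ability is redrawn whenever the level changes (a fresh
# stimulus stream starts at the new level). Returns pooled counts plus the
# level at block start, and the updated algorithm state.
simulate_block_staircase <- function(skill, plan, profile, alg, state,
                                     max_level) {
  n <- plan$trials_per_block
  z_start <- state$level
  tp <- fn <- fp <- m <- 0L
  draw_ability <- function(z) {
    a <- icc(skill, z, profile$irt)
    a <- pmin(pmax(a, 1e-6), 1 - 1e-6)
    stats::rbeta(1, profile$irt$alpha * a, profile$irt$alpha * (1 - a))
  }
  a_hat <- draw_ability(state$level)
  for (trial in seq_len(n)) {
    lvl_before <- state$level
    if (stats::runif(1) < plan$target_rate) {
      m <- m + 1L
      if (stats::runif(1) < a_hat) {
        tp <- tp + 1L
        state <- step_algorithm(alg, state, "hit", max_level = max_level)
      } else {
        fn <- fn + 1L
        state <- step_algorithm(alg, state, "error", max_level = max_level)
      }
    } else {
      if (stats::runif(1) < profile$fp_rate) {
        fp <- fp + 1L
        state <- step_algorithm(alg, state, "error", max_level = max_level)
      } else {
        state <- step_algorithm(alg, state, "none", max_level = max_level)
      }
    }
    if (state$level != lvl_before) a_hat <- draw_ability(state$level)
  }
  list(tp = tp, fn = fn, fp = fp, n_trials = n, n_targets = m,
       z_start = z_start, state = state)
}

# One-block skill update for each archetype.
advance_skill <- function(skill, profile, z_prev, y_prev, max_level) {
  u <- stats::runif(1)
  new <- switch(
    profile$archetype,
    non_learner = skill,
    steady_learner = {
      if (skill < profile$plateau && u < profile$learn_rate) skill + 1L
      else if (skill > 1 && u > 1 - profile$lapse_prob) skill - 1L
      else skill
    },
    oscillator = {
      if (skill < profile$plateau && u < profile$learn_rate) skill + 1L
      else if (skill >= profile$plateau - 1 && u < profile$osc_rate) {
        skill + sample(c(-1L, 1L), 1)
      } else skill
    },
    hmm_generative = {
      row <- transition_row(profile$transition, skill, z_prev,
                            if (is.na(y_prev)) 0 else y_prev)
      sample.int(profile$transition$N, 1, prob = row)
    })
  clamp_level(new, max_level)
}

#' Simulate a training cohort with known ground-truth skill
#'
#' Composes the block generator, the adaptive progression algorithm and the
#' profile's skill dynamics into full training sequences. Fully
#' deterministic given `seed`. The true latent skill is recorded per block
#' and round-trips through [write_session_log()] /
#' [read_session_log()] via the truth sidecar.
#'
#' @param n_participants Number of participants.
#' @param plan A [session_plan()].
#' @param profile A [participant_profile()], or a list of them (recycled
#'   over participants).
#' @param alg An [algorithm_spec()].
#' @param seed Integer seed.
#' @param max_level Cap on both skill and presented level (matches the HMM
#'   state count; default 10).
#' @param start_level Presented n-level at the start of training.
#' @param id_prefix Participant id prefix.
#' @return An [nback_cohort()] with `true_skill` filled in and the
#'   algorithm name recorded as each sequence's `condition`.
#' @export
simulate_cohort <- function(n_participants, plan = session_plan(),
                            profile = participant_profile(),
                            alg = algorithm_spec("blockwise_85_70"),
                            seed = 1, max_level = 10, start_level = 2,
                            id_prefix = "SIM") {
  stopifnot(n_participants >= 1)
  profiles <- if (inherits(profile, "participant_profile")) {
    rep(list(profile), n_participants)
  } else {
    rep(profile, length.out = n_participants)
  }
  local_seed(seed, {
    seqs <- vector("list", n_participants)
    for (i in seq_len(n_participants)) {
      seqs[[i]] <- simulate_participant(
        sprintf("%s%03d", id_prefix, i), plan, profiles[[i]], alg,
        max_level, start_level)
    }
    nback_cohort(seqs)
  })
}

simulate_participant <- function(id, plan, profile, alg, max_level,
                                 start_level) {
  T_ <- plan$n_sessions * plan$blocks_per_session
  rows <- vector("list", T_)
  true_skill <- integer(T_)
  skill <- clamp_level(profile$start_skill, max_level)
  state <- algorithm_state(alg, level = start_level)
  z_prev <- NA_integer_; y_prev <- NA_real_
  t <- 0L
  for (s in seq_len(plan$n_sessions)) {
    if (alg$structure == "between") {
      state <- step_algorithm(alg, state, outcome = NULL,
                              session_start = TRUE, max_level = max_level)
    }
    for (b in seq_len(plan$blocks_per_session)) {
      t <- t + 1L
      if (t > 1) {
        skill <- advance_skill(skill, profile, z_prev, y_prev, max_level)
      }
      true_skill[t] <- skill
      if (alg$structure == "within") {
        res <- simulate_block_staircase(skill, plan, profile, alg, state,
                                        max_level)
        state <- res$state
        z <- res$z_start
        blk <- res[c("tp", "fn", "fp", "n_trials", "n_targets")]
      } else {
        z <- state$level
        blk <- simulate_block(skill, z, plan, profile)
        outcome <- list(errors = blk$fn + blk$fp,
                        acc = if (blk$tp + blk$fn + blk$fp > 0) {
                          blk$tp / (blk$tp + blk$fn + blk$fp)
                        } else NA_real_)
        state <- step_algorithm(alg, state, outcome, max_level = max_level)
      }
      denom <- blk$tp + blk$fn + blk$fp
      y_prev <- if (denom > 0) blk$tp / denom else NA_real_
      z_prev <- z
      rows[[t]] <- data.frame(t = t, session = s, z = z,
                              n_trials = blk$n_trials,
                              n_targets = blk$n_targets,
                              tp = blk$tp, fn = blk$fn, fp = blk$fp)
    }
  }
  participant_sequence(id, do.call(rbind, rows), true_skill = true_skill,
                       condition = alg$name)
}
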