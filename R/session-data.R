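#' Trial outcome counts for one training block
#'
#' @param tp Collected targets (hits).
#' @param fn Missed targets.
#' @param fp Collected non-targets (false alarms).
#' @param n_trials Total trials in the block.
#' @param n_targets Number of target trials `m`.
#' @return A `trial_counts` object (named list).
#' @examples
#' trial_counts(tp = 8, fn = 1, fp = 1, n_trials = 30, n_targets = 9)
#' @export
trial_counts <- function(tp, fn, fp, n_trials, n_targets) {
  x <- list(tp = tp, fn = fn, fp = fp,
            n_trials = n_trials, n_targets = n_targets)
  validate_trial_counts(x)
  structure(x, class = "trial_counts")
}

validate_trial_counts <- function(x, where = "trial_counts") {
  with(x, {
    if (any(c(tp, fn, fp, n_trials, n_targets) < 0)) {
      stop(where, ": counts must be non-negative", call. = FALSE)
    }
    if (any(tp + fn != n_targets)) {
      stop(where, ": tp + fn must equal n_targets", call. = FALSE)
    }
    if (any(n_targets > n_trials)) {
      stop(where, ": n_targets cannot exceed n_trials", call. = FALSE)
    }
    if (any(fp > n_trials - n_targets)) {
      stop(where, ": fp cannot exceed the number of non-target trials",
           call. = FALSE)
    }
  })
  invisible(x)
}

#' Assemble a participant's training sequence
#'
#' A participant sequence is the unit the models consume: an ordered set of
#' blocks, each with its presented n-level and trial outcome counts. Derived
#' columns `y_frac` (block accuracy) and `y_succ` (effective success count
#' out of `n_targets`, `round(y_frac * n_targets)`) are computed here.
#'
#' @param participant_id Identifier string.
#' @param blocks A data.frame with columns `t` (1-based block index,
#'   strictly increasing), `session`, `z` (presented n-level >= 1),
#'   `n_trials`, `n_targets`, `tp`, `fn`, `fp`.
#' @param true_skill Optional ground-truth latent skill per block (simulated
#'   data only).
#' @param condition Optional condition/algorithm label used by
#'   condition-based splits.
#' @return An object of class `participant_sequence`.
#' @export
participant_sequence <- function(participant_id, blocks, true_skill = NULL,
                                 condition = NULL) {
  required <- c("t", "session", "z", "n_trials", "n_targets", "tp", "fn", "fp")
  missing <- setdiff(required, names(blocks))
  if (length(missing)) {
    stop("blocks is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(blocks) == 0L) stop("blocks must be non-empty", call. = FALSE)
  if (any(diff(blocks$t) <= 0)) {
    stop("block indices `t` must be strictly increasing", call. = FALSE)
  }
  if (any(blocks$z < 1)) stop("presented n-level `z` must be >= 1",
                              call. = FALSE)
  validate_trial_counts(blocks, where = paste0("participant ", participant_id))
  blocks$y_frac <- suppressWarnings(acc_block(blocks))
  blocks$y_succ <- ifelse(is.na(blocks$y_frac), NA_integer_,
                          as.integer(round(blocks$y_frac * blocks$n_targets)))
  if (!is.null(true_skill) && length(true_skill) != nrow(blocks)) {
    stop("true_skill must have one entry per block", call. = FALSE)
  }
  structure(list(participant_id = as.character(participant_id),
                 blocks = blocks,
                 true_skill = true_skill,
                 condition = condition),
            class = "participant_sequence")
}

#' @export
print.participant_sequence <- function(x, ...) {
  cat(sprintf("Participant %s: %d blocks, sessions %d-%d, n-levels %d-%d%s\n",
              x$participant_id, nrow(x$blocks),
              min(x$blocks$session), max(x$blocks$session),
              min(x$blocks$z), max(x$blocks$z),
              if (is.null(x$true_skill)) "" else " (ground truth attached)"))
  invisible(x)
}

#' Bundle participant sequences into a cohort
#'
#' @param sequences List of [participant_sequence()] objects.
#' @return An object of class `nback_cohort` (a list of sequences).
#' @export
nback_cohort <- function(sequences) {
  if (!length(sequences)) stop("cohort must be non-empty", call. = FALSE)
  ok <- vapply(sequences, inherits, logical(1), "participant_sequence")
  if (!all(ok)) stop("all elements must be participant_sequence objects",
                     call. = FALSE)
  ids <- vapply(sequences, `[[`, character(1), "participant_id")
  if (anyDuplicated(ids)) stop("participant ids must be unique", call. = FALSE)
  names(sequences) <- ids
  structure(sequences, class = "nback_cohort")
}

#' @export
print.nback_cohort <- function(x, ...) {
  nb <- vapply(x, function(s) nrow(s$blocks), integer(1))
  cat(sprintf("N-back training cohort: %d participants, %d blocks total (%d-%d per participant)\n",
              length(x), sum(nb), min(nb), max(nb)))
  invisible(x)
}

#' @export
`[.nback_cohort` <- function(x, i) {
  nback_cohort(unclass(x)[i])
}

#' Read a session-log CSV into a cohort
#'
#' Expected columns: `participant_id, session, block, n_level, n_trials,
#' n_targets, tp, fn, fp` (UTF-8, header row, comma-separated). An optional
#' sidecar CSV with columns `participant_id, block, true_skill` attaches
#' ground-truth skill (simulated data).
#'
#' @param path Path to the session-log CSV.
#' @param truth_path Optional path to the ground-truth sidecar CSV.
#' @return An [nback_cohort()].
#' @export
read_session_log <- function(path, truth_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  truth <- if (!is.null(truth_path)) {
    utils::read.csv(truth_path, stringsAsFactors = FALSE)
  }
  seqs <- lapply(split(df, df$participant_id), function(d) {
    d <- d[order(d$block), , drop = FALSE]
    blocks <- data.frame(t = d$block, session = d$session, z = d$n_level,
                         n_trials = d$n_trials, n_targets = d$n_targets,
                         tp = d$tp, fn = d$fn, fp = d$fp)
    ts <- NULL
    if (!is.null(truth)) {
      tr <- truth[truth$participant_id == d$participant_id[1], , drop = FALSE]
      if (nrow(tr)) {
        tr <- tr[order(tr$block), , drop = FALSE]
        ts <- tr$true_skill
      }
    }
    cond <- if ("condition" %in% names(d)) d$condition[1] else NULL
    participant_sequence(d$participant_id[1], blocks, true_skill = ts,
                         condition = cond)
  })
  nback_cohort(seqs[order(names(seqs))])
}

#' Write a cohort to a session-log CSV
#'
#' Inverse of [read_session_log()]; round-trips bit-exactly. Ground-truth
#' skill, when present, goes to a sidecar CSV so the main log matches the
#' format of real training exports.
#'
#' @param cohort An [nback_cohort()].
#' @param path Output CSV path.
#' @param truth_path Optional sidecar path for ground-truth skill.
#' @export
write_session_log <- function(cohort, path, truth_path = NULL) {
  stopifnot(inherits(cohort, "nback_cohort"))
  rows <- lapply(cohort, function(s) {
    b <- s$blocks
    out <- data.frame(participant_id = s$participant_id, session = b$session,
                      block = b$t, n_level = b$z, n_trials = b$n_trials,
                      n_targets = b$n_targets, tp = b$tp, fn = b$fn,
                      fp = b$fp)
    if (!is.null(s$condition)) out$condition <- s$condition
    out
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  if (!is.null(truth_path)) {
    tr <- lapply(cohort, function(s) {
      if (is.null(s$true_skill)) return(NULL)
      data.frame(participant_id = s$participant_id, block = s$blocks$t,
                 true_skill = s$true_skill)
    })
    tr <- do.call(rbind, tr)
    if (!is.null(tr)) {
      utils::write.csv(tr, truth_path, row.names = FALSE, quote = FALSE,
                       fileEncoding = "UTF-8")
    }
  }
  invisible(path)
}

# Blocks usable for likelihood work: defined accuracy and at least one target.
# Returns the blocks data.frame subset; warns when anything is dropped.
fit_blocks <- function(seq) {
  b <- seq$blocks
  keep <- !is.na(b$y_frac) & b$n_targets >= 1
  if (!all(keep)) {
    warning(sprintf(
      "participant %s: dropping %d block(s) with undefined accuracy or no targets",
      seq$participant_id, sum(!keep)), call. = FALSE)
    b <- b[keep, , drop = FALSE]
  }
  if (!nrow(b)) stop("participant ", seq$participant_id,
                     ": no usable blocks", call. = FALSE)
  b
}

# Run `code` with a temporarily-seeded RNG, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
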