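#' Configuration for the 2-down-1-up calibration staircase
#'
#' The threshold-search used in device calibration: an ascending method with
#' small fixed steps, levels decreasing by one step after two consecutive
#' heard responses (counted since the last level change) and increasing after
#' every miss, terminating after a fixed number of reversals. This transformed
#' up-down rule converges on the level where the probability of hearing is
#' `2^(-1/2)` (about 70.7%).
#'
#' @param step_db Level step (dB). Default 1.
#' @param n_reversals Reversal count at termination. Default 3.
#' @param initial_offset_db Start offset relative to a pre-determined lowest
#'   response level (dB). Default -10.
#' @param max_trials Safety cap on trials. Default 400.
#' @return An object of class `staircase_config`.
#' @export
staircase_config <- function(step_db = 1, n_reversals = 3,
                             initial_offset_db = -10, max_trials = 400) {
  if (step_db <= 0) stop("`step_db` must be > 0", call. = FALSE)
  if (n_reversals < 1) stop("`n_reversals` must be >= 1", call. = FALSE)
  if (max_trials < 1) stop("`max_trials` must be >= 1", call. = FALSE)
  structure(list(step_db = step_db, n_reversals = as.integer(n_reversals),
                 initial_offset_db = initial_offset_db,
                 max_trials = as.integer(max_trials)),
            class = "staircase_config")
}

#' Ascending pre-scan for the staircase start level
#'
#' Models the "lowest response level" pre-determination as a single ascending
#' pass in coarse steps: ascend from `start_level_db` until the responder
#' first reports hearing, and return that level. The staircase then starts
#' `initial_offset_db` (default -10 dB) relative to it.
#'
#' @param responder Function `(frequency_hz, level_db_hl) -> logical`.
#' @param frequency_hz Frequency under test.
#' @param start_level_db Lowest level of the ascending pass (dB). Default -10.
#' @param step_db Pre-scan step (dB). Default 5.
#' @param max_level_db Abort level. Default 100.
#' @return The lowest level (dB) at which a response occurred, or `NA` if none
#'   up to `max_level_db`.
#' @export
ascending_prescan <- function(responder, frequency_hz, start_level_db = -10,
                              step_db = 5, max_level_db = 100) {
  lev <- start_level_db
  while (lev <= max_level_db) {
    if (isTRUE(responder(frequency_hz, lev))) return(lev)
    lev <- lev + step_db
  }
  NA_real_
}

#' Run a 2-down-1-up adaptive staircase
#'
#' Level decreases by `step_db` after two consecutive heard responses since
#' the last level change and increases by `step_db` after each miss. A
#' reversal is a trial at which the direction of level change flips; the run
#' terminates once `n_reversals` reversals have occurred (or at `max_trials`,
#' flagged non-converged). The threshold estimate is the mean of the reversal
#' levels.
#'
#' @param responder Function `(frequency_hz, level_db_hl) -> logical`.
#' @param frequency_hz Frequency under test.
#' @param start_level_db Starting level (dB).
#' @param config An [staircase_config()].
#' @return An object of class `staircase_run`: data frame `trials`
#'   (`level_db`, `heard`), `reversal_levels_db`, `threshold_db` (mean of
#'   reversal levels; `NA` if none) and `converged`.
#' @export
run_staircase <- function(responder, frequency_hz, start_level_db,
                          config = staircase_config()) {
  stopifnot(inherits(config, "staircase_config"))
  level <- start_level_db
  levels <- numeric(0); heards <- logical(0)
  reversals <- numeric(0)
  direction <- 0L          # sign of the last applied level change
  consec_heard <- 0L       # heard count since the last level change
  n <- 0L
  while (n < config$max_trials && length(reversals) < config$n_reversals) {
    n <- n + 1L
    heard <- isTRUE(responder(frequency_hz, level))
    levels[n] <- level; heards[n] <- heard
    if (heard) {
      consec_heard <- consec_heard + 1L
      if (consec_heard >= 2L) {
        if (direction == 1L) reversals <- c(reversals, level)
        direction <- -1L
        level <- level - config$step_db
        consec_heard <- 0L
      }
    } else {
      if (direction == -1L) reversals <- c(reversals, level)
      direction <- 1L
      level <- level + config$step_db
      consec_heard <- 0L
    }
  }
  structure(
    list(trials = data.frame(level_db = levels, heard = heards),
         reversal_levels_db = reversals,
         threshold_db = if (length(reversals)) mean(reversals) else NA_real_,
         converged = length(reversals) >= config$n_reversals,
         config = config),
    class = "staircase_run"
  )
}

#' @export
print.staircase_run <- function(x, ...) {
  cat("2-down-1-up staircase: ", nrow(x$trials), " trials, ",
      length(x$reversal_levels_db), " reversals",
      if (!x$converged) " (non-converged)", "\n", sep = "")
  cat("threshold estimate:", round(x$threshold_db, 2), "dB\n")
  invisible(x)
}
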