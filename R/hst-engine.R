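#' @title Adaptive Hearing Scale Test engine
#' @description
#' The adaptive screening state machine. Starting at a fixed scale (default
#' S_5), the four test tones are presented in a fixed order at that scale's
#' levels. If all tones are heard the level descends by one scale; descent
#' continues until a scale with a miss, and the last fully heard scale is the
#' result (the minimum audible hearing scale). If the start scale has a miss
#' the level ascends until a fully heard scale; a miss at the highest scale
#' yields a no-response (NR) outcome. Scales S_1..S_5 classify as pass; higher
#' scales and NR classify as fail.
#' @name hst_engine
NULL

# Presentation logs accumulate as parallel vectors (cheap appends for short
# sessions) and finalize to a data frame in the result constructor.
new_presentation_log <- function() {
  list(frequency_hz = numeric(0), level_db_hl = numeric(0),
       scale = integer(0), heard = logical(0),
       onset_s = numeric(0), isi_s = numeric(0))
}

append_presentation <- function(log, f, level, scale, heard, onset, isi) {
  log$frequency_hz <- c(log$frequency_hz, f)
  log$level_db_hl <- c(log$level_db_hl, level)
  log$scale <- c(log$scale, scale)
  log$heard <- c(log$heard, heard)
  log$onset_s <- c(log$onset_s, onset)
  log$isi_s <- c(log$isi_s, isi)
  log
}

finalize_log <- function(log) {
  if (is.data.frame(log)) return(log)
  as.data.frame(log)
}

new_hst_result <- function(assigned_scale, classification, presentations,
                           n_procedures = 1L, protocol = "HST", ear = NA_character_) {
  structure(
    list(assigned_scale = assigned_scale,
         classification = classification,
         presentations = finalize_log(presentations),
         n_procedures = n_procedures,
         protocol = protocol,
         ear = ear),
    class = "hst_result"
  )
}

#' Engine configuration for the adaptive scale test
#'
#' @param start_scale Starting scale index. Default 5 (25 dB HL at 500 Hz,
#'   20 dB HL at the other frequencies).
#' @param tone_order Frequencies in presentation order. Default
#'   `c(1000, 2000, 4000, 500)`.
#' @param abort_scale_on_first_miss If `TRUE` (default) the remaining tones of
#'   a scale are skipped after the first miss, since the scale can no longer be
#'   fully heard; `FALSE` presents all tones for log fidelity.
#' @param tone_duration_s Tone duration (s). Default 1.5.
#' @param isi_bounds_s Uniform bounds for the random silent interval before
#'   each tone (s). Default `c(2, 3)`.
#' @return An object of class `hst_engine_config`.
#' @export
engine_config <- function(start_scale = 5,
                          tone_order = c(1000, 2000, 4000, 500),
                          abort_scale_on_first_miss = TRUE,
                          tone_duration_s = 1.5,
                          isi_bounds_s = c(2, 3)) {
  if (start_scale < 1 || start_scale != round(start_scale))
    stop("`start_scale` must be a positive integer", call. = FALSE)
  if (length(isi_bounds_s) != 2 || any(isi_bounds_s < 0) ||
      isi_bounds_s[1] > isi_bounds_s[2])
    stop("`isi_bounds_s` must be a valid non-negative interval", call. = FALSE)
  structure(
    list(start_scale = as.integer(start_scale), tone_order = tone_order,
         abort_scale_on_first_miss = isTRUE(abort_scale_on_first_miss),
         tone_duration_s = tone_duration_s, isi_bounds_s = isi_bounds_s),
    class = "hst_engine_config"
  )
}

# Present all tones of one scale; returns list(all_heard, log, t_now).
present_scale <- function(responder, table, config, scale, log, t_now) {
  all_heard <- TRUE
  for (f in config$tone_order) {
    lev <- scale_level(table, f, scale)
    isi <- stats::runif(1, config$isi_bounds_s[1], config$isi_bounds_s[2])
    t_now <- t_now + isi
    heard <- isTRUE(responder(f, lev))
    log <- append_presentation(log, f, lev, as.integer(scale), heard, t_now, isi)
    t_now <- t_now + config$tone_duration_s
    if (!heard) {
      all_heard <- FALSE
      if (config$abort_scale_on_first_miss) break
    }
  }
  list(all_heard = all_heard, log = log, t_now = t_now)
}

#' Run the adaptive Hearing Scale Test on one ear
#'
#' @param responder A function `(frequency_hz, level_db_hl) -> logical`
#'   (`TRUE` = heard). See [make_responder()] for simulated listeners.
#' @param table An [scale_table()].
#' @param config An [engine_config()].
#' @param pass_cutoff Highest passing scale. Default 5.
#' @param ear Optional ear label (`"left"`/`"right"`).
#' @return An `hst_result`: the assigned scale (`NA` = NR), its
#'   pass/fail classification, and the full presentation log.
#' @examples
#' l <- simulated_listener(thresholds_db_hl = c("500" = 12, "1000" = 18,
#'                                              "2000" = 10, "4000" = 5))
#' run_hst(make_responder(l), scale_table())$assigned_scale  # 5
#' @export
run_hst <- function(responder, table = scale_table(), config = engine_config(),
                    pass_cutoff = 5, ear = NA_character_) {
  stopifnot(inherits(table, "hst_scale_table"), inherits(config, "hst_engine_config"))
  if (config$start_scale > table$max_scale)
    stop("`start_scale` exceeds the table's max_scale", call. = FALSE)
  if (!all(config$tone_order %in% table$frequencies_hz) ||
      !setequal(config$tone_order, table$frequencies_hz))
    stop("`tone_order` must be a permutation of the table frequencies", call. = FALSE)

  log <- new_presentation_log()
  t_now <- 0
  s <- config$start_scale
  first <- present_scale(responder, table, config, s, log, t_now)
  log <- first$log; t_now <- first$t_now

  if (first$all_heard) {
    # descend one scale at a time; the result is the last fully heard scale
    assigned <- s
    while (s > 1) {
      s <- s - 1L
      step <- present_scale(responder, table, config, s, log, t_now)
      log <- step$log; t_now <- step$t_now
      if (step$all_heard) assigned <- s else break
    }
  } else {
    # ascend until a fully heard scale; NR if the top scale has a miss
    assigned <- NA_integer_
    while (s < table$max_scale) {
      s <- s + 1L
      step <- present_scale(responder, table, config, s, log, t_now)
      log <- step$log; t_now <- step$t_now
      if (step$all_heard) { assigned <- s; break }
    }
  }

  new_hst_result(assigned_scale = if (is.na(assigned)) NA_integer_ else as.integer(assigned),
                 classification = classify_scale(assigned, pass_cutoff, table$max_scale),
                 presentations = log, n_procedures = 1L,
                 protocol = "HST", ear = ear)
}

#' Brute-force minimum-audible-scale oracle
#'
#' Exhaustively finds the smallest scale `s` such that
#' `scale_level(f, s) >= threshold(f)` at every table frequency, i.e. the
#' scale a deterministic listener would be assigned; `NA` (NR) if no scale up
#' to `max_scale` qualifies. Serves as an independent check on [run_hst()].
#'
#' @param thresholds_db_hl Named numeric vector of per-frequency thresholds
#'   (dB HL); names are frequencies, which must cover the table.
#' @param table An [scale_table()].
#' @return Scale index, or `NA` for NR.
#' @export
minimum_audible_scale_oracle <- function(thresholds_db_hl, table = scale_table()) {
  need <- as.character(table$frequencies_hz)
  if (!all(need %in% names(thresholds_db_hl)))
    stop("thresholds missing for frequency: ",
         paste(setdiff(need, names(thresholds_db_hl)), collapse = ", "),
         call. = FALSE)
  for (s in seq_len(table$max_scale)) {
    lv <- scale_levels_all(table, s)
    if (all(lv >= thresholds_db_hl[need])) return(s)
  }
  NA_integer_
}

#' Test-retest pair of adaptive screening runs
#'
#' Runs [run_hst()] twice on the same responder and reports agreement: an
#' exact-match flag and the scale difference (retest minus test). Two NR
#' outcomes agree with difference 0 by convention; one NR against a scale is a
#' disagreement with difference `NA`.
#'
#' @inheritParams run_hst
#' @return A list with elements `test`, `retest` (both `hst_result`),
#'   `match` and `scale_difference`.
#' @export
test_retest <- function(responder, table = scale_table(), config = engine_config(),
                        pass_cutoff = 5) {
  r1 <- run_hst(responder, table, config, pass_cutoff)
  r2 <- run_hst(responder, table, config, pass_cutoff)
  s1 <- r1$assigned_scale; s2 <- r2$assigned_scale
  both_nr <- is.na(s1) && is.na(s2)
  match <- both_nr || (!is.na(s1) && !is.na(s2) && s1 == s2)
  diff <- if (both_nr) 0L else if (is.na(s1) || is.na(s2)) NA_integer_ else s2 - s1
  list(test = r1, retest = r2, match = match, scale_difference = diff)
}

#' Session duration implied by a presentation log
#'
#' Sums, over the logged presentations, the tone duration plus the realized
#' inter-stimulus interval preceding each tone.
#'
#' @param result An `hst_result`.
#' @param tone_duration_s Tone duration (s). Default 1.5.
#' @return Duration in seconds (0 for an empty log).
#' @export
estimate_session_duration <- function(result, tone_duration_s = 1.5) {
  stopifnot(inherits(result, "hst_result"))
  n <- nrow(result$presentations)
  if (n == 0) return(0)
  n * tone_duration_s + sum(result$presentations$isi_s)
}

#' @export
print.hst_result <- function(x, ...) {
  sc <- if (is.na(x$assigned_scale)) "NR" else paste0("S_", x$assigned_scale)
  cat(x$protocol, " screening result: ", sc, " -> ", x$classification, "\n",
      nrow(x$presentations), " presentations, ", x$n_procedures,
      " procedure(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.hst_result <- function(object, ...) {
  print(object)
  cat("estimated session duration:",
      round(estimate_session_duration(object), 1), "s\n")
  invisible(object)
}
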