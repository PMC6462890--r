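#' Screening protocol specification
#'
#' A protocol is either adaptive-scale (the Hearing Scale Test: a scale table
#' plus the adaptive engine) or fixed-level (conventional pure-tone screening:
#' one presentation level per frequency, pass iff every tone is heard in at
#' least one of `max_procedures` procedures).
#'
#' @param name Protocol identifier.
#' @param mode `"adaptive-scale"` or `"fixed-level"`.
#' @param frequencies_hz Test frequencies in presentation order.
#' @param levels_db_hl Named numeric vector of per-frequency levels (dB HL);
#'   fixed-level mode only.
#' @param table An [scale_table()]; adaptive mode only.
#' @param max_procedures Number of procedures before a fail is assigned
#'   (fixed-level mode). Default 2.
#' @param pass_cutoff Highest passing scale (adaptive mode). Default 5.
#' @return An object of class `hst_protocol`.
#' @export
protocol_spec <- function(name, mode = c("fixed-level", "adaptive-scale"),
                          frequencies_hz, levels_db_hl = NULL, table = NULL,
                          max_procedures = 2, pass_cutoff = 5) {
  mode <- match.arg(mode)
  if (max_procedures < 1) stop("`max_procedures` must be >= 1", call. = FALSE)
  if (mode == "fixed-level") {
    if (is.null(levels_db_hl) ||
        !setequal(names(levels_db_hl), as.character(frequencies_hz)))
      stop("fixed-level mode needs exactly one level per frequency", call. = FALSE)
    table <- NULL
  } else {
    if (is.null(table) || !inherits(table, "hst_scale_table"))
      stop("adaptive mode needs a scale table", call. = FALSE)
    if (!all(frequencies_hz %in% table$frequencies_hz))
      stop("protocol frequencies missing from the scale table", call. = FALSE)
    levels_db_hl <- NULL
  }
  structure(
    list(name = name, mode = mode,
         frequencies_hz = as.numeric(frequencies_hz),
         levels_db_hl = levels_db_hl, table = table,
         max_procedures = as.integer(max_procedures),
         pass_cutoff = as.integer(pass_cutoff)),
    class = "hst_protocol"
  )
}

#' Built-in screening protocol presets
#'
#' * `"HST"` — the adaptive Hearing Scale Test: scales S_1..S_10, start S_5,
#'   tone order 1000/2000/4000/500 Hz; at S_5 the levels are 20/20/20 dB HL at
#'   1/2/4 kHz and 25 dB HL at 500 Hz. Scales S_1..S_5 pass.
#' * `"AAP"` — fixed-level screen at 20 dB HL at 500, 1000, 2000, 4000 Hz.
#' * `"ASHA_recommended"` — fixed-level at 20 dB HL at 1000, 2000, 4000 Hz
#'   (the published recommendation).
#' * `"ASHA_as_tested"` — fixed-level at 15 dB HL at 500, 1000, 2000, 4000 Hz
#'   (the variant actually run in the validation study; the source is
#'   internally inconsistent, so both ASHA variants are shipped explicitly).
#'
#' @param name One of `"HST"`, `"AAP"`, `"ASHA_recommended"`, `"ASHA_as_tested"`.
#' @param max_scale Scale-table range for the HST preset (10 or 20). Default 10.
#' @return An `hst_protocol`.
#' @export
protocol_preset <- function(name, max_scale = 10) {
  presets <- c("HST", "AAP", "ASHA_recommended", "ASHA_as_tested")
  if (length(name) != 1 || !name %in% presets)
    stop("unknown protocol '", name, "'; available: ",
         paste(presets, collapse = ", "), call. = FALSE)
  switch(name,
    HST = protocol_spec("HST", "adaptive-scale",
                        frequencies_hz = c(1000, 2000, 4000, 500),
                        table = scale_table(max_scale = max_scale)),
    AAP = protocol_spec("AAP", "fixed-level",
                        frequencies_hz = c(500, 1000, 2000, 4000),
                        levels_db_hl = c("500" = 20, "1000" = 20,
                                         "2000" = 20, "4000" = 20)),
    ASHA_recommended = protocol_spec("ASHA_recommended", "fixed-level",
                        frequencies_hz = c(1000, 2000, 4000),
                        levels_db_hl = c("1000" = 20, "2000" = 20, "4000" = 20)),
    ASHA_as_tested = protocol_spec("ASHA_as_tested", "fixed-level",
                        frequencies_hz = c(500, 1000, 2000, 4000),
                        levels_db_hl = c("500" = 15, "1000" = 15,
                                         "2000" = 15, "4000" = 15))
  )
}

#' Run a fixed-level screening procedure
#'
#' Presents each protocol frequency at its fixed level; the ear passes iff in
#' at least one of up to `max_procedures` procedures the responder reports
#' hearing every tone. Every presentation is logged.
#'
#' @param responder A function `(frequency_hz, level_db_hl) -> logical`.
#' @param spec A fixed-level [protocol_spec()].
#' @param tone_duration_s Tone duration used for the presentation timeline (s).
#' @param isi_bounds_s Bounds of the uniform random silent interval preceding
#'   each tone (s).
#' @return An `hst_result` with `assigned_scale = NA` (fixed-level protocols
#'   carry no scale), a `classification`, the presentation log and the number
#'   of procedures run.
#' @export
fixed_level_screen <- function(responder, spec,
                               tone_duration_s = 1.5, isi_bounds_s = c(2, 3)) {
  stopifnot(inherits(spec, "hst_protocol"))
  if (spec$mode != "fixed-level")
    stop("`fixed_level_screen` needs a fixed-level protocol", call. = FALSE)
  log <- new_presentation_log()
  t_now <- 0
  passed <- FALSE
  n_proc <- 0L
  for (proc in seq_len(spec$max_procedures)) {
    n_proc <- proc
    all_heard <- TRUE
    for (f in spec$frequencies_hz) {
      lev <- unname(spec$levels_db_hl[as.character(f)])
      isi <- stats::runif(1, isi_bounds_s[1], isi_bounds_s[2])
      t_now <- t_now + isi
      heard <- isTRUE(responder(f, lev))
      log <- append_presentation(log, f, lev, NA_integer_, heard, t_now, isi)
      t_now <- t_now + tone_duration_s
      if (!heard) all_heard <- FALSE
    }
    if (all_heard) { passed <- TRUE; break }
  }
  new_hst_result(assigned_scale = NA_integer_,
                 classification = if (passed) "pass" else "fail",
                 presentations = log, n_procedures = n_proc,
                 protocol = spec$name)
}
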