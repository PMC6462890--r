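#' Stratified hearing-scale table
#'
#' A scale table maps a (frequency, scale index) pair to a stimulus level in
#' dB HL. Adjacent scales differ by a constant step (5 dB); each frequency may
#' carry an additive offset. With the defaults, scale `s` presents
#' `5 * (s - 1)` dB HL at 1000/2000/4000 Hz and `5 * s` dB HL at 500 Hz, so
#' S_1 is 0/0/0/5 dB and S_10 is 45/45/45/50 dB. The screening range tops out
#' at S_10; a full-range table extends the same formula to S_20.
#'
#' @param frequencies_hz Test frequencies, in presentation order used by the
#'   adaptive engine. Default `c(1000, 2000, 4000, 500)`.
#' @param base_step_db Level increment between adjacent scales (dB). Default 5.
#' @param offsets_db Named numeric vector of per-frequency additive offsets
#'   (dB); names are frequencies in Hz. Frequencies absent from the vector get
#'   offset 0. Default gives 500 Hz an offset of +5 dB.
#' @param max_scale Highest scale index. 10 for screening (default), 20 for
#'   the full-range mode.
#' @return An object of class `hst_scale_table`.
#' @examples
#' tbl <- scale_table()
#' scale_level(tbl, 1000, 1)  # 0 dB HL
#' scale_level(tbl, 500, 5)   # 25 dB HL
#' @export
scale_table <- function(frequencies_hz = c(1000, 2000, 4000, 500),
                        base_step_db = 5,
                        offsets_db = c("500" = 5),
                        max_scale = 10) {
  stopifnot(length(frequencies_hz) >= 1, !anyDuplicated(frequencies_hz))
  if (!is.numeric(base_step_db) || base_step_db <= 0)
    stop("`base_step_db` must be a positive number", call. = FALSE)
  if (!is.numeric(max_scale) || max_scale < 1 || max_scale != round(max_scale))
    stop("`max_scale` must be a positive integer", call. = FALSE)
  off <- setNames(numeric(length(frequencies_hz)), as.character(frequencies_hz))
  if (length(offsets_db)) {
    if (is.null(names(offsets_db)))
      stop("`offsets_db` must be named by frequency (Hz)", call. = FALSE)
    keep <- intersect(names(offsets_db), names(off))
    off[keep] <- offsets_db[keep]
  }
  if (any(base_step_db * 0 + off < 0))
    stop("offsets must keep all levels non-negative", call. = FALSE)
  structure(
    list(frequencies_hz = as.numeric(frequencies_hz),
         base_step_db = as.numeric(base_step_db),
         offsets_db = off,
         max_scale = as.integer(max_scale)),
    class = "hst_scale_table"
  )
}

#' Stimulus level for a frequency and scale index
#'
#' `level = base_step * (scale - 1) + offset(frequency)`.
#'
#' @param table An `hst_scale_table`.
#' @param frequency_hz A frequency present in the table.
#' @param scale Scale index (vectorised), each in `1..max_scale`.
#' @return Stimulus level(s) in dB HL.
#' @export
scale_level <- function(table, frequency_hz, scale) {
  stopifnot(inherits(table, "hst_scale_table"))
  if (length(frequency_hz) != 1 || !frequency_hz %in% table$frequencies_hz)
    stop("unknown frequency: ", frequency_hz, " Hz (table has ",
         paste(table$frequencies_hz, collapse = ", "), ")", call. = FALSE)
  if (any(is.na(scale)) || any(scale < 1) || any(scale > table$max_scale) ||
      any(scale != round(scale)))
    stop("scale index out of range 1..", table$max_scale, call. = FALSE)
  table$base_step_db * (scale - 1) + unname(table$offsets_db[as.character(frequency_hz)])
}

#' Per-scale level vector across all table frequencies
#' @param table An `hst_scale_table`.
#' @param scale A single scale index.
#' @return Named numeric vector of dB HL levels, names are frequencies.
#' @keywords internal
scale_levels_all <- function(table, scale) {
  setNames(
    vapply(table$frequencies_hz, function(f) scale_level(table, f, scale), numeric(1)),
    as.character(table$frequencies_hz)
  )
}

#' Classify a scale outcome as pass or fail
#'
#' Scales up to `pass_cutoff` (default S_5) are a pass; higher scales and a
#' no-response (NR) outcome are a fail. NR is represented as `NA`.
#'
#' @param scale Scale index, or `NA` for NR. Vectorised.
#' @param pass_cutoff Highest passing scale index. Default 5.
#' @param max_scale Highest valid scale index. Default 10.
#' @return Character vector, `"pass"` or `"fail"`.
#' @export
classify_scale <- function(scale, pass_cutoff = 5, max_scale = 10) {
  bad <- !is.na(scale) & (scale < 1 | scale > max_scale | scale != round(scale))
  if (any(bad))
    stop("invalid scale index: ", paste(scale[bad], collapse = ", "), call. = FALSE)
  ifelse(!is.na(scale) & scale <= pass_cutoff, "pass", "fail")
}

#' @export
print.hst_scale_table <- function(x, ...) {
  cat("Hearing-scale table: S_1..S_", x$max_scale,
      " (step ", x$base_step_db, " dB)\n", sep = "")
  lv <- sapply(seq_len(x$max_scale), function(s) scale_levels_all(x, s))
  rownames(lv) <- paste0(x$frequencies_hz, " Hz")
  colnames(lv) <- paste0("S_", seq_len(x$max_scale))
  print(lv)
  invisible(x)
}
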