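#' Simulated listener with a psychometric response model
#'
#' A listener is defined by per-frequency true thresholds in the app's dB HL
#' domain, a psychometric spread, guess and lapse rates, and a separate
#' reference booth pure-tone average (PTA) label. The probability of reporting
#' "heard" at level `L` for threshold `T` is
#' `guess + (1 - guess - lapse) * F((L - T) / slope)` with `F` a logistic
#' sigmoid; `slope = 0` degenerates to the deterministic step
#' "heard iff `L >= T`" (closed at equality), which consumes no randomness.
#'
#' App-domain thresholds and the booth PTA are deliberately distinct
#' attributes: transducers and test environments differ, so the booth means
#' attached to a scale group need not equal the app's scale levels. Screening
#' simulation uses the app-domain thresholds; reference impairment labelling
#' (`booth_pta_db > 25`) uses the booth PTA.
#'
#' @param thresholds_db_hl Named numeric vector of per-frequency app-domain
#'   thresholds (dB HL); names are frequencies in Hz.
#' @param slope_db Psychometric spread in dB (logistic scale parameter);
#'   0 = deterministic step. Default 0.
#' @param guess_rate Probability of a spurious "heard" far below threshold.
#' @param lapse_rate Probability of a miss far above threshold.
#' @param booth_pta_db Reference booth PTA label (dB); `> 25` marks impairment.
#' @param ear Optional `"left"`/`"right"` label.
#' @return An object of class `hst_listener`.
#' @export
simulated_listener <- function(thresholds_db_hl, slope_db = 0,
                               guess_rate = 0, lapse_rate = 0,
                               booth_pta_db = NA_real_, ear = NA_character_) {
  if (is.null(names(thresholds_db_hl)))
    stop("`thresholds_db_hl` must be named by frequency (Hz)", call. = FALSE)
  if (slope_db < 0) stop("`slope_db` must be >= 0", call. = FALSE)
  if (guess_rate < 0 || lapse_rate < 0 || guess_rate + lapse_rate >= 1)
    stop("need 0 <= guess_rate + lapse_rate < 1", call. = FALSE)
  structure(
    list(thresholds_db_hl = thresholds_db_hl, slope_db = slope_db,
         guess_rate = guess_rate, lapse_rate = lapse_rate,
         booth_pta_db = booth_pta_db, ear = ear),
    class = "hst_listener"
  )
}

#' Single response draw from a simulated listener
#'
#' @param listener An [simulated_listener()].
#' @param frequency_hz Frequency of the presented tone (must have a threshold).
#' @param level_db_hl Presented level in dB HL.
#' @return Logical: heard or not. Deterministic (no RNG consumed) when
#'   `slope_db = 0` and guess/lapse are 0.
#' @export
respond <- function(listener, frequency_hz, level_db_hl) {
  stopifnot(inherits(listener, "hst_listener"))
  thr <- listener$thresholds_db_hl[as.character(frequency_hz)]
  if (is.na(thr))
    stop("listener has no threshold at ", frequency_hz, " Hz", call. = FALSE)
  thr <- unname(thr)
  step <- listener$slope_db == 0
  if (step && listener$guess_rate == 0 && listener$lapse_rate == 0)
    return(level_db_hl >= thr)
  f <- if (step) as.numeric(level_db_hl >= thr)
       else stats::plogis((level_db_hl - thr) / listener$slope_db)
  p <- listener$guess_rate + (1 - listener$guess_rate - listener$lapse_rate) * f
  stats::runif(1) < p
}

#' Responder callback for the screening engines
#'
#' Wraps a listener into the `(frequency, level) -> logical` callback consumed
#' by [run_hst()], [fixed_level_screen()] and [run_staircase()].
#'
#' @param listener An [simulated_listener()].
#' @return A function of `(frequency_hz, level_db_hl)`.
#' @export
make_responder <- function(listener) {
  force(listener)
  function(frequency_hz, level_db_hl) respond(listener, frequency_hz, level_db_hl)
}

#' Study-cohort specification (per-scale group rows)
#'
#' Defaults encode the pooled 170-ear validation cohort: group counts
#' 16/58/59/27/8 at S_1..S_5 with booth PTA means 5/7/9/11/12 dB, one ear at
#' S_7 (PTA 31 dB) and one at S_8 (PTA 36 dB). All group PTAs at S_1..S_5 are
#' at most 25 dB (normal); the S_7 and S_8 ears exceed 25 dB (impaired).
#'
#' @param scale Scale index per group.
#' @param n Ear count per group.
#' @param mean_pta_db Group mean booth PTA (dB).
#' @param sd_pta_db Group SD of booth PTA (dB); `NA` where the source prints
#'   none (n = 1 groups).
#' @return A `data.frame` of class `hst_cohort_spec`.
#' @export
cohort_spec_table3 <- function(scale = c(1, 2, 3, 4, 5, 7, 8),
                               n = c(16, 58, 59, 27, 8, 1, 1),
                               mean_pta_db = c(5, 7, 9, 11, 12, 31, 36),
                               sd_pta_db = c(2.9, 3.0, 2.8, 3.8, 3.6, NA, NA)) {
  stopifnot(length(scale) == length(n), length(n) == length(mean_pta_db))
  if (any(n < 0)) stop("group counts must be non-negative", call. = FALSE)
  if (length(sd_pta_db) != length(scale))
    sd_pta_db <- rep(NA_real_, length(scale))
  structure(
    data.frame(scale = as.integer(scale), n = as.integer(n),
               mean_pta_db = mean_pta_db, sd_pta_db = sd_pta_db),
    class = c("hst_cohort_spec", "data.frame")
  )
}

#' Deterministic cohort fixture from per-scale group counts
#'
#' For each group row `(s, n, m)` generates `n` deterministic listeners whose
#' app-domain thresholds are flat across frequencies and equal to the scale
#' level at 1000 Hz for scale `s` — which guarantees the minimum audible scale
#' is exactly `s` — with booth PTA label `m`. With the default spec this
#' reconstructs the 170-ear validation cohort.
#'
#' @param spec An [cohort_spec_table3()] (or any data frame with columns
#'   `scale`, `n`, `mean_pta_db`).
#' @param table The [scale_table()] defining the scale levels.
#' @param expected_total Optional declared cohort size; a mismatch with
#'   `sum(spec$n)` is an error.
#' @return A list of [simulated_listener()] objects, of class `hst_cohort`.
#' @export
cohort_from_table3 <- function(spec = cohort_spec_table3(),
                               table = scale_table(),
                               expected_total = NULL) {
  if (any(spec$scale < 1 | spec$scale > table$max_scale))
    stop("spec references scales outside the table range", call. = FALSE)
  if (!is.null(expected_total) && sum(spec$n) != expected_total)
    stop("cohort size mismatch: spec totals ", sum(spec$n),
         " but ", expected_total, " declared", call. = FALSE)
  freqs <- as.character(table$frequencies_hz)
  out <- list()
  for (i in seq_len(nrow(spec))) {
    if (spec$n[i] == 0) next
    thr_flat <- scale_level(table, 1000, spec$scale[i])
    thr <- setNames(rep(thr_flat, length(freqs)), freqs)
    for (j in seq_len(spec$n[i])) {
      out[[length(out) + 1]] <- simulated_listener(
        thresholds_db_hl = thr, booth_pta_db = spec$mean_pta_db[i])
    }
  }
  structure(out, class = "hst_cohort")
}

#' Randomised cohort sampler
#'
#' Draws `n` listeners with impairment prevalence `prevalence`: impaired
#' listeners get a booth PTA above 25 dB, normal listeners at most 25 dB
#' (truncated normal draws), and per-frequency app-domain thresholds are the
#' PTA plus independent normal jitter.
#'
#' @param n Cohort size.
#' @param prevalence Impairment fraction in `[0, 1]`.
#' @param frequencies_hz Frequencies to give thresholds at.
#' @param normal_mean,normal_sd Booth PTA distribution of normal ears (dB),
#'   truncated to `(-10, 25]`.
#' @param impaired_mean,impaired_sd Booth PTA distribution of impaired ears
#'   (dB), truncated to `(25, 90]`.
#' @param jitter_sd SD of per-frequency threshold jitter around the PTA (dB).
#' @param slope_db,guess_rate,lapse_rate Psychometric parameters shared by all
#'   sampled listeners.
#' @return An `hst_cohort` list of listeners.
#' @export
sample_cohort <- function(n, prevalence,
                          frequencies_hz = c(500, 1000, 2000, 4000),
                          normal_mean = 10, normal_sd = 5,
                          impaired_mean = 35, impaired_sd = 8,
                          jitter_sd = 3,
                          slope_db = 0, guess_rate = 0, lapse_rate = 0) {
  if (prevalence < 0 || prevalence > 1)
    stop("`prevalence` must be in [0, 1]", call. = FALSE)
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  rtrunc <- function(mean, sd, lo, hi) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x > lo && x <= hi) return(x)
    }
  }
  fq <- as.character(frequencies_hz)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    impaired <- stats::runif(1) < prevalence
    pta <- if (impaired) rtrunc(impaired_mean, impaired_sd, 25, 90)
           else rtrunc(normal_mean, normal_sd, -10, 25)
    thr <- setNames(pta + stats::rnorm(length(fq), 0, jitter_sd), fq)
    out[[i]] <- simulated_listener(thr, slope_db = slope_db,
                                   guess_rate = guess_rate,
                                   lapse_rate = lapse_rate,
                                   booth_pta_db = pta)
  }
  structure(out, class = "hst_cohort")
}

#' Reference impairment labels of a cohort
#'
#' Impairment is a booth PTA strictly greater than 25 dB; PTA = 25 is normal.
#'
#' @param cohort An `hst_cohort`.
#' @return Logical vector, `TRUE` = impaired.
#' @export
reference_impaired <- function(cohort) {
  vapply(cohort, function(l) isTRUE(l$booth_pta_db > 25), logical(1))
}

#' @export
print.hst_cohort <- function(x, ...) {
  pta <- vapply(x, function(l) l$booth_pta_db, numeric(1))
  cat("Simulated cohort:", length(x), "ears;",
      sum(pta > 25, na.rm = TRUE), "impaired (booth PTA > 25 dB)\n")
  invisible(x)
}
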