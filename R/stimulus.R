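#' Device calibration profile (RETSPL + maximum output)
#'
#' Maps the app's dB HL domain onto the digital amplitude domain for one
#' device + earphone pairing: per-frequency RETSPL values (the SPL that
#' corresponds to 0 dB HL for the transducer) and the SPL produced at digital
#' full scale with the device volume at its maximum. The user volume is
#' assumed at 100% of maximum.
#'
#' @param device Device identifier string.
#' @param retspl_db Named numeric vector of RETSPLs (dB SPL re 20 uPa), named
#'   by frequency in Hz.
#' @param max_output_spl_db Named numeric vector of full-scale output SPLs
#'   (dB SPL), same names.
#' @return An object of class `calibration_profile`.
#' @export
calibration_profile <- function(device, retspl_db, max_output_spl_db) {
  if (is.null(names(retspl_db)) || is.null(names(max_output_spl_db)) ||
      !setequal(names(retspl_db), names(max_output_spl_db)))
    stop("RETSPL and max-output vectors must be named by the same frequencies",
         call. = FALSE)
  common <- names(retspl_db)
  if (any(max_output_spl_db[common] <= retspl_db[common]))
    stop("max output SPL must exceed the RETSPL at every frequency", call. = FALSE)
  structure(list(device = device, retspl_db = retspl_db,
                 max_output_spl_db = max_output_spl_db,
                 volume_policy = "full-scale"),
            class = "calibration_profile")
}

#' Read / write a calibration profile as JSON
#' @param path File path.
#' @return `read_calibration_profile` returns a [calibration_profile()];
#'   `write_calibration_profile` returns `path` invisibly.
#' @export
read_calibration_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_profile(x$device,
                      setNames(as.numeric(x$retspl_db), names(x$retspl_db)),
                      setNames(as.numeric(x$max_output_spl_db),
                               names(x$max_output_spl_db)))
}

#' @rdname read_calibration_profile
#' @param profile A [calibration_profile()].
#' @export
write_calibration_profile <- function(profile, path) {
  stopifnot(inherits(profile, "calibration_profile"))
  jsonlite::write_json(
    list(device = profile$device,
         retspl_db = as.list(profile$retspl_db),
         max_output_spl_db = as.list(profile$max_output_spl_db),
         volume_policy = profile$volume_policy),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Convert dB HL to dB SPL via the RETSPL
#'
#' `SPL = HL + RETSPL(frequency)` — the RETSPL is by definition the SPL of a
#' 0 dB HL stimulus for the transducer.
#'
#' @param level_db_hl Level in dB HL.
#' @param frequency_hz Frequency present in the profile.
#' @param profile A [calibration_profile()].
#' @return Level in dB SPL.
#' @export
hl_to_spl <- function(level_db_hl, frequency_hz, profile) {
  stopifnot(inherits(profile, "calibration_profile"))
  r <- profile$retspl_db[as.character(frequency_hz)]
  if (is.na(r))
    stop("no RETSPL calibrated at ", frequency_hz, " Hz", call. = FALSE)
  level_db_hl + unname(r)
}

#' Convert a target SPL to a linear digital amplitude
#'
#' With the device at full volume, digital full scale produces
#' `max_output_spl(frequency)`; the amplitude for a target SPL is
#' `10^((target - max_output_spl) / 20)`.
#'
#' @param target_spl_db Target level in dB SPL.
#' @param frequency_hz Frequency present in the profile.
#' @param profile A [calibration_profile()].
#' @return Amplitude as a fraction of digital full scale, in `(0, 1]`.
#' @export
spl_to_amplitude <- function(target_spl_db, frequency_hz, profile) {
  stopifnot(inherits(profile, "calibration_profile"))
  mx <- profile$max_output_spl_db[as.character(frequency_hz)]
  if (is.na(mx))
    stop("no max output calibrated at ", frequency_hz, " Hz", call. = FALSE)
  mx <- unname(mx)
  if (target_spl_db > mx)
    stop("target ", target_spl_db, " dB SPL exceeds the device maximum of ",
         mx, " dB SPL (", round(target_spl_db - mx, 2),
         " dB of headroom missing)", call. = FALSE)
  10^((target_spl_db - mx) / 20)
}

#' Amplitude for a dB HL level through the full calibration chain
#' @inheritParams hl_to_spl
#' @return Linear amplitude fraction of digital full scale.
#' @export
hl_to_amplitude <- function(level_db_hl, frequency_hz, profile) {
  spl_to_amplitude(hl_to_spl(level_db_hl, frequency_hz, profile),
                   frequency_hz, profile)
}

#' Tone specification
#'
#' @param frequency_hz Carrier frequency (Hz).
#' @param level_db_hl Nominal level (dB HL), carried as metadata.
#' @param duration_s Tone duration (s). Default 1.5.
#' @param am_depth Amplitude-modulation depth fraction in `[0, 1]`. Default 1
#'   (100% depth: the envelope reaches zero).
#' @param am_rate_hz Modulation rate (Hz). Default 20 (the depth is prescribed
#'   by the screening method; the rate is an implementation choice).
#' @param ramp_s Cosine on/off ramp duration (s). Default 0.02; set 0 to
#'   disable.
#' @param sample_rate_hz Sampling rate (Hz). Default 44100.
#' @return An object of class `tone_spec`.
#' @export
tone_spec <- function(frequency_hz, level_db_hl = NA_real_, duration_s = 1.5,
                      am_depth = 1, am_rate_hz = 20, ramp_s = 0.02,
                      sample_rate_hz = 44100) {
  if (am_depth < 0 || am_depth > 1)
    stop("`am_depth` must be in [0, 1]", call. = FALSE)
  if (duration_s <= 2 * ramp_s)
    stop("`duration_s` must exceed twice the ramp", call. = FALSE)
  if (sample_rate_hz < 2 * (frequency_hz + am_rate_hz))
    stop("sample rate below the Nyquist requirement", call. = FALSE)
  structure(list(frequency_hz = frequency_hz, level_db_hl = level_db_hl,
                 duration_s = duration_s, am_depth = am_depth,
                 am_rate_hz = am_rate_hz, ramp_s = ramp_s,
                 sample_rate_hz = sample_rate_hz),
            class = "tone_spec")
}

#' Synthesize an amplitude-modulated pure tone
#'
#' A sinusoid at the carrier frequency, amplitude-modulated at `am_rate_hz`
#' with depth `am_depth` (envelope `(1 + depth * sin(2 pi f_m t)) / (1 +
#' depth)`, so the peak equals `amplitude` and at depth 1 the envelope minimum
#' is 0), with cosine on/off ramps.
#'
#' @param spec A [tone_spec()].
#' @param amplitude Peak amplitude as a fraction of full scale, in `[0, 1]`.
#' @return Numeric waveform vector of `round(duration_s * sample_rate_hz)`
#'   samples, peak magnitude at most `amplitude`.
#' @export
synthesize_tone <- function(spec, amplitude) {
  stopifnot(inherits(spec, "tone_spec"))
  if (amplitude < 0 || amplitude > 1)
    stop("`amplitude` must be in [0, 1]", call. = FALSE)
  n <- round(spec$duration_s * spec$sample_rate_hz)
  t <- (seq_len(n) - 1) / spec$sample_rate_hz
  carrier <- sin(2 * pi * spec$frequency_hz * t)
  env <- (1 + spec$am_depth * sin(2 * pi * spec$am_rate_hz * t)) / (1 + spec$am_depth)
  ramp <- rep(1, n)
  nr <- round(spec$ramp_s * spec$sample_rate_hz)
  if (nr > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    ramp[seq_len(nr)] <- up
    ramp[n - nr + seq_len(nr)] <- rev(up)
  }
  amplitude * carrier * env * ramp
}

#' Schedule a session playlist with randomized silent intervals
#'
#' Preserves presentation order; draws each inter-stimulus interval uniformly
#' within `isi_bounds_s`, so onsets are strictly increasing.
#'
#' @param presentations A data frame with at least columns `frequency_hz` and
#'   `level_db_hl`, in presentation order.
#' @param tone_duration_s Tone duration (s). Default 1.5.
#' @param isi_bounds_s Interval bounds for the silent gap before each tone (s).
#'   Default `c(2, 3)`.
#' @return The input data frame with added `isi_s` and `onset_s` columns.
#' @export
build_session_playlist <- function(presentations, tone_duration_s = 1.5,
                                   isi_bounds_s = c(2, 3)) {
  if (length(isi_bounds_s) != 2 || any(isi_bounds_s < 0) ||
      isi_bounds_s[1] > isi_bounds_s[2])
    stop("`isi_bounds_s` must be a valid non-negative interval", call. = FALSE)
  n <- nrow(presentations)
  if (is.null(n) || n == 0) {
    presentations$isi_s <- numeric(0)
    presentations$onset_s <- numeric(0)
    return(presentations)
  }
  isi <- stats::runif(n, isi_bounds_s[1], isi_bounds_s[2])
  onset <- cumsum(isi + tone_duration_s) - tone_duration_s
  presentations$isi_s <- isi
  presentations$onset_s <- onset
  presentations
}

#' Write a waveform as a 16-bit PCM WAV file
#'
#' Amplitudes must already lie in `[-1, 1]`; out-of-range samples are an
#' error, never silently clipped.
#'
#' @param waveform Numeric vector of samples in `[-1, 1]`.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, sample_rate_hz, path) {
  if (length(waveform) && max(abs(waveform)) > 1)
    stop("waveform samples exceed [-1, 1]; refusing to clip", call. = FALSE)
  pcm <- as.integer(round(waveform * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")            # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")             # PCM
  writeBin(1L, con, size = 2, endian = "little")             # mono
  writeBin(as.integer(sample_rate_hz), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")             # block align
  writeBin(16L, con, size = 2, endian = "little")            # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path File path.
#' @return List with `waveform` (numeric in `[-1, 1]`), `sample_rate_hz` and
#'   `duration_s`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file", call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file", call. = FALSE)
  sample_rate <- NA_integer_; bits <- NA_integer_; channels <- NA_integer_
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found", call. = FALSE)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (id == "data") {
      if (bits != 16 || channels != 1)
        stop("only 16-bit mono PCM supported", call. = FALSE)
      pcm <- readBin(con, integer(), n = sz / 2, size = 2,
                     signed = TRUE, endian = "little")
      return(list(waveform = pcm / 32767,
                  sample_rate_hz = sample_rate,
                  duration_s = length(pcm) / sample_rate))
    } else {
      readBin(con, raw(), n = sz)
    }
  }
}

#' Synthesize and export a calibrated screening tone
#'
#' Full chain: dB HL -> dB SPL (RETSPL) -> digital amplitude (max-output
#' headroom) -> amplitude-modulated tone -> WAV.
#'
#' @param frequency_hz Carrier frequency (Hz).
#' @param level_db_hl Level in dB HL.
#' @param profile A [calibration_profile()].
#' @param path Output WAV path.
#' @param ... Passed to [tone_spec()].
#' @return `path`, invisibly.
#' @export
export_calibrated_tone <- function(frequency_hz, level_db_hl, profile, path, ...) {
  amp <- hl_to_amplitude(level_db_hl, frequency_hz, profile)
  spec <- tone_spec(frequency_hz, level_db_hl, ...)
  write_wav(synthesize_tone(spec, amp), spec$sample_rate_hz, path)
}
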