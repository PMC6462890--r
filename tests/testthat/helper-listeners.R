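# Shared helpers: deterministic listeners and random threshold vectors.

FREQS <- c("500", "1000", "2000", "4000")

det_listener <- function(...) {
  # det_listener("1000" = 18, "2000" = 10, ...) or det_listener(all = 20)
  thr <- c(...)
  if (length(thr) == 1 && names(thr) == "all")
    thr <- setNames(rep(thr[[1]], 4), FREQS)
  missing <- setdiff(FREQS, names(thr))
  thr <- c(thr, setNames(rep(0, length(missing)), missing))
  simulated_listener(thresholds_db_hl = thr[FREQS])
}

random_thresholds <- function(lo = -5, hi = 60) {
  setNames(runif(4, lo, hi), FREQS)
}

fixture_pta <- function(cohort) {
  vapply(cohort, function(l) l$booth_pta_db, numeric(1))
}
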