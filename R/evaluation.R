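#' 2x2 contingency table for a screening test
#'
#' Convention: the "positive" test outcome is a screen *fail*, the reference
#' condition is impairment (booth PTA > 25 dB). So `tp` counts impaired ears
#' that failed the screen, `fp` normal ears that failed, `fn` impaired ears
#' that passed, `tn` normal ears that passed.
#'
#' @param test_results Character vector of `"pass"`/`"fail"` per ear.
#' @param reference_impaired Logical vector per ear, `TRUE` = impaired.
#' @return An object of class `hst_contingency` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
contingency <- function(test_results, reference_impaired) {
  if (length(test_results) != length(reference_impaired))
    stop("test and reference vectors differ in length", call. = FALSE)
  if (!all(test_results %in% c("pass", "fail")))
    stop("test results must be 'pass' or 'fail'", call. = FALSE)
  fail <- test_results == "fail"
  structure(
    list(tp = sum(fail & reference_impaired),
         fp = sum(fail & !reference_impaired),
         fn = sum(!fail & reference_impaired),
         tn = sum(!fail & !reference_impaired)),
    class = "hst_contingency"
  )
}

#' Diagnostic metrics from a 2x2 table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)`, false-positive rate `1 - specificity`, false-negative
#' rate `1 - sensitivity`. A zero denominator yields `NaN` (undefined), never
#' a silent 0.
#'
#' @param table An [contingency()] table.
#' @return An object of class `hst_metrics` (named list of fractions).
#' @export
screen_metrics <- function(table) {
  stopifnot(inherits(table, "hst_contingency"))
  ratio <- function(num, den) if (den == 0) NaN else num / den
  sens <- ratio(table$tp, table$tp + table$fn)
  spec <- ratio(table$tn, table$tn + table$fp)
  structure(
    list(sensitivity = sens, specificity = spec,
         ppv = ratio(table$tp, table$tp + table$fp),
         npv = ratio(table$tn, table$tn + table$fn),
         false_positive_rate = 1 - spec,
         false_negative_rate = 1 - sens),
    class = "hst_metrics"
  )
}

#' Per-scale threshold summary
#'
#' One row per occupied scale: ear count, mean and SD of the booth PTA of the
#' ears assigned that scale. SD is `NaN` for n = 1 groups. NR ears are
#' summarised in a separate attribute count, not a scale row.
#'
#' @param assigned_scales Integer vector of assigned scales per ear (`NA` = NR).
#' @param booth_pta Numeric vector of booth PTA values per ear (dB).
#' @return A data frame (`scale`, `n`, `mean_pta_db`, `sd_pta_db`) with
#'   attribute `n_nr` (count of NR ears).
#' @export
scale_group_summary <- function(assigned_scales, booth_pta) {
  if (length(assigned_scales) != length(booth_pta))
    stop("scale and PTA vectors differ in length", call. = FALSE)
  keep <- !is.na(assigned_scales)
  if (!any(keep)) {
    out <- data.frame(scale = integer(0), n = integer(0),
                      mean_pta_db = numeric(0), sd_pta_db = numeric(0))
    attr(out, "n_nr") <- sum(!keep)
    return(out)
  }
  s <- assigned_scales[keep]; p <- booth_pta[keep]
  lev <- sort(unique(s))
  out <- data.frame(
    scale = lev,
    n = vapply(lev, function(x) sum(s == x), integer(1)),
    mean_pta_db = vapply(lev, function(x) mean(p[s == x]), numeric(1)),
    sd_pta_db = vapply(lev, function(x) {
      g <- p[s == x]
      if (length(g) < 2) NaN else stats::sd(g)
    }, numeric(1))
  )
  attr(out, "n_nr") <- sum(!keep)
  out
}

#' Correlation between assigned scale and booth PTA
#'
#' Product-moment correlation between the scale index and the booth PTA. By
#' default NR ears are excluded (their count is reported via the `n_excluded`
#' attribute); with `include_nr = TRUE` they enter at rank `max_scale + 1`.
#' Zero-variance input yields `NaN`.
#'
#' @param assigned_scales Integer scales per ear (`NA` = NR).
#' @param booth_pta Booth PTA per ear (dB).
#' @param include_nr Include NR ears at the worst rank? Default `FALSE`.
#' @param max_scale Scale range, used for the NR rank. Default 10.
#' @return Correlation coefficient with attribute `n_excluded`.
#' @export
scale_pta_correlation <- function(assigned_scales, booth_pta,
                                  include_nr = FALSE, max_scale = 10) {
  if (length(assigned_scales) != length(booth_pta))
    stop("scale and PTA vectors differ in length", call. = FALSE)
  x <- as.numeric(assigned_scales)
  n_excl <- 0L
  if (include_nr) {
    x[is.na(x)] <- max_scale + 1
  } else {
    keep <- !is.na(x)
    n_excl <- sum(!keep)
    x <- x[keep]; booth_pta <- booth_pta[keep]
  }
  if (length(x) < 3)
    stop("need at least 3 ears with defined scales", call. = FALSE)
  r <- if (stats::sd(x) == 0 || stats::sd(booth_pta) == 0) NaN
       else stats::cor(x, booth_pta)
  attr(r, "n_excluded") <- n_excl
  r
}

#' Run one protocol over a cohort
#'
#' @param cohort An `hst_cohort`.
#' @param protocol An `hst_protocol` (preset name strings also accepted).
#' @return A list with `results` (list of `hst_result`), `classifications`,
#'   `assigned_scales` (all `NA` for fixed-level protocols).
#' @export
run_protocol <- function(cohort, protocol) {
  if (is.character(protocol)) protocol <- protocol_preset(protocol)
  stopifnot(inherits(protocol, "hst_protocol"))
  results <- lapply(cohort, function(l) {
    resp <- make_responder(l)
    if (protocol$mode == "adaptive-scale")
      run_hst(resp, protocol$table,
              engine_config(tone_order = protocol$frequencies_hz),
              pass_cutoff = protocol$pass_cutoff, ear = l$ear)
    else
      fixed_level_screen(resp, protocol)
  })
  list(results = results,
       classifications = vapply(results, function(r) r$classification, character(1)),
       assigned_scales = vapply(results, function(r) r$assigned_scale, integer(1)))
}

#' Compare screening protocols on the same cohort
#'
#' Runs each protocol on the same cohort (deterministic cohorts give
#' deterministic comparisons) and tabulates the diagnostic metrics against the
#' booth-PTA impairment reference side by side.
#'
#' @param cohort An `hst_cohort`.
#' @param protocols List of `hst_protocol` objects or preset names.
#' @return Data frame, one row per protocol with the six metrics (as
#'   fractions) plus the 2x2 counts.
#' @export
compare_protocols <- function(cohort, protocols) {
  ref <- reference_impaired(cohort)
  rows <- lapply(protocols, function(p) {
    if (is.character(p)) p <- protocol_preset(p)
    for (f in p$frequencies_hz) {
      miss <- vapply(cohort, function(l)
        is.na(l$thresholds_db_hl[as.character(f)]), logical(1))
      if (any(miss))
        stop("cohort listeners lack thresholds at ", f,
             " Hz required by protocol ", p$name, call. = FALSE)
    }
    run <- run_protocol(cohort, p)
    m <- screen_metrics(contingency(run$classifications, ref))
    ct <- contingency(run$classifications, ref)
    data.frame(protocol = p$name,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv,
               false_positive_rate = m$false_positive_rate,
               false_negative_rate = m$false_negative_rate,
               tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn)
  })
  do.call(rbind, rows)
}

#' @export
print.hst_contingency <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("screen fail", "screen pass"),
                              c("impaired", "normal")))
  print(m)
  invisible(x)
}

#' @export
print.hst_metrics <- function(x, ...) {
  pct <- function(v) if (is.nan(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat("sensitivity:        ", pct(x$sensitivity), "\n",
      "specificity:        ", pct(x$specificity), "\n",
      "PPV:                ", pct(x$ppv), "\n",
      "NPV:                ", pct(x$npv), "\n",
      "false-positive rate:", pct(x$false_positive_rate), "\n",
      "false-negative rate:", pct(x$false_negative_rate), "\n", sep = "")
  invisible(x)
}
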