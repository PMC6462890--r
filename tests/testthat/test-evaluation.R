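test_that("contingency cells place every ear correctly", {
  # exhaustive check on all 2x2 label assignments of a 3-ear toy cohort
  for (t1 in c("pass", "fail")) for (t2 in c("pass", "fail"))
    for (t3 in c("pass", "fail"))
      for (r1 in c(TRUE, FALSE)) for (r2 in c(TRUE, FALSE))
        for (r3 in c(TRUE, FALSE)) {
          tst <- c(t1, t2, t3); ref <- c(r1, r2, r3)
          ct <- contingency(tst, ref)
          expect_equal(ct$tp, sum(tst == "fail" & ref))
          expect_equal(ct$fp, sum(tst == "fail" & !ref))
          expect_equal(ct$fn, sum(tst == "pass" & ref))
          expect_equal(ct$tn, sum(tst == "pass" & !ref))
          expect_equal(ct$tp + ct$fp + ct$fn + ct$tn, 3)
        }
  ct <- contingency(rep("pass", 5), rep(FALSE, 5))
  expect_equal(unlist(ct[c("tp", "fp", "fn", "tn")]),
               c(tp = 0, fp = 0, fn = 0, tn = 5))
  expect_error(contingency(c("pass", "fail"), TRUE), "length")
  expect_error(contingency(c("pass", "maybe"), c(TRUE, FALSE)), "pass")
})

test_that("screening metrics follow the 2x2 definitions with NaN for 0/0", {
  m <- screen_metrics(structure(list(tp = 2, fp = 0, fn = 0, tn = 168),
                                class = "hst_contingency"))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$ppv, 1)
  expect_equal(m$npv, 1)
  expect_equal(m$false_positive_rate, 0)
  expect_equal(m$false_negative_rate, 0)

  m <- screen_metrics(structure(list(tp = 20, fp = 0, fn = 1, tn = 149),
                                class = "hst_contingency"))
  expect_equal(m$sensitivity, 20 / 21)
  expect_equal(m$false_negative_rate, 1 / 21)

  m <- screen_metrics(structure(list(tp = 0, fp = 0, fn = 0, tn = 170),
                                class = "hst_contingency"))
  expect_true(is.nan(m$sensitivity))   # undefined, never a silent 0
  expect_equal(m$specificity, 1)

  # transposing the table swaps sensitivity and specificity
  ct <- structure(list(tp = 7, fp = 3, fn = 2, tn = 50),
                  class = "hst_contingency")
  tr <- structure(list(tp = ct$tn, fp = ct$fn, fn = ct$fp, tn = ct$tp),
                  class = "hst_contingency")
  expect_equal(screen_metrics(ct)$sensitivity, screen_metrics(tr)$specificity)
  expect_equal(screen_metrics(ct)$specificity, screen_metrics(tr)$sensitivity)
})

test_that("per-scale summaries reproduce group counts, means and the n=1 NaN", {
  s <- c(1, 1, 2, 2, 2, 7)
  p <- c(4, 6, 7, 8, 6, 31)
  out <- scale_group_summary(s, p)
  expect_equal(out$scale, c(1, 2, 7))
  expect_equal(out$n, c(2, 3, 1))
  expect_equal(out$mean_pta_db, c(5, 7, 31))
  expect_true(is.nan(out$sd_pta_db[3]))   # single-ear group
  expect_equal(out$sd_pta_db[1], sd(c(4, 6)))
  expect_equal(sum(out$n) + attr(out, "n_nr"), length(s))

  # NR ears counted separately, not as a scale row
  out <- scale_group_summary(c(1, NA, NA), c(5, 40, 45))
  expect_equal(out$n, 1)
  expect_equal(attr(out, "n_nr"), 2)

  empty <- scale_group_summary(integer(0), numeric(0))
  expect_equal(nrow(empty), 0)
  expect_error(scale_group_summary(1:3, 1:2), "length")
})

test_that("scale-PTA correlation matches the textbook formula and handles NR", {
  # perfect linear relation
  expect_equal(as.numeric(scale_pta_correlation(1:5, 5 * (1:5) - 3)), 1)
  # constant scales -> undefined
  expect_true(is.nan(scale_pta_correlation(rep(3, 5), c(1, 2, 3, 4, 5))))
  expect_error(scale_pta_correlation(1:2, 1:2), "at least 3")

  # independent recomputation from the raw moment formula
  set.seed(12)
  s <- sample(1:8, 40, replace = TRUE)
  p <- 5 * s + rnorm(40, 0, 4)
  r <- as.numeric(scale_pta_correlation(s, p))
  manual <- sum((s - mean(s)) * (p - mean(p))) /
    sqrt(sum((s - mean(s))^2) * sum((p - mean(p))^2))
  expect_equal(r, manual)

  # NR handling: excluded by default (with count), worst rank if included
  s2 <- c(s, NA, NA)
  p2 <- c(p, 50, 55)
  r_excl <- scale_pta_correlation(s2, p2)
  expect_equal(attr(r_excl, "n_excluded"), 2L)
  expect_equal(as.numeric(r_excl), manual)
  r_incl <- scale_pta_correlation(s2, p2, include_nr = TRUE)
  expect_equal(attr(r_incl, "n_excluded"), 0L)
  expect_gt(as.numeric(r_incl), as.numeric(r_excl))  # high-PTA NR ears at rank 11
})

test_that("the fixture cohort yields a strongly positive scale-PTA correlation", {
  coh <- cohort_from_table3()
  set.seed(1)
  run <- run_protocol(coh, "HST")
  r <- scale_pta_correlation(run$assigned_scales, fixture_pta(coh))
  expect_gt(as.numeric(r), 0.8)
})

test_that("protocol comparison separates protocols around a discriminating ear", {
  # one impaired ear with flat thresholds at 18 dB HL: heard at 20 dB (AAP
  # passes it -> a miss) but not at 15 dB (the stricter as-tested variant
  # fails it -> detected)
  coh <- structure(list(
    simulated_listener(setNames(rep(18, 4), FREQS), booth_pta_db = 30),
    simulated_listener(setNames(rep(5, 4), FREQS), booth_pta_db = 8)
  ), class = "hst_cohort")
  set.seed(2)
  cmp <- compare_protocols(coh, list("AAP", "ASHA_as_tested"))
  expect_equal(cmp$sensitivity[cmp$protocol == "AAP"], 0)
  expect_equal(cmp$sensitivity[cmp$protocol == "ASHA_as_tested"], 1)
  expect_true(all(cmp$specificity == 1))
  # identity: false-positive rate is 1 - specificity
  expect_equal(cmp$false_positive_rate, 1 - cmp$specificity)
})

test_that("protocol comparison is deterministic on deterministic cohorts", {
  coh <- cohort_from_table3()
  set.seed(3); a <- compare_protocols(coh, list("HST", "AAP"))
  set.seed(4); b <- compare_protocols(coh, list("HST", "AAP"))
  expect_equal(a[, -1], b[, -1])
  expect_error(compare_protocols(
    structure(list(simulated_listener(c("1000" = 5), booth_pta_db = 5)),
              class = "hst_cohort"),
    list("AAP")), "lack thresholds")
})
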