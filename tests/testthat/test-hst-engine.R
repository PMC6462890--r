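test_that("the adaptive engine reproduces worked deterministic outcomes", {
  tbl <- scale_table()
  set.seed(2)
  cases <- list(
    # thresholds equal the S_1 levels exactly -> minimum scale S_1
    list(thr = c("1000" = 0, "2000" = 0, "4000" = 0, "500" = 5),
         scale = 1L, cls = "pass"),
    # all thresholds above the S_10 levels -> no response
    list(thr = c("1000" = 60, "2000" = 60, "4000" = 60, "500" = 60),
         scale = NA_integer_, cls = "fail"),
    # mixed thresholds with 1 kHz binding at 18 dB -> S_5 (frozen from the
    # brute-force oracle: smallest s with 5(s-1) >= 18 is 5)
    list(thr = c("1000" = 18, "2000" = 10, "4000" = 5, "500" = 12),
         scale = 5L, cls = "pass"),
    # 1 kHz at 32 dB -> S_8 (smallest s with 5(s-1) >= 32 is 8)
    list(thr = c("1000" = 32, "2000" = 0, "4000" = 0, "500" = 0),
         scale = 8L, cls = "fail")
  )
  for (cs in cases) {
    r <- run_hst(make_responder(simulated_listener(cs$thr)), tbl)
    expect_identical(r$assigned_scale, cs$scale)
    expect_equal(r$classification, cs$cls)
    expect_identical(r$assigned_scale, minimum_audible_scale_oracle(cs$thr, tbl))
  }
})

test_that("oracle anchors hold and missing frequencies error", {
  tbl <- scale_table()
  expect_equal(minimum_audible_scale_oracle(setNames(rep(0, 4), FREQS), tbl), 1)
  expect_equal(minimum_audible_scale_oracle(
    c("1000" = 21, "2000" = 0, "4000" = 0, "500" = 0), tbl), 6)
  expect_true(is.na(minimum_audible_scale_oracle(
    c("500" = 51, "1000" = 0, "2000" = 0, "4000" = 0), tbl)))
  expect_error(minimum_audible_scale_oracle(c("1000" = 5), tbl), "missing")
})

test_that("engine matches the brute-force oracle on random deterministic listeners", {
  tbl <- scale_table()
  set.seed(314)
  for (i in 1:500) {
    thr <- random_thresholds()
    got <- run_hst(make_responder(simulated_listener(thr)), tbl)$assigned_scale
    want <- minimum_audible_scale_oracle(thr, tbl)
    expect_identical(got, if (is.na(want)) NA_integer_ else as.integer(want))
  }
})

test_that("raising any single threshold never lowers the assigned scale", {
  tbl <- scale_table()
  set.seed(271)
  rank_of <- function(s) if (is.na(s)) tbl$max_scale + 1L else s
  for (i in 1:200) {
    thr <- random_thresholds()
    base <- run_hst(make_responder(simulated_listener(thr)), tbl)$assigned_scale
    f <- sample(FREQS, 1)
    thr2 <- thr; thr2[f] <- thr2[f] + runif(1, 0, 20)
    up <- run_hst(make_responder(simulated_listener(thr2)), tbl)$assigned_scale
    expect_gte(rank_of(up), rank_of(base))
  }
})

test_that("logged scale sequence moves in single steps and is unimodal", {
  tbl <- scale_table()
  set.seed(5)
  for (i in 1:100) {
    thr <- random_thresholds()
    r <- run_hst(make_responder(simulated_listener(thr)), tbl)
    sc <- unique(r$presentations$scale)  # scale per visited block, in order
    expect_equal(sc[1], 5)               # start scale
    if (length(sc) > 1) {
      d <- diff(sc)
      expect_true(all(abs(d) == 1))      # one scale at a time
      expect_true(all(d == d[1]))        # descend-only or ascend-only
    }
    # logged levels agree with the scale table at every presentation
    lv <- mapply(function(f, s) scale_level(tbl, f, s),
                 r$presentations$frequency_hz, r$presentations$scale)
    expect_equal(unname(lv), r$presentations$level_db_hl)
    # classification field always matches classify_scale of the result
    expect_equal(r$classification, classify_scale(r$assigned_scale))
  }
})

test_that("test-retest agrees exactly for deterministic listeners", {
  set.seed(11)
  tr <- test_retest(make_responder(det_listener("1000" = 18)), scale_table())
  expect_true(tr$match)
  expect_equal(tr$scale_difference, 0L)

  # both NR: agreement with difference 0 by convention
  tr <- test_retest(make_responder(det_listener(all = 60)), scale_table())
  expect_true(is.na(tr$test$assigned_scale))
  expect_true(tr$match)
  expect_equal(tr$scale_difference, 0L)
})

test_that("test-retest of steep-slope listeners stays within one scale", {
  set.seed(2024)
  n <- 200
  within_one <- logical(n)
  for (i in 1:n) {
    l <- simulated_listener(setNames(runif(4, 0, 40), FREQS), slope_db = 0.5)
    tr <- test_retest(make_responder(l), scale_table())
    d <- tr$scale_difference
    within_one[i] <- !is.na(d) && abs(d) <= 1
  }
  expect_gte(mean(within_one), 0.95)
})

test_that("session duration sums tone durations and realized silent intervals", {
  set.seed(3)
  r <- run_hst(make_responder(det_listener(all = 60)), scale_table())
  # NR path visits S_5..S_10 with aborts; duration equals the log's own sums
  expect_equal(estimate_session_duration(r),
               nrow(r$presentations) * 1.5 + sum(r$presentations$isi_s))
  # empty log -> 0
  empty <- r; empty$presentations <- r$presentations[0, ]
  expect_equal(estimate_session_duration(empty), 0)
  # worst case: 10 scales x 4 tones x (1.5 s tone + <= 3 s gap) <= 180 s
  l <- simulated_listener(setNames(rep(60, 4), FREQS))
  cfg <- engine_config(abort_scale_on_first_miss = FALSE)
  r <- run_hst(make_responder(l), scale_table(), cfg)
  expect_lte(estimate_session_duration(r), 180)
})

test_that("strict mode presents all four tones per scale", {
  set.seed(4)
  cfg <- engine_config(abort_scale_on_first_miss = FALSE)
  r <- run_hst(make_responder(det_listener(all = 60)), scale_table(), cfg)
  expect_equal(nrow(r$presentations), 6 * 4)  # S_5..S_10, 4 tones each
  per_scale <- table(r$presentations$scale)
  expect_true(all(per_scale == 4))
})

test_that("engine rejects non-conforming configurations", {
  expect_error(engine_config(start_scale = 0), "positive integer")
  expect_error(run_hst(function(f, l) TRUE, scale_table(),
                       engine_config(start_scale = 15)), "max_scale")
  expect_error(run_hst(function(f, l) TRUE, scale_table(),
                       engine_config(tone_order = c(1000, 2000))),
               "permutation")
})
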