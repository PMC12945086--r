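mk_set <- function(t, sel, uid = "u01") set_event(uid, t, sel)
mk_rev <- function(t, perf, extras = character(), uid = "u01")
  review_event(uid, t, perf, extras)

test_that("set-review pairing enforces the strict 12-36 hour window", {
  t0 <- "2026-01-05T20:00:00"
  # 24 h gap pairs
  log <- tiny_log(list(mk_set(t0, c("A", "B")),
                       mk_rev("2026-01-06T20:00:00", c(A = TRUE, B = FALSE))))
  p <- pair_set_review(log)
  expect_identical(nrow(p), 1L)
  expect_equal(p$gap_hours, 24)
  expect_identical(p$Y, 1L)
  expect_identical(p$week_index, 1L)

  # exactly 12 h is excluded (strict inequality), as is 40 h
  for (t_rev in c("2026-01-06T08:00:00", "2026-01-07T12:00:00")) {
    log <- tiny_log(list(mk_set(t0, "A"), mk_rev(t_rev, c(A = TRUE))))
    p <- pair_set_review(log)
    expect_identical(nrow(p), 0L)
    expect_identical(attr(p, "drop_report")$unmatched_reviews, 1L)
    expect_identical(attr(p, "drop_report")$unmatched_sets, 1L)
  }

  # one-to-one: the earlier of two reviews in a set's window claims it
  log <- tiny_log(list(
    mk_set(t0, "A"),
    mk_rev("2026-01-06T10:00:00", c(A = TRUE)),
    mk_rev("2026-01-06T20:00:00", c(A = FALSE))))
  p <- pair_set_review(log)
  expect_identical(nrow(p), 1L)
  expect_identical(p$review_time, "2026-01-06T10:00:00")
  expect_identical(attr(p, "drop_report")$unmatched_reviews, 1L)

  # performed keys outside the matched selection is a malformed log
  log <- tiny_log(list(mk_set(t0, "A"),
                       mk_rev("2026-01-06T20:00:00", c(A = TRUE, Q = TRUE))))
  expect_error(pair_set_review(log), "malformed log")
})

test_that("pairing never yields a gap outside (12, 36) hours", {
  set.seed(31)
  base <- as.POSIXct("2026-01-05T00:00:00", format = "%Y-%m-%dT%H:%M:%S",
                     tz = "UTC")
  for (rep in 1:15) {
    n_set <- sample(3:8, 1)
    sets <- sort(base + runif(n_set, 0, 20) * 86400)
    revs <- sort(base + runif(n_set, 0, 21) * 86400)
    events <- c(lapply(sets, function(t) mk_set(t, "A")),
                lapply(revs, function(t) mk_rev(t, c(A = TRUE))))
    ts <- vapply(events, `[[`, "", "timestamp")
    p <- pair_set_review(tiny_log(events[order(ts)]))
    expect_true(all(p$gap_hours > 12 & p$gap_hours < 36))
    # one-to-one
    expect_identical(anyDuplicated(p$set_time), 0L)
    expect_identical(anyDuplicated(p$review_time), 0L)
    rep_drop <- attr(p, "drop_report")
    expect_identical(nrow(p) + rep_drop$unmatched_reviews, n_set)
  }
})

test_that("mood scoring averages each subscale's items onto [0, 1]", {
  expect_equal(score_mood(rep(0, 9)),
               c(depression = 0, anxiety = 0, positive_affect = 0))
  expect_equal(score_mood(rep(100, 9)),
               c(depression = 1, anxiety = 1, positive_affect = 1))
  expect_equal(score_mood(c(20, 40, 60, rep(0, 6)))[["depression"]], 0.40)
  # a permuted mapping reassigns items
  m <- list(depression = 7:9, anxiety = 1:3, positive_affect = 4:6)
  expect_equal(score_mood(c(30, 30, 30, 60, 60, 60, 90, 90, 90), m),
               c(depression = 0.9, anxiety = 0.3, positive_affect = 0.6))

  expect_error(score_mood(rep(10, 8)), "9")
  expect_error(score_mood(c(rep(10, 8), 101)), "\\[0, 100\\]")
  expect_error(score_mood(rep(10, 9),
                          list(depression = 1:4, anxiety = 5:6,
                               positive_affect = 7:9)),
               "exactly one")
  expect_error(mood_observation("u01", "2026-01-05T10:00:00", rep(10, 8)),
               "9 items")
})

test_that("daily outcome counts performed selections plus extras, order-free", {
  expect_identical(compute_daily_outcome(c(A = TRUE, B = TRUE, C = FALSE), "D"), 3L)
  expect_identical(compute_daily_outcome(c(A = FALSE, B = FALSE)), 0L)
  expect_identical(compute_daily_outcome(setNames(rep(TRUE, 5), letters[1:5]),
                                         c("x", "y")), 7L)
  perf <- c(A = TRUE, B = FALSE, C = TRUE)
  expect_identical(compute_daily_outcome(perf, c("D", "E")),
                   compute_daily_outcome(rev(perf), c("E", "D")))
})

test_that("use rate is distinct review days over scheduled days", {
  day_reviews <- function(days)
    lapply(days, function(d)
      mk_rev(sprintf("2026-01-%02dT20:00:00", d), c(A = TRUE)))
  expect_identical(unname(compute_use_rate(tiny_log(day_reviews(1:28)))), 100)
  expect_identical(unname(compute_use_rate(tiny_log(day_reviews(1:21)))), 75)
  # a 26-day denominator reproduces a 76.9% minimum
  expect_identical(
    unname(compute_use_rate(tiny_log(day_reviews(1:20)), scheduled_days = 26)),
    76.9)
  # two reviews on one calendar day count once
  log2 <- tiny_log(c(day_reviews(1:3),
                     list(mk_rev("2026-01-03T21:30:00", c(A = FALSE)))))
  expect_identical(unname(compute_use_rate(log2)), round(100 * 3 / 28, 1))
  expect_error(compute_use_rate(tiny_log(day_reviews(1:10)), scheduled_days = 5),
               "log error")
  expect_identical(unname(compute_use_rate(tiny_log(list()))), 0)
})

test_that("weight deltas use the latest observation strictly before the review", {
  d <- function(n) sprintf("2026-01-%02dT07:00:00", n)
  w <- weight_deltas(c(d(1), d(11)), c(90, 89), d(12))
  expect_equal(w$delta_baseline, -1)
  expect_equal(w$delta_previous, -1)

  w1 <- weight_deltas(d(1), 90, d(5))
  expect_equal(w1$delta_baseline, 0)
  expect_true(w1$missing_previous)
  expect_true(is.na(w1$delta_previous))

  w3 <- weight_deltas(c(d(1), d(2), d(3)), c(90, 91, 89), d(4))
  expect_equal(w3$delta_baseline, -1)
  expect_equal(w3$delta_previous, -2)

  # "strictly before": an observation at the query time is ignored
  w4 <- weight_deltas(c(d(1), d(2)), c(90, 91), d(2))
  expect_equal(w4$delta_baseline, 0)

  expect_error(weight_deltas(d(5), 90, d(4)), "missing covariate")
})

test_that("event logs round-trip through JSON Lines unchanged", {
  events <- list(
    mk_set("2026-01-05T20:30:00", c("A", "B")),
    weight_observation("u01", "2026-01-06T07:00:00", 93.6),
    mood_observation("u01", "2026-01-06T10:00:00",
                     c(20, 35, 50, 10, 0, 100, 60, 55, 45)),
    mk_rev("2026-01-06T20:00:00", c(A = TRUE, B = FALSE), extras = "C"))
  log <- study_log(users = list(list(user_id = "u01", seed = 5L,
                                     sex = "female", bmi_start = 34.9,
                                     psych_comorbidity = TRUE)),
                   events = events)
  path <- tempfile(fileext = ".jsonl")
  on.exit(unlink(path))
  write_event_log(log, path)
  back <- read_event_log(path)
  expect_identical(back$events, log$events)
  expect_identical(back$header$users[[1]]$user_id, "u01")
  expect_identical(back$header$users[[1]]$bmi_start, 34.9)
  expect_identical(back$header$tz, "UTC")
})

test_that("the analysis table joins outcome, preceding mood, weight, baseline", {
  events <- list(
    weight_observation("u01", "2026-01-05T07:00:00", 90),
    mk_set("2026-01-05T20:30:00", c("A", "B")),
    weight_observation("u01", "2026-01-06T07:00:00", 89.2),
    mood_observation("u01", "2026-01-06T02:00:00",
                     c(90, 90, 90, 10, 10, 10, 50, 50, 50)), # stale-r mood
    mood_observation("u01", "2026-01-06T10:00:00",
                     c(20, 40, 60, 30, 30, 30, 60, 60, 60)), # latest in window
    mk_rev("2026-01-06T20:00:00", c(A = TRUE, B = FALSE), extras = "C"))
  log <- study_log(users = list(list(user_id = "u01", seed = 5L,
                                     sex = "female", bmi_start = 37.5,
                                     psych_comorbidity = FALSE)),
                   events = events)
  tab <- build_analysis_table(log)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$Y, 2L)
  expect_equal(tab$depression, 0.40)
  expect_equal(tab$anxiety, 0.30)
  expect_equal(tab$positive_affect, 0.60)
  expect_equal(tab$delta_weight_baseline, -0.8)
  expect_equal(tab$delta_weight_previous, -0.8)
  expect_identical(tab$sex, "female")
  expect_equal(tab$bmi_centered, 2.5)
  expect_identical(tab$psych_comorbidity, 0)

  # no mood in the 24 h window => record dropped and counted
  log2 <- study_log(users = log$header$users,
                    events = events[c(1, 2, 3, 6)])
  tab2 <- build_analysis_table(log2)
  expect_identical(nrow(tab2), 0L)
  expect_identical(attr(tab2, "drop_report")$no_mood_in_window, 1L)
})
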