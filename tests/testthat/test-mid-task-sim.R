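test_that("staircase adjusts every third trial toward the target", {
  p <- mid_behavior_params()
  # below-target accuracy on an adjustment trial lengthens the probe
  expect_equal(
    staircase_update(0.3, c("Hit", "Hit", "TooSlow", "TooSlow", "TooSlow",
                            "TooSlow"), 3, p),
    0.3 + p$staircase_step)
  # at-or-above-target accuracy shortens it
  expect_equal(
    staircase_update(0.3, c(rep("Hit", 4), "TooSlow", "TooSlow"), 6, p),
    0.3 - p$staircase_step)
  # non-multiple-of-three trials never adjust
  expect_equal(staircase_update(0.3, rep("TooSlow", 6), 4, p), 0.3)
  # clamped at the probe bounds
  expect_equal(staircase_update(p$probe_min, rep("Hit", 6), 3, p),
               p$probe_min)
  expect_equal(staircase_update(p$probe_max, rep("TooSlow", 6), 3, p),
               p$probe_max)
})

test_that("outcome classification follows the press-window rules", {
  # any press before probe onset: Too Soon, and no RT without a second
  # press after onset
  r <- classify_outcome(9.5, 10, 10.3)
  expect_equal(r$outcome, "TooSoon")
  expect_true(is.na(r$rt))
  # a second press after onset grants the Too Soon trial an RT
  r <- classify_outcome(c(9.5, 10.4), 10, 10.3)
  expect_equal(r$outcome, "TooSoon")
  expect_equal(r$rt, 0.4)
  # no presses: Too Slow, no RT
  r <- classify_outcome(numeric(0), 10, 10.3)
  expect_equal(r$outcome, "TooSlow")
  expect_true(is.na(r$rt))
  # press inside the window: Hit with RT from probe onset
  r <- classify_outcome(10.2, 10, 10.3)
  expect_equal(r$outcome, "Hit")
  expect_equal(r$rt, 0.2)
  # late press: Too Slow but RT still recorded
  r <- classify_outcome(10.5, 10, 10.3)
  expect_equal(r$outcome, "TooSlow")
  expect_equal(r$rt, 0.5)
  expect_error(classify_outcome(c(10.4, 10.2), 10, 10.3), "sorted")
})

test_that("simulated runs have the MID trial structure", {
  run <- fixture_run(1)
  expect_s3_class(run, "mid_run")
  expect_equal(nrow(run), 50)
  # exactly 10 trials per condition
  expect_true(all(table(run$condition) == 10))
  # contiguous events: each component starts where the previous ended,
  # and trials abut with no inter-trial interval
  expect_equal(run$fixation_onset, run$cue_onset + run$cue_duration,
               tolerance = 1e-9)
  expect_equal(run$probe_onset,
               run$fixation_onset + run$fixation_duration,
               tolerance = 1e-9)
  expect_equal(run$feedback_onset, run$probe_onset + run$probe_duration,
               tolerance = 1e-9)
  expect_equal(run$cue_onset[-1],
               (run$feedback_onset + run$feedback_duration)[-50],
               tolerance = 1e-9)
  expect_equal(run$cue_onset[1], 0)
  # component durations inside the task's ranges
  expect_true(all(run$cue_duration >= 1.781 & run$cue_duration <= 2.039))
  expect_true(all(run$fixation_duration >= 1.5 &
                    run$fixation_duration <= 3.666))
  expect_true(all(run$probe_duration >= 0.150 &
                    run$probe_duration <= 0.500))
  # feedback fills the remainder of a fixed feedback+probe envelope
  expect_equal(run$feedback_duration, 1.950 - run$probe_duration,
               tolerance = 1e-9)
  # recorded RTs inside the recordable window
  rts <- run$rt[!is.na(run$rt)]
  expect_true(all(rts >= 0.105 & rts <= 1.581))
  expect_equal(attr(run, "total_duration"),
               run$feedback_onset[50] + run$feedback_duration[50])
})

test_that("identical seeds reproduce runs exactly and RNG state is safe", {
  a <- simulate_mid_run(seed = 99)
  set.seed(7)
  before <- runif(1)
  b <- simulate_mid_run(seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  set.seed(7)
  expect_identical(before, runif(1))
  expect_false(identical(as.data.frame(a),
                         as.data.frame(simulate_mid_run(seed = 100))))
})

test_that("an instantly-responding subject drives the probe to its floor", {
  p <- mid_behavior_params(rt_location = 0.001, rt_scale = 0.05,
                           rt_shift = 0.01, fixation_benefit = 0,
                           p_too_soon_base = 0)
  tr <- simulate_mid_trials(300, params = p, seed = 5)
  expect_true(all(tr$probe_duration[200:300] == p$probe_min))
})

test_that("staircase converges near the target accuracy", {
  tr <- simulate_mid_trials(5000, seed = 23)
  hit <- mean(tr$outcome[-(1:200)] == "Hit")
  expect_gt(hit, 0.55)
  expect_lt(hit, 0.65)
})

test_that("long-run behavior matches the calibrated asymmetries", {
  trials <- simulate_mid_trials(8000, seed = 31)[-(1:200), ]
  props <- prop.table(table(trials$outcome))
  # outcome mix near the 57/36/7 percent split
  expect_equal(unname(props[["Hit"]]), 0.57, tolerance = 0.08)
  expect_equal(unname(props[["TooSlow"]]), 0.36, tolerance = 0.12)
  expect_equal(unname(props[["TooSoon"]]), 0.07, tolerance = 0.35)
  b <- summarize_behavior(trials)
  g <- function(m, grp) b$mean[b$measure == m & b$group == grp]
  # probe slightly longer on hits (staircase-coupled)
  expect_gt(g("probe_duration", "Hit") - g("probe_duration", "Miss"),
            0.015)
  expect_lt(g("probe_duration", "Hit") - g("probe_duration", "Miss"),
            0.045)
  # fixation longer on hits (preparation benefit)
  gap_fix <- g("fixation_duration", "Hit") - g("fixation_duration", "Miss")
  expect_gt(gap_fix, 0.04)
  expect_lt(gap_fix, 0.20)
  # misses have slower recorded RTs
  gap_rt <- g("rt", "Miss") - g("rt", "Hit")
  expect_gt(gap_rt, 0.05)
  expect_lt(gap_rt, 0.15)
  # premature-press trials follow much longer fixations
  gap_ts <- g("fixation_duration", "TooSoon") -
    g("fixation_duration", "TooSlow")
  expect_gt(gap_ts, 0.45)
  expect_lt(gap_ts, 1.1)
})

test_that("behavior summaries flag empty outcome cells", {
  run <- fixture_run(1)
  hits <- run[run$outcome == "Hit", ]
  b <- summarize_behavior(hits)
  expect_true(all(b$n[b$group %in% c("Miss", "TooSlow", "TooSoon")] == 0))
  expect_true(all(is.na(b$mean[b$group == "Miss"])))
  expect_true(all(b$n[b$group == "Hit"] > 0))
})

test_that("events tables round-trip losslessly", {
  run <- fixture_run(2)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_events(run, tmp)
  back <- read_events(tmp)
  expect_equal(nrow(readr::read_tsv(tmp, show_col_types = FALSE)), 200)
  expect_equal(lapply(back, c), lapply(run, c), tolerance = 1e-12)
})

test_that("events reader validates its input", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(onset = c(0, 1), duration = c(1, -1),
                                  trial_type = c("cue_Neutral",
                                                 "fixation_Neutral")),
                   tmp)
  expect_error(read_events(tmp), "nonnegative")
  readr::write_tsv(tibble::tibble(onset = 0, trial_type = "cue_Neutral"),
                   tmp)
  expect_error(read_events(tmp), "duration")
  readr::write_tsv(tibble::tibble(onset = c(1, 0), duration = c(1, 1),
                                  trial_type = c("cue_Neutral",
                                                 "fixation_Neutral")),
                   tmp)
  expect_error(read_events(tmp), "non-decreasing")
})

test_that("staircase state chains across runs", {
  run1 <- simulate_mid_run(seed = 3)
  run2 <- simulate_mid_run(seed = 4,
                           probe_init = attr(run1, "staircase_probe"),
                           prev_outcomes = attr(run1,
                                                "staircase_outcomes"))
  expect_equal(run2$probe_duration[1], attr(run1, "staircase_probe"))
  # trial 51 overall is an adjustment trial (index 1 of run 2 is not a
  # multiple of 3 locally, but the carried outcomes affect trial 3)
  expect_equal(run2$cue_onset[1], 0)
})
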