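test_that("double-gamma kernel has the canonical shape", {
  k <- hrf_kernel(hrf_spec())
  expect_equal(k$kernel[1], 0)
  peak_t <- k$time[which.max(k$kernel)]
  expect_gt(peak_t, 4.5)
  expect_lt(peak_t, 6.5)
  # undershoot after the peak
  late <- k$kernel[k$time > 10 & k$time < 25]
  expect_lt(min(late), 0)
  # unit integral; derivative of a pulse integrates to ~0
  expect_equal(sum(k$kernel) * k$dt, 1, tolerance = 1e-8)
  expect_equal(sum(k$derivative) * k$dt, 0, tolerance = 1e-3)
  expect_error(hrf_spec(microtime_dt = -1), "positive")
})

test_that("convolution matches a brute-force microtime oracle", {
  hrf <- hrf_spec()
  ft <- seq(0, 100, by = 0.8)
  onsets <- c(3.17, 21.4, 55.03, 80.6)
  for (durs in list(0, c(1.9, 2.3, 0.3, 1.1))) {
    ours <- convolve_regressor(ft, onsets, durs, hrf = hrf)[, 1]
    oracle <- oracle_convolve(ft, onsets, durs, hrf)
    expect_equal(ours, oracle, tolerance = 5e-3)
  }
})

test_that("boxcar duration scales the response amplitude", {
  ft <- seq(0, 120, by = 0.8)
  one <- convolve_regressor(ft, 30, 1)
  two <- convolve_regressor(ft, 30, 2)
  expect_equal(max(two) / max(one), 2, tolerance = 0.2)
  # impulse equals a matched-area short boxcar in the limit
  imp <- convolve_regressor(ft, 30, 0)
  short <- convolve_regressor(ft, 30, 0.001, amplitudes = 1000)
  expect_equal(imp[, 1], short[, 1], tolerance = 1e-3)
  expect_error(convolve_regressor(ft, numeric(0)), "all zero")
  expect_error(convolve_regressor(ft, 30, 1, amplitudes = 0), "zero")
})

test_that("convolution is linear and shift-equivariant", {
  ft <- seq(0, 150, by = 0.8)
  a <- c(5, 42.3)
  b <- c(20.8, 90.1)
  both <- convolve_regressor(ft, c(a, b), 1.5)[, 1]
  parts <- convolve_regressor(ft, a, 1.5)[, 1] +
    convolve_regressor(ft, b, 1.5)[, 1]
  expect_equal(both, parts, tolerance = 1e-10)
  k <- 5L
  shifted <- convolve_regressor(ft, a + k * 0.8, 1.5)[, 1]
  base <- convolve_regressor(ft, a, 1.5)[, 1]
  n <- length(ft)
  expect_equal(shifted[(k + 1):n], base[1:(n - k)], tolerance = 1e-8)
})

test_that("CueFeedback builder yields 30 task regressors with derivatives", {
  run <- fixture_complete_run()
  d <- build_cuefeedback_design(run)
  task <- design_cols <- names(d$roles)[d$roles %in% c("task",
                                                       "derivative")]
  expect_length(task, 30)
  expect_true("cue_LargeWin_derivative" %in% task)
  expect_true("feedback_LargeWin_hit" %in% task)
  expect_true(all(c("feedback_Neutral_miss", "cue_SmallLoss") %in% task))
  # no all-zero task columns
  expect_true(all(colSums(abs(d$values[, task])) > 0))
})

test_that("empty feedback cells are dropped with a warning", {
  run <- fixture_run(1)
  # force all LargeWin trials to hits so largewin_miss is empty
  run$outcome[run$condition == "LargeWin"] <- "Hit"
  expect_warning(d <- build_cuefeedback_design(run),
                 "feedback_LargeWin_miss")
  task <- names(d$roles)[d$roles %in% c("task", "derivative")]
  expect_length(task, 28)
  expect_true("feedback_LargeWin_miss" %in% d$dropped)
})

test_that("Saturated builder yields 24 boxcar task regressors", {
  run <- fixture_complete_run()
  d <- build_saturated_design(run)
  task <- names(d$roles)[d$roles == "task"]
  expect_length(task, 24)
  expect_equal(sum(d$roles == "derivative"), 0)
  expect_setequal(
    task[grepl("^probe", task)],
    c("probe_win", "probe_loss", "probe_neutral"))
  expect_true("rt" %in% task)
  # probe columns pool large+small within valence: the win probe regressor
  # covers every win trial's probe window
  win_trials <- run$condition %in% c("LargeWin", "SmallWin")
  expect_equal(sum(win_trials), 20)
})

test_that("runs with no recorded RTs lose the RT regressor", {
  run <- fixture_run(1)
  run$rt <- NA_real_
  run$outcome[run$outcome == "Hit"] <- "TooSlow"  # hits imply an RT
  w <- capture_warnings(d <- build_saturated_design(run))
  expect_true(any(grepl("`rt`", w)))
  task <- names(d$roles)[d$roles == "task"]
  expect_false("rt" %in% task)
})

test_that("cosine drift basis has the right order and orthogonality", {
  ft <- seq(0, by = 0.8, length.out = 400)  # 320 s
  dr <- cosine_drift(ft, cutoff = 128)
  expect_equal(ncol(dr), 5)  # floor(2 * 320 / 128)
  gram <- crossprod(dr)
  expect_equal(gram, diag(diag(gram)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # cutoff longer than twice the run: single slowest cosine
  expect_equal(ncol(cosine_drift(ft, cutoff = 2 * 320 + 10)), 1)
  expect_error(cosine_drift(ft, cutoff = 1), "cutoff")
  expect_error(cosine_drift(ft[1], cutoff = 128), "two frames")
})

test_that("run concatenation stacks frames and isolates nuisance blocks", {
  r1 <- fixture_run(1)
  r2 <- fixture_run(2)
  d1 <- build_saturated_design(r1, drift_cutoff = 128)
  d2 <- build_saturated_design(r2, drift_cutoff = 128)
  cc <- concatenate_runs(list(d1, d2))
  expect_equal(nrow(cc$values), nrow(d1$values) + nrow(d2$values))
  # one intercept per run, each supported only on its own frames
  ints <- names(cc$roles)[cc$roles == "intercept"]
  expect_length(ints, 2)
  n1 <- nrow(d1$values)
  expect_true(all(cc$values[seq_len(n1), "run2_intercept"] == 0))
  expect_true(all(cc$values[-seq_len(n1), "run1_intercept"] == 0))
  # a column missing from one run is zero-filled over that run's frames
  run3 <- fixture_run(1)
  run3$outcome[run3$condition == "LargeWin"] <- "Hit"
  d3 <- suppressWarnings(build_saturated_design(run3,
                                                drift_cutoff = 128))
  cc2 <- concatenate_runs(list(d3, d2))
  n3 <- nrow(d3$values)
  expect_true(all(cc2$values[seq_len(n3), "feedback_LargeWin_miss"] == 0))
  expect_gt(sum(abs(cc2$values[-seq_len(n3),
                               "feedback_LargeWin_miss"])), 0)
  expect_error(concatenate_runs(list(d1, build_saturated_design(r2,
                                                                tr = 1))),
               "same tr")
})

test_that("standard contrasts carry the published weights", {
  run <- fixture_complete_run()
  d <- build_saturated_design(run, drift_cutoff = 128)
  cons <- make_contrasts(d)
  expect_equal(nrow(cons), 7)
  w <- cons$weights[[match("FB:WHit-WMiss", cons$name)]]
  expect_equal(w[c("feedback_LargeWin_hit", "feedback_SmallWin_hit",
                   "feedback_LargeWin_miss", "feedback_SmallWin_miss")],
               c(feedback_LargeWin_hit = 0.5, feedback_SmallWin_hit = 0.5,
                 feedback_LargeWin_miss = -0.5,
                 feedback_SmallWin_miss = -0.5))
  w <- cons$weights[[match("Cue:LW-Base", cons$name)]]
  expect_equal(w, c(cue_LargeWin = 1))
  expect_setequal(cons$name[cons$starred],
                  c("Cue:LW-Neut", "Cue:LL-Neut", "FB:WHit-WMiss",
                    "FB:LHit-LMiss"))
  # expanded vectors put zero weight everywhere else, incl. nuisance
  full <- midvif:::contrast_vector(d, cons$weights[[1]])
  nuis <- names(d$roles)[d$roles %in% c("nuisance", "intercept")]
  expect_true(all(full[nuis] == 0))
  # contrasts referencing dropped columns are skipped with a warning
  run2 <- fixture_run(1)
  run2$outcome[run2$condition == "LargeWin"] <- "Hit"
  d2 <- suppressWarnings(build_cuefeedback_design(run2))
  expect_warning(cons2 <- make_contrasts(d2), "skipped")
  expect_false("FB:WHit-WMiss" %in% cons2$name)
})

test_that("designs survive a CSV + sidecar round trip", {
  run <- fixture_run(3)
  d <- build_saturated_design(run, drift_cutoff = 128)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_design(d, tmp)
  back <- read_design(tmp)
  expect_equal(back$values, d$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$roles, d$roles)
  expect_equal(back$tr, d$tr)
})
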