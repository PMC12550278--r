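#' Behavioral model parameters for the synthetic MID task
#'
#' Parameters of the generative behavioral model driving the synthetic
#' Monetary Incentive Delay (MID) task. Latent response times follow a
#' shifted log-normal distribution whose median decreases with the duration
#' of the preceding fixation (longer fixation, better preparation, faster
#' response); a trial is a Hit when the latent response time falls within
#' the probe window. Premature presses arise independently of the
#' response-time process, with a probability that grows with fixation
#' time beyond a patience threshold. The probe duration is driven by an
#' adaptive staircase targeting a fixed accuracy.
#'
#' Defaults are calibrated so long-run behavior matches the ABCD MID
#' statistics: roughly 57/36/7 percent Hit / Too Slow / Too Soon, probe
#' durations modestly longer on Hit trials, fixation ~60-160 ms longer on
#' Hit trials, response times ~80-100 ms longer on Miss trials, and
#' fixation ~0.7 s longer on Too Soon than Too Slow trials.
#'
#' @param rt_location Log-normal location: median latent response time
#'   (above `rt_shift`) at the average fixation duration, seconds.
#' @param rt_scale Log-normal scale (sdlog), dimensionless.
#' @param rt_shift Shift (minimum possible response time), seconds.
#' @param fixation_benefit Approximate hit-probability gain per second of
#'   fixation duration, evaluated at the distribution median.
#' @param p_too_soon_base Marginal probability of a premature press.
#'   Premature presses arise from impatience: their conditional
#'   probability grows linearly with fixation time beyond
#'   `too_soon_onset`, normalized so the average over the fixation
#'   distribution equals `p_too_soon_base` (this is what makes premature
#'   trials have markedly longer fixations, as observed).
#' @param too_soon_onset Fixation duration (seconds) below which
#'   premature presses do not occur.
#' @param staircase_step Probe-duration adjustment per staircase update,
#'   seconds.
#' @param probe_min,probe_max Probe duration bounds, seconds.
#' @param probe_init Initial probe duration, seconds.
#' @param target_accuracy Staircase accuracy target, proportion.
#' @param rt_max Longest press latency that is still recorded, seconds.
#'
#' @return An object of class `mid_behavior_params`.
#' @export
mid_behavior_params <- function(rt_location = 0.190,
                                rt_scale = 0.32,
                                rt_shift = 0.105,
                                fixation_benefit = 0.18,
                                p_too_soon_base = 0.07,
                                too_soon_onset = 2.15,
                                staircase_step = 0.020,
                                probe_min = 0.150,
                                probe_max = 0.500,
                                probe_init = 0.300,
                                target_accuracy = 0.60,
                                rt_max = 1.581) {
  p <- list(rt_location = rt_location, rt_scale = rt_scale,
            rt_shift = rt_shift, fixation_benefit = fixation_benefit,
            p_too_soon_base = p_too_soon_base,
            too_soon_onset = too_soon_onset,
            staircase_step = staircase_step,
            probe_min = probe_min, probe_max = probe_max,
            probe_init = probe_init, target_accuracy = target_accuracy,
            rt_max = rt_max)
  if (!(p$probe_min < p$probe_init && p$probe_init < p$probe_max)) {
    stop("require probe_min < probe_init < probe_max", call. = FALSE)
  }
  if (p$p_too_soon_base < 0 || p$p_too_soon_base > 1) {
    stop("p_too_soon_base must lie in [0, 1]", call. = FALSE)
  }
  if (p$target_accuracy <= 0 || p$target_accuracy >= 1) {
    stop("target_accuracy must lie in (0, 1)", call. = FALSE)
  }
  if (p$rt_location <= 0 || p$rt_scale <= 0 || p$staircase_step <= 0) {
    stop("rt_location, rt_scale and staircase_step must be positive",
         call. = FALSE)
  }
  structure(p, class = "mid_behavior_params")
}

# trial-component timing constants of the ABCD MID variant (seconds)
mid_timing <- function() {
  list(cue_range = c(1.781, 2.039),
       fixation_range = c(1.500, 3.666),
       feedback_total = 1.950,
       conditions = c("LargeWin", "SmallWin", "Neutral",
                      "LargeLoss", "SmallLoss"),
       n_per_condition = 10)
}

#' Adaptive staircase update for the probe duration
#'
#' The probe duration is adjusted on every third trial, using the hit
#' accuracy over the last six trials pooled across all cue conditions: when
#' accuracy is below the target the probe lengthens (easier), otherwise it
#' shortens, always clamped to the allowed probe range.
#'
#' @param current_probe_duration Current probe duration, seconds.
#' @param last_six_outcomes Character vector of the most recent trial
#'   outcomes (up to six of `"Hit"`, `"TooSoon"`, `"TooSlow"`).
#' @param trial_index 1-based index of the trial just completed.
#' @param params A [mid_behavior_params()].
#' @return The probe duration for the next trial, seconds.
#' @examples
#' p <- mid_behavior_params()
#' staircase_update(0.3, rep(c("Hit", "TooSlow"), 3), 3, p)  # lengthens
#' @export
staircase_update <- function(current_probe_duration, last_six_outcomes,
                             trial_index, params = mid_behavior_params()) {
  stopifnot(trial_index >= 1)
  if (trial_index %% 3L != 0L || length(last_six_outcomes) == 0L) {
    return(current_probe_duration)
  }
  outcomes <- utils::tail(last_six_outcomes, 6L)
  acc <- mean(outcomes == "Hit")
  out <- if (acc < params$target_accuracy) {
    current_probe_duration + params$staircase_step
  } else {
    current_probe_duration - params$staircase_step
  }
  min(max(out, params$probe_min), params$probe_max)
}

#' Classify a trial outcome from button-press times
#'
#' A trial is Too Soon if any press precedes probe onset, a Hit if a press
#' falls inside the probe window, and Too Slow otherwise. The response time
#' is the latency of the first press after probe onset; Too Soon trials
#' only receive a response time when a secondary press occurs after probe
#' onset.
#'
#' @param press_times Sorted (ascending) press times, seconds from run
#'   start; may be empty.
#' @param probe_onset,probe_offset Probe window, seconds from run start.
#' @return A list with `outcome` (`"Hit"`, `"TooSoon"` or `"TooSlow"`) and
#'   `rt` (seconds, or `NA_real_` when absent).
#' @examples
#' classify_outcome(numeric(0), 10, 10.3)           # TooSlow, no RT
#' classify_outcome(c(10.2), 10, 10.3)              # Hit, RT 0.2
#' @export
classify_outcome <- function(press_times, probe_onset, probe_offset) {
  if (is.unsorted(press_times)) {
    stop("press_times must be sorted ascending", call. = FALSE)
  }
  after <- press_times[press_times >= probe_onset]
  rt <- if (length(after)) after[[1L]] - probe_onset else NA_real_
  outcome <- if (length(press_times) && any(press_times < probe_onset)) {
    "TooSoon"
  } else if (length(after) && after[[1L]] <= probe_offset) {
    "Hit"
  } else {
    "TooSlow"
  }
  list(outcome = outcome, rt = rt)
}

# conditional premature-press probability given the fixation duration:
# linear-in-excess hazard above the patience threshold, normalized so the
# marginal over the uniform fixation distribution is p_too_soon_base
p_too_soon <- function(params, fixation_duration) {
  tm <- mid_timing()
  f0 <- params$too_soon_onset
  upper <- tm$fixation_range[2]
  width <- diff(tm$fixation_range)
  if (f0 >= upper) return(params$p_too_soon_base)
  norm <- (upper - f0)^2 / (2 * width)  # E[(F - f0)+]
  min(1, params$p_too_soon_base * max(0, fixation_duration - f0) / norm)
}

# draw one latent response time (seconds from probe onset)
draw_latent_rt <- function(params, fixation_duration) {
  tm <- mid_timing()
  fix_mid <- mean(tm$fixation_range)
  # log-median shrinks with fixation so that d P(hit) / d fixation at the
  # median equals fixation_benefit
  meanlog <- log(params$rt_location) -
    params$fixation_benefit * params$rt_scale * sqrt(2 * pi) *
      (fixation_duration - fix_mid)
  params$rt_shift + stats::rlnorm(1L, meanlog = meanlog,
                                  sdlog = params$rt_scale)
}

# core trial engine: generates `conditions` trials sequentially, carrying
# the staircase state; assumes the RNG is already seeded by the caller
simulate_trials_engine <- function(conditions, params,
                                   probe_start = params$probe_init,
                                   prev_outcomes = character(),
                                   start_index = 1L) {
  tm <- mid_timing()
  n <- length(conditions)
  probe <- probe_start
  outcomes_hist <- prev_outcomes
  t_now <- 0
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cue_dur <- stats::runif(1L, tm$cue_range[1], tm$cue_range[2])
    fix_dur <- stats::runif(1L, tm$fixation_range[1], tm$fixation_range[2])
    probe_dur <- probe
    fb_dur <- tm$feedback_total - probe_dur
    cue_on <- t_now
    fix_on <- cue_on + cue_dur
    probe_on <- fix_on + fix_dur
    fb_on <- probe_on + probe_dur

    presses <- numeric(0)
    if (stats::runif(1L) < p_too_soon(params, fix_dur)) {
      lo <- min(params$too_soon_onset, fix_dur)
      presses <- fix_on + stats::runif(1L, lo, fix_dur)
    }
    latent <- draw_latent_rt(params, fix_dur)
    if (latent <= params$rt_max) {
      presses <- sort(c(presses, probe_on + latent))
    }
    cls <- classify_outcome(presses, probe_on, probe_on + probe_dur)

    rows[[i]] <- list(
      trial_index = start_index + i - 1L,
      condition = conditions[[i]],
      cue_onset = cue_on, cue_duration = cue_dur,
      fixation_onset = fix_on, fixation_duration = fix_dur,
      probe_onset = probe_on, probe_duration = probe_dur,
      feedback_onset = fb_on, feedback_duration = fb_dur,
      outcome = cls$outcome, rt = cls$rt
    )
    outcomes_hist <- c(outcomes_hist, cls$outcome)
    probe <- staircase_update(probe, utils::tail(outcomes_hist, 6L),
                              start_index + i - 1L, params)
    t_now <- fb_on + fb_dur
  }
  trials <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  list(trials = trials, probe = probe,
       outcomes = utils::tail(outcomes_hist, 6L),
       total_duration = t_now)
}

#' Simulate one run of the synthetic MID task
#'
#' Generates a 50-trial run (10 trials per cue condition, in a seeded
#' pseudo-random order) with contiguous Cue, Fixation, Probe and Feedback
#' events (no inter-trial interval), an adaptive probe-duration staircase,
#' and outcomes drawn from the behavioral model in
#' [mid_behavior_params()].
#'
#' @param params A [mid_behavior_params()].
#' @param run_id Integer run identifier.
#' @param seed Integer seed fixing all randomness for the run.
#' @param probe_init Starting probe duration; defaults to
#'   `params$probe_init`. Supply the `staircase_probe` attribute of a
#'   previous run to continue its staircase.
#' @param prev_outcomes Outcomes of the trials preceding this run (used by
#'   the staircase when continuing across runs).
#' @return A tibble of class `mid_run` with one row per trial and columns
#'   `trial_index`, `condition`, per-component `*_onset`/`*_duration`,
#'   `outcome` and `rt`; attributes `run_id`, `total_duration`,
#'   `staircase_probe` and `staircase_outcomes`.
#' @examples
#' run <- simulate_mid_run(seed = 1)
#' table(run$outcome)
#' @export
simulate_mid_run <- function(params = mid_behavior_params(), run_id = 1L,
                             seed = 1L, probe_init = NULL,
                             prev_outcomes = character()) {
  stopifnot(inherits(params, "mid_behavior_params"))
  tm <- mid_timing()
  res <- with_preserved_seed(seed, {
    conds <- sample(rep(tm$conditions, each = tm$n_per_condition))
    simulate_trials_engine(conds, params,
                           probe_start = probe_init %||% params$probe_init,
                           prev_outcomes = prev_outcomes)
  })
  new_mid_run(res$trials, run_id = run_id,
              total_duration = res$total_duration,
              staircase_probe = res$probe,
              staircase_outcomes = res$outcomes)
}

new_mid_run <- function(trials, run_id, total_duration,
                        staircase_probe = NULL,
                        staircase_outcomes = NULL) {
  structure(trials,
            class = c("mid_run", class(tibble::tibble())),
            run_id = run_id,
            total_duration = total_duration,
            staircase_probe = staircase_probe,
            staircase_outcomes = staircase_outcomes)
}

#' Simulate a long sequence of MID trials
#'
#' Convenience wrapper used to study staircase convergence: simulates
#' `n_trials` consecutive trials (conditions cycled) with the staircase
#' carried throughout.
#'
#' @inheritParams simulate_mid_run
#' @param n_trials Number of trials.
#' @return A tibble with one row per trial (same columns as a `mid_run`).
#' @export
simulate_mid_trials <- function(n_trials, params = mid_behavior_params(),
                                seed = 1L) {
  stopifnot(n_trials >= 1)
  tm <- mid_timing()
  res <- with_preserved_seed(seed, {
    conds <- rep_len(tm$conditions, n_trials)
    simulate_trials_engine(conds, params)
  })
  res$trials
}

# evaluate `expr` under a fixed seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
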