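#' Write a MID run to a BIDS-style events table
#'
#' One row per trial component (cue, fixation, probe, feedback), with
#' `trial_type` encoding component and condition (and outcome for
#' feedback), `response_time` carried on probe rows, and `outcome` on every
#' row of the trial.
#'
#' @param run A `mid_run` (see [simulate_mid_run()]).
#' @param file Path of the TSV to write.
#' @return The events tibble, invisibly.
#' @export
write_events <- function(run, file) {
  ev <- events_table(run)
  out <- dplyr::mutate(
    ev,
    response_time = ifelse(is.na(.data$response_time), "n/a",
                           format(.data$response_time, digits = 15))
  )
  readr::write_tsv(out, file)
  invisible(ev)
}

# long (one row per component event) view of a run
events_table <- function(run) {
  stopifnot(nrow(run) >= 1)
  trials <- tibble::as_tibble(run)
  comp <- function(component, onset, duration, type) {
    tibble::tibble(
      onset = onset, duration = duration, trial_type = type,
      response_time = if (component == "probe") trials$rt else
        rep(NA_real_, nrow(trials)),
      outcome = trials$outcome, trial_index = trials$trial_index,
      component = component
    )
  }
  fb_out <- ifelse(trials$outcome == "Hit", "hit", "miss")
  ev <- dplyr::bind_rows(
    comp("cue", trials$cue_onset, trials$cue_duration,
         paste0("cue_", trials$condition)),
    comp("fixation", trials$fixation_onset, trials$fixation_duration,
         paste0("fixation_", trials$condition)),
    comp("probe", trials$probe_onset, trials$probe_duration,
         paste0("probe_", trials$condition)),
    comp("feedback", trials$feedback_onset, trials$feedback_duration,
         paste0("feedback_", trials$condition, "_", fb_out))
  )
  dplyr::arrange(ev, .data$onset, .data$trial_index)
}

#' Read a BIDS-style events table into a MID run
#'
#' Inverse of [write_events()]: reconstructs the per-trial representation
#' from the long events table. Requires `onset`, `duration` and
#' `trial_type` columns; `response_time` and `outcome` are used when
#' present.
#'
#' @param file Path to a TSV events file.
#' @param run_id Run identifier to attach.
#' @return A `mid_run` tibble.
#' @examples
#' f <- system.file("extdata", "sample_run_events.tsv",
#'                  package = "midvif")
#' run <- read_events(f)
#' head(run)
#' @export
read_events <- function(file, run_id = 1L) {
  ev <- readr::read_tsv(file, show_col_types = FALSE, na = c("n/a", "NA"))
  required <- c("onset", "duration", "trial_type")
  missing <- setdiff(required, names(ev))
  if (length(missing)) {
    stop("events table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(ev$onset)) {
    stop("event onsets must be non-decreasing", call. = FALSE)
  }
  if (any(ev$duration < 0)) {
    stop("event durations must be nonnegative", call. = FALSE)
  }
  parts <- strsplit(ev$trial_type, "_", fixed = TRUE)
  ev$component <- vapply(parts, `[[`, "", 1L)
  ev$condition <- vapply(parts, function(p) {
    if (length(p) >= 2) p[[2L]] else NA_character_
  }, "")
  bad <- !ev$component %in% c("cue", "fixation", "probe", "feedback")
  if (any(bad)) {
    stop("unrecognized trial_type value(s): ",
         paste(unique(ev$trial_type[bad]), collapse = ", "), call. = FALSE)
  }
  ev <- ev[order(ev$onset), ]
  cues <- which(ev$component == "cue")
  n_tr <- length(cues)
  get <- function(component, col) {
    x <- ev[ev$component == component, ][[col]]
    if (length(x) != n_tr) {
      stop("events table is not composed of complete cue/fixation/",
           "probe/feedback trials", call. = FALSE)
    }
    x
  }
  fb_type <- get("feedback", "trial_type")
  outcome <- if ("outcome" %in% names(ev)) get("probe", "outcome") else
    ifelse(grepl("_hit$", fb_type), "Hit", "TooSlow")
  rt <- if ("response_time" %in% names(ev)) {
    as.numeric(get("probe", "response_time"))
  } else NA_real_
  trials <- tibble::tibble(
    trial_index = seq_len(n_tr),
    condition = get("cue", "condition"),
    cue_onset = get("cue", "onset"),
    cue_duration = get("cue", "duration"),
    fixation_onset = get("fixation", "onset"),
    fixation_duration = get("fixation", "duration"),
    probe_onset = get("probe", "onset"),
    probe_duration = get("probe", "duration"),
    feedback_onset = get("feedback", "onset"),
    feedback_duration = get("feedback", "duration"),
    outcome = outcome,
    rt = rt
  )
  total <- trials$feedback_onset[n_tr] + trials$feedback_duration[n_tr]
  new_mid_run(trials, run_id = run_id, total_duration = total)
}

#' Summarize behavioral asymmetries across runs
#'
#' Mean and SD of fixation, probe and feedback durations and of response
#' time, split by trial outcome: Hit vs Miss (Too Soon or Too Slow), and
#' Too Soon vs Too Slow. Cells with no trials are kept with `n = 0` and
#' `NA` statistics.
#'
#' @param runs A `mid_run`, a tibble of trials, or a list of them.
#' @return A tibble with columns `measure`, `group`, `n`, `mean`, `sd`.
#' @examples
#' runs <- lapply(1:5, function(s) simulate_mid_run(seed = s))
#' summarize_behavior(runs)
#' @export
summarize_behavior <- function(runs) {
  if (inherits(runs, "data.frame")) runs <- list(runs)
  if (!length(runs)) stop("need at least one run", call. = FALSE)
  trials <- dplyr::bind_rows(lapply(runs, tibble::as_tibble))
  long <- tidyr::pivot_longer(
    dplyr::select(trials, "outcome", "fixation_duration",
                  "probe_duration", "feedback_duration", "rt"),
    cols = -"outcome", names_to = "measure", values_to = "value"
  )
  groups <- list(
    Hit = c("Hit"), Miss = c("TooSoon", "TooSlow"),
    TooSoon = c("TooSoon"), TooSlow = c("TooSlow")
  )
  purrr::map_dfr(names(groups), function(g) {
    sub <- dplyr::filter(long, .data$outcome %in% groups[[g]],
                         !is.na(.data$value))
    out <- dplyr::summarize(
      dplyr::group_by(sub, .data$measure),
      n = dplyr::n(), mean = mean(.data$value), sd = stats::sd(.data$value),
      .groups = "drop"
    )
    full <- tibble::tibble(measure = c("fixation_duration", "probe_duration",
                                       "feedback_duration", "rt"))
    out <- dplyr::left_join(full, out, by = "measure")
    out$n[is.na(out$n)] <- 0L
    dplyr::mutate(out, group = g, .after = "measure")
  })
}
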