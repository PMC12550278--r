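#' @importFrom rlang .data
NULL

# linear interpolation of a regular-grid vector v (grid 0, dt, 2dt, ...)
# at points x; `left` below 0, `right` beyond the grid
interp_grid <- function(v, x, dt, left = 0, right = 0) {
  n <- length(v)
  out <- numeric(length(x))
  idx <- x / dt
  lo <- floor(idx)
  frac <- idx - lo
  inside <- lo >= 0 & lo < (n - 1)
  i <- lo[inside] + 1L
  out[inside] <- v[i] * (1 - frac[inside]) + v[i + 1L] * frac[inside]
  out[lo < 0] <- left
  out[lo >= (n - 1)] <- right
  out
}

#' Convolve event onsets with the hemodynamic response function
#'
#' Builds one HRF-convolved regressor column (optionally with its temporal
#' derivative) sampled at the frame times. Events with zero duration are
#' treated as unit impulses (Dirac delta of area `amplitude`); positive
#' durations are boxcars of the given amplitude. The convolution is
#' evaluated semi-analytically from the cumulative integral of the kernel
#' on the microtime grid, so the boxcar response converges exactly to the
#' impulse response as the duration shrinks at matched area.
#'
#' @param frame_times Strictly increasing scan acquisition times, seconds.
#' @param onsets Event onsets, seconds.
#' @param durations Event durations, seconds (0 means impulse); recycled.
#' @param amplitudes Event amplitudes; recycled.
#' @param hrf An [hrf_spec()].
#' @param add_derivative Also return the temporal-derivative column.
#' @param name Column base name.
#' @return A matrix with `length(frame_times)` rows and 1 or 2 named
#'   columns (`name`, `name_derivative`).
#' @examples
#' ft <- seq(0, 60, by = 0.8)
#' x <- convolve_regressor(ft, onsets = c(5, 35), durations = 2)
#' @export
convolve_regressor <- function(frame_times, onsets, durations = 0,
                               amplitudes = 1, hrf = hrf_spec(),
                               add_derivative = FALSE,
                               name = "regressor") {
  if (!length(onsets)) {
    stop("no events: regressor `", name, "` would be all zero",
         call. = FALSE)
  }
  n_ev <- length(onsets)
  durations <- rep_len(durations, n_ev)
  amplitudes <- rep_len(amplitudes, n_ev)
  spacing <- if (length(frame_times) > 1) diff(frame_times[1:2]) else 0
  if (any(onsets < 0) || any(onsets > max(frame_times) + spacing)) {
    stop("onsets must lie within the scanned run", call. = FALSE)
  }
  if (all(amplitudes == 0)) {
    stop("all event amplitudes are zero for regressor `", name, "`",
         call. = FALSE)
  }
  k <- hrf_kernel(hrf)
  cum_k <- cumsum(k$kernel) * k$dt      # integral of the kernel
  n_fr <- length(frame_times)
  col <- numeric(n_fr)
  dcol <- if (add_derivative) numeric(n_fr) else NULL
  for (e in seq_len(n_ev)) {
    x <- frame_times - onsets[e]
    if (durations[e] > 0) {
      resp <- interp_grid(cum_k, x, k$dt, left = 0, right = 1) -
        interp_grid(cum_k, x - durations[e], k$dt, left = 0, right = 1)
      if (add_derivative) {
        # d/dt of the boxcar response: kernel difference at window edges
        dresp <- interp_grid(k$kernel, x, k$dt) -
          interp_grid(k$kernel, x - durations[e], k$dt)
      }
    } else {
      resp <- interp_grid(k$kernel, x, k$dt)
      if (add_derivative) dresp <- interp_grid(k$derivative, x, k$dt)
    }
    col <- col + amplitudes[e] * resp
    if (add_derivative) dcol <- dcol + amplitudes[e] * dresp
  }
  out <- cbind(col, dcol)
  colnames(out) <- c(name, if (add_derivative) paste0(name, "_derivative"))
  out
}

new_mid_design <- function(values, frame_times, tr, roles,
                           dropped = character(), model = "custom",
                           run_frames = length(frame_times)) {
  stopifnot(ncol(values) == length(roles),
            nrow(values) == length(frame_times))
  structure(
    list(values = values, frame_times = frame_times, tr = tr,
         roles = stats::setNames(roles, colnames(values)),
         dropped = dropped, model = model, run_frames = run_frames),
    class = "mid_design"
  )
}

#' @export
print.mid_design <- function(x, ...) {
  cat(sprintf("<mid_design> %s model: %d frames (tr %g s), %d columns\n",
              x$model, nrow(x$values), x$tr, ncol(x$values)))
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$roles)),
                                table(x$roles)), collapse = ", "), "\n")
  if (length(x$dropped)) {
    cat("  dropped (empty cells):", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

# names of columns with the given role(s)
design_columns <- function(design, roles = c("task", "derivative")) {
  names(design$roles)[design$roles %in% roles]
}

# condition label -> win/loss/neutral valence
condition_valence <- function(condition) {
  dplyr::case_when(
    condition %in% c("LargeWin", "SmallWin") ~ "win",
    condition %in% c("LargeLoss", "SmallLoss") ~ "loss",
    TRUE ~ "neutral"
  )
}

design_frame_times <- function(run, tr) {
  total <- attr(run, "total_duration")
  if (is.null(total)) {
    total <- run$feedback_onset[nrow(run)] + run$feedback_duration[nrow(run)]
  }
  n <- floor(total / tr)
  (seq_len(n) - 1) * tr
}

# assemble regressor definitions (a tibble of name/onsets/durations) into a
# design, dropping empty cells with a warning
assemble_design <- function(defs, frame_times, tr, hrf, add_derivatives,
                            model, drift_cutoff = NULL, intercept = TRUE) {
  cols <- list()
  roles <- character()
  dropped <- character()
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    ons <- d$onsets[[1L]]
    if (!length(ons)) {
      warning("no events for regressor `", d$name, "`; column dropped",
              call. = FALSE)
      dropped <- c(dropped, d$name)
      next
    }
    m <- convolve_regressor(frame_times, ons, d$durations[[1L]],
                            hrf = hrf, add_derivative = add_derivatives,
                            name = d$name)
    cols[[length(cols) + 1L]] <- m
    roles <- c(roles, "task", if (add_derivatives) "derivative")
  }
  X <- do.call(cbind, cols)
  if (!is.null(drift_cutoff)) {
    dr <- cosine_drift(frame_times, cutoff = drift_cutoff)
    X <- cbind(X, dr)
    roles <- c(roles, rep("nuisance", ncol(dr)))
  }
  if (intercept) {
    X <- cbind(X, intercept = 1)
    roles <- c(roles, "intercept")
  }
  new_mid_design(X, frame_times, tr, roles, dropped = dropped,
                 model = model)
}

#' Build the CueFeedback design matrix
#'
#' The model used for the released ABCD MID analyses: impulse regressors at
#' the 5 cue onsets (by cue type) and at the 10 feedback onsets (cue type
#' crossed with hit/miss; a Miss is a Too Soon or Too Slow trial), each
#' paired with its temporal derivative, for 30 task-related columns.
#' Feedback cells with no trials are dropped with a warning and recorded in
#' the design's `dropped` field.
#'
#' @param run A `mid_run` or equivalent trials tibble.
#' @param tr Repetition time, seconds.
#' @param hrf An [hrf_spec()].
#' @param drift_cutoff High-pass cutoff in seconds for a discrete cosine
#'   nuisance set, or `NULL` for none.
#' @param intercept Include an intercept column.
#' @return A `mid_design`.
#' @export
build_cuefeedback_design <- function(run, tr = 0.8, hrf = hrf_spec(),
                                     drift_cutoff = NULL,
                                     intercept = TRUE) {
  trials <- tibble::as_tibble(run)
  tm <- mid_timing()
  ft <- design_frame_times(run, tr)
  defs <- list()
  for (cond in tm$conditions) {
    sel <- trials$condition == cond
    defs[[length(defs) + 1L]] <- tibble::tibble(
      name = paste0("cue_", cond),
      onsets = list(trials$cue_onset[sel]), durations = list(0))
  }
  for (cond in tm$conditions) {
    for (out in c("hit", "miss")) {
      sel <- trials$condition == cond &
        (trials$outcome == "Hit") == (out == "hit")
      defs[[length(defs) + 1L]] <- tibble::tibble(
        name = paste0("feedback_", cond, "_", out),
        onsets = list(trials$feedback_onset[sel]), durations = list(0))
    }
  }
  assemble_design(dplyr::bind_rows(defs), ft, tr, hrf,
                  add_derivatives = TRUE, model = "cuefeedback",
                  drift_cutoff = drift_cutoff, intercept = intercept)
}

#' Build the Saturated design matrix
#'
#' Boxcar regressors for every trial component: 5 cue (by cue type), 5
#' fixation (by cue type), 3 probe (win/loss/neutral), 1 response-time
#' regressor (probe onset, response time as duration; trials without a
#' recorded response time contribute nothing), and 10 feedback (cue type by
#' hit/miss) — 24 task columns, no derivatives by default.
#'
#' @inheritParams build_cuefeedback_design
#' @param add_derivatives Pair every task regressor with its temporal
#'   derivative (not part of the standard Saturated model; available for
#'   collinearity exploration).
#' @return A `mid_design`.
#' @export
build_saturated_design <- function(run, tr = 0.8, hrf = hrf_spec(),
                                   add_derivatives = FALSE,
                                   drift_cutoff = NULL, intercept = TRUE) {
  trials <- tibble::as_tibble(run)
  tm <- mid_timing()
  ft <- design_frame_times(run, tr)
  defs <- list()
  add <- function(name, sel, onset_col, dur) {
    defs[[length(defs) + 1L]] <<- tibble::tibble(
      name = name, onsets = list(trials[[onset_col]][sel]),
      durations = list(dur))
  }
  for (cond in tm$conditions) {
    sel <- trials$condition == cond
    add(paste0("cue_", cond), sel, "cue_onset",
        trials$cue_duration[sel])
  }
  for (cond in tm$conditions) {
    sel <- trials$condition == cond
    add(paste0("fixation_", cond), sel, "fixation_onset",
        trials$fixation_duration[sel])
  }
  valence <- condition_valence(trials$condition)
  for (v in c("win", "loss", "neutral")) {
    sel <- valence == v
    add(paste0("probe_", v), sel, "probe_onset",
        trials$probe_duration[sel])
  }
  sel <- !is.na(trials$rt)
  add("rt", sel, "probe_onset", trials$rt[sel])
  for (cond in tm$conditions) {
    for (out in c("hit", "miss")) {
      sel <- trials$condition == cond &
        (trials$outcome == "Hit") == (out == "hit")
      add(paste0("feedback_", cond, "_", out), sel, "feedback_onset",
          trials$feedback_duration[sel])
    }
  }
  assemble_design(dplyr::bind_rows(defs), ft, tr, hrf,
                  add_derivatives = add_derivatives, model = "saturated",
                  drift_cutoff = drift_cutoff, intercept = intercept)
}

#' Build a design matrix for a MID run
#'
#' Front end dispatching to [build_saturated_design()] or
#' [build_cuefeedback_design()].
#'
#' @inheritParams build_cuefeedback_design
#' @param model `"saturated"` or `"cuefeedback"`.
#' @param ... Passed to the specific builder.
#' @return A `mid_design`.
#' @examples
#' run <- simulate_mid_run(seed = 1)
#' d <- build_design(run, model = "saturated")
#' @export
build_design <- function(run, model = c("saturated", "cuefeedback"),
                         tr = 0.8, hrf = hrf_spec(), ...) {
  model <- match.arg(model)
  switch(model,
         saturated = build_saturated_design(run, tr = tr, hrf = hrf, ...),
         cuefeedback = build_cuefeedback_design(run, tr = tr, hrf = hrf,
                                                ...))
}

#' Discrete cosine high-pass drift basis
#'
#' DCT-II basis restricted to periods at or above the cutoff (order
#' `floor(2 T / cutoff)`, at least 1), mutually orthogonal on the frame
#' grid; tagged as nuisance when used inside a design.
#'
#' @param frame_times Strictly increasing frame times, seconds.
#' @param cutoff High-pass cutoff period, seconds.
#' @return A matrix with columns `drift_1`, ..., `drift_K`.
#' @examples
#' ncol(cosine_drift(seq(0, 319.2, by = 0.8), 128))  # 5
#' @export
cosine_drift <- function(frame_times, cutoff = 128) {
  n <- length(frame_times)
  if (n < 2) stop("need at least two frames", call. = FALSE)
  tr <- frame_times[2] - frame_times[1]
  if (cutoff <= 2 * tr) {
    stop("cutoff must exceed twice the frame spacing", call. = FALSE)
  }
  total <- n * tr
  order <- max(1L, floor(2 * total / cutoff))
  i <- seq_len(n) - 1
  basis <- vapply(seq_len(order), function(k) {
    sqrt(2 / n) * cos(pi * k * (2 * i + 1) / (2 * n))
  }, numeric(n))
  colnames(basis) <- paste0("drift_", seq_len(order))
  basis
}

#' Concatenate runs into a single design
#'
#' Task (and derivative) columns are block-stacked over the union of
#' column names, zero-filled where a run lacks a column; intercept and
#' nuisance columns are kept run-specific (prefixed `run<i>_`) so drift and
#' baseline remain orthogonal across runs.
#'
#' @param designs A list of `mid_design` objects with identical `tr`.
#' @return A `mid_design` spanning all runs.
#' @export
concatenate_runs <- function(designs) {
  stopifnot(length(designs) >= 1)
  trs <- vapply(designs, function(d) d$tr, numeric(1))
  if (length(unique(trs)) != 1L) {
    stop("all runs must share the same tr", call. = FALSE)
  }
  task_roles <- c("task", "derivative")
  task_names <- unique(unlist(lapply(designs, design_columns)))
  blocks <- list()
  other_roles <- character()
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    nf <- nrow(d$values)
    task <- matrix(0, nf, length(task_names),
                   dimnames = list(NULL, task_names))
    have <- intersect(task_names, design_columns(d))
    task[, have] <- d$values[, have, drop = FALSE]
    oth_names <- names(d$roles)[!d$roles %in% task_roles]
    oth <- d$values[, oth_names, drop = FALSE]
    if (length(oth_names)) colnames(oth) <- paste0("run", i, "_", oth_names)
    blocks[[i]] <- list(task = task, other = oth,
                        other_roles = stats::setNames(
                          d$roles[oth_names], colnames(oth)))
  }
  n_total <- sum(vapply(blocks, function(b) nrow(b$task), numeric(1)))
  task_all <- do.call(rbind, lapply(blocks, `[[`, "task"))
  other_all <- matrix(0, n_total,
                      sum(vapply(blocks, function(b) ncol(b$other),
                                 numeric(1))))
  other_names <- unlist(lapply(blocks, function(b) colnames(b$other)))
  colnames(other_all) <- other_names
  row0 <- 0L
  for (b in blocks) {
    nf <- nrow(b$task)
    if (ncol(b$other)) {
      other_all[row0 + seq_len(nf), colnames(b$other)] <- b$other
    }
    row0 <- row0 + nf
  }
  roles <- c(stats::setNames(
    ifelse(grepl("_derivative$", task_names), "derivative", "task"),
    task_names),
    unlist(lapply(blocks, `[[`, "other_roles")))
  tr <- trs[1]
  ft <- (seq_len(n_total) - 1) * tr
  new_mid_design(cbind(task_all, other_all), ft, tr,
                 roles[colnames(cbind(task_all, other_all))],
                 dropped = unique(unlist(lapply(designs, `[[`, "dropped"))),
                 model = designs[[1]]$model,
                 run_frames = vapply(blocks, function(b) nrow(b$task),
                                     numeric(1)))
}

#' Standard MID contrasts
#'
#' Emits the standard set of MID contrasts applicable to a design: large
#' win/loss cue versus neutral, cue versus implicit baseline, win and loss
#' feedback hit-versus-miss (half weights over large/small), large-win-hit
#' versus neutral-hit, and large-win-hit versus baseline. Contrasts whose
#' columns are absent from the design are skipped with a warning.
#'
#' @param design A `mid_design`.
#' @return A tibble with columns `name`, `starred` (contrast of primary
#'   interest) and `weights` (list column of named sparse weight vectors).
#' @examples
#' run <- simulate_mid_run(seed = 1)
#' make_contrasts(build_design(run, "cuefeedback"))
#' @export
make_contrasts <- function(design) {
  defs <- list(
    list(name = "Cue:LW-Neut", starred = TRUE,
         w = c(cue_LargeWin = 1, cue_Neutral = -1)),
    list(name = "Cue:LL-Neut", starred = TRUE,
         w = c(cue_LargeLoss = 1, cue_Neutral = -1)),
    list(name = "Cue:LW-Base", starred = FALSE,
         w = c(cue_LargeWin = 1)),
    list(name = "FB:WHit-WMiss", starred = TRUE,
         w = c(feedback_LargeWin_hit = 0.5, feedback_SmallWin_hit = 0.5,
               feedback_LargeWin_miss = -0.5,
               feedback_SmallWin_miss = -0.5)),
    list(name = "FB:LHit-LMiss", starred = TRUE,
         w = c(feedback_LargeLoss_hit = 0.5, feedback_SmallLoss_hit = 0.5,
               feedback_LargeLoss_miss = -0.5,
               feedback_SmallLoss_miss = -0.5)),
    list(name = "FB:LWHit-NeutHit", starred = FALSE,
         w = c(feedback_LargeWin_hit = 1, feedback_Neutral_hit = -1)),
    list(name = "FB:LWHit-Base", starred = FALSE,
         w = c(feedback_LargeWin_hit = 1))
  )
  cols <- colnames(design$values)
  keep <- purrr::map_lgl(defs, function(d) {
    ok <- all(names(d$w) %in% cols)
    if (!ok) {
      warning("contrast `", d$name, "` skipped: missing column(s) ",
              paste(setdiff(names(d$w), cols), collapse = ", "),
              call. = FALSE)
    }
    ok
  })
  defs <- defs[keep]
  tibble::tibble(
    name = purrr::map_chr(defs, "name"),
    starred = purrr::map_lgl(defs, "starred"),
    weights = purrr::map(defs, "w")
  )
}

# expand a sparse named weight vector to the full column space of a design;
# allow_missing drops weights on absent columns (used when a rare subject
# lacks an empty-cell column) instead of erroring
contrast_vector <- function(design, weights, allow_missing = FALSE) {
  cols <- colnames(design$values)
  if (!all(names(weights) %in% cols)) {
    if (!allow_missing) {
      stop("contrast references missing column(s): ",
           paste(setdiff(names(weights), cols), collapse = ", "),
           call. = FALSE)
    }
    weights <- weights[names(weights) %in% cols]
  }
  v <- stats::setNames(numeric(length(cols)), cols)
  v[names(weights)] <- weights
  v
}

#' Build a design object from a plain matrix
#'
#' Wraps an arbitrary numeric matrix (e.g., custom regressors) as a
#' `mid_design` so the collinearity and fitting tools apply to it.
#'
#' @param values Numeric matrix, one row per frame; column names become
#'   regressor names (defaulting to `x1`, `x2`, ...).
#' @param tr Frame spacing, seconds.
#' @param roles Per-column roles (`task`, `derivative`, `nuisance`,
#'   `intercept`); defaults to all `task`.
#' @param frame_times Frame times; defaults to `0, tr, 2 tr, ...`.
#' @return A `mid_design`.
#' @examples
#' d <- as_mid_design(cbind(a = rnorm(20), b = rnorm(20)))
#' tvif(d, "a")
#' @export
as_mid_design <- function(values, tr = 1,
                          roles = rep("task", ncol(values)),
                          frame_times = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("x", seq_len(ncol(values)))
  }
  frame_times <- frame_times %||% ((seq_len(nrow(values)) - 1) * tr)
  new_mid_design(values, frame_times, tr, roles)
}
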