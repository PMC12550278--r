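#' Table of simulation settings for the MID bias study
#'
#' True parameter means (in the Saturated-model column basis) for each
#' simulation setting: a null setting, single-component settings (cue,
#' fixation, probe, response time, feedback signal on Win trials), and two
#' compound settings in which all non-cue or all non-feedback parameters
#' are nonzero. Effect sizes are calibrated so that single-parameter group
#' power is approximately 80% at 500 subjects.
#'
#' @return A named list of named numeric vectors (zero-mean parameters are
#'   simply absent).
#' @export
mid_simulation_settings <- function() {
  cue <- c(cue_LargeWin = 0.22, cue_SmallWin = 0.22)
  fixation <- c(fixation_LargeWin = 0.22, fixation_SmallWin = 0.22)
  probe <- c(probe_win = 0.85)
  rt <- c(rt = 0.35)
  feedback <- c(feedback_LargeWin_hit = 0.25, feedback_LargeWin_miss = 0.25)
  list(
    null = stats::setNames(numeric(0), character(0)),
    cue_win = cue,
    fixation_win = fixation,
    probe_win = probe,
    response_time = rt,
    feedback = feedback,
    all_but_cue = c(fixation, probe, rt, feedback),
    all_but_feedback = c(cue, fixation, probe, rt)
  )
}

#' Define a simulation scenario
#'
#' @param name Scenario name; when `true_means` is missing, one of the
#'   preset names from [mid_simulation_settings()].
#' @param true_means Named numeric vector of true parameter means over
#'   Saturated-model task columns (absent means zero).
#' @param sigma_within Within-subject noise SD (signal units).
#' @param sigma_between Between-subject SD applied to nonzero-mean
#'   parameters (signal units).
#' @param n_subjects Subjects per simulated dataset.
#' @param n_reps Number of simulated datasets.
#' @param alpha Two-sided significance level of the group t-test.
#' @param seed Integer seed for the scenario.
#' @param vary_null_params Also give zero-mean parameters between-subject
#'   variability (default: only nonzero-mean parameters vary).
#' @return An object of class `simulation_scenario`.
#' @examples
#' simulation_scenario("cue_win", n_subjects = 50, n_reps = 100, seed = 1)
#' @export
simulation_scenario <- function(name, true_means = NULL,
                                sigma_within = 1, sigma_between = 1.5,
                                n_subjects = 100, n_reps = 200,
                                alpha = 0.05, seed = 1L,
                                vary_null_params = FALSE) {
  if (is.null(true_means)) {
    presets <- mid_simulation_settings()
    if (!name %in% names(presets)) {
      stop("unknown preset `", name, "`; supply true_means or one of: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    true_means <- presets[[name]]
  }
  if (sigma_within <= 0) stop("sigma_within must be positive",
                              call. = FALSE)
  if (sigma_between < 0) stop("sigma_between must be nonnegative",
                              call. = FALSE)
  if (n_subjects < 2) stop("need at least two subjects", call. = FALSE)
  structure(
    list(name = name, true_means = true_means,
         sigma_within = sigma_within, sigma_between = sigma_between,
         n_subjects = n_subjects, n_reps = n_reps, alpha = alpha,
         seed = as.integer(seed), vary_null_params = vary_null_params),
    class = "simulation_scenario"
  )
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf("<simulation_scenario> %s: %d subjects x %d reps\n",
              x$name, x$n_subjects, x$n_reps))
  cat(sprintf("  sigma_within %g, sigma_between %g, alpha %g, seed %d\n",
              x$sigma_within, x$sigma_between, x$alpha, x$seed))
  if (length(x$true_means)) {
    cat("  nonzero means:",
        paste(names(x$true_means), "=", x$true_means, collapse = ", "),
        "\n")
  } else cat("  all true means zero\n")
  invisible(x)
}

#' Draw one subject's true parameter vector
#'
#' Parameters with nonzero mean receive Gaussian between-subject
#' variability (`Normal(mean, sigma_between^2)`); zero-mean parameters stay
#' exactly zero unless `vary_null_params` is set in the scenario.
#'
#' @param scenario A [simulation_scenario()].
#' @param columns Saturated task column names defining the parameter
#'   space.
#' @return Named numeric vector of true parameter values.
#' @export
draw_subject_truth <- function(scenario, columns) {
  beta <- stats::setNames(numeric(length(columns)), columns)
  mu <- scenario$true_means
  unknown <- setdiff(names(mu), columns)
  if (length(unknown)) {
    stop("scenario means name unknown column(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  vary <- if (scenario$vary_null_params) columns else names(mu)
  beta[names(mu)] <- mu
  beta[vary] <- beta[vary] +
    stats::rnorm(length(vary), 0, scenario$sigma_between)
  beta
}

#' Simulate a single-voxel BOLD time series
#'
#' `Y = X beta + epsilon` with independent Gaussian noise: the task columns
#' of the (Saturated) design are multiplied by the true parameter vector
#' and white noise of SD `sigma_within` is added at each frame.
#'
#' @param design A `mid_design` (generating model).
#' @param true_beta Named numeric vector over (a subset of) the design's
#'   task columns.
#' @param sigma_within Noise SD.
#' @param seed Optional seed fixing the noise.
#' @return Numeric vector of length `nrow(design$values)`.
#' @export
simulate_timeseries <- function(design, true_beta, sigma_within = 1,
                                seed = NULL) {
  cols <- design_columns(design)
  unknown <- setdiff(names(true_beta), cols)
  if (length(unknown)) {
    stop("true_beta names do not match task columns: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  gen <- function() {
    signal <- if (length(true_beta)) {
      drop(design$values[, names(true_beta), drop = FALSE] %*% true_beta)
    } else 0
    signal + stats::rnorm(nrow(design$values), 0, sigma_within)
  }
  if (is.null(seed)) gen() else with_preserved_seed(seed, gen())
}

#' Ordinary least squares fit of a design to a time series
#'
#' @param design A `mid_design` (fitting model; full column rank).
#' @param y Numeric response vector (one value per frame).
#' @param contrasts Optional contrast tibble ([make_contrasts()]) or named
#'   list of weight vectors for which estimates and variances are
#'   returned.
#' @return A list of class `mid_ols_fit` with `coefficients`, `sigma2`
#'   (residual mean square), `df_residual`, and `contrasts` (tibble with
#'   `name`, `estimate`, `variance`).
#' @examples
#' run <- simulate_mid_run(seed = 1)
#' d <- build_design(run, "saturated", drift_cutoff = 128)
#' y <- simulate_timeseries(d, c(cue_LargeWin = 1), seed = 2)
#' fit <- fit_ols(d, y, make_contrasts(d))
#' @export
fit_ols <- function(design, y, contrasts = NULL) {
  X <- design$values
  if (length(y) != nrow(X)) {
    stop("length(y) must equal the number of frames", call. = FALSE)
  }
  Ginv <- gram_inverse(X)
  beta <- drop(Ginv %*% crossprod(X, y))
  names(beta) <- colnames(X)
  resid <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  ctab <- NULL
  if (!is.null(contrasts)) {
    wlist <- if (is.data.frame(contrasts)) {
      stats::setNames(contrasts$weights, contrasts$name)
    } else contrasts
    ctab <- purrr::imap_dfr(wlist, function(w, nm) {
      cv <- contrast_vector(design, w)
      tibble::tibble(name = nm,
                     estimate = drop(cv %*% beta),
                     variance = drop(cv %*% Ginv %*% cv) * sigma2)
    })
  }
  structure(list(coefficients = beta, sigma2 = sigma2, df_residual = df,
                 residuals = resid, contrasts = ctab),
            class = "mid_ols_fit")
}

#' Mixed-effects variance of a first-level contrast
#'
#' Total mixed-effects variance of a contrast estimate:
#' `sigma_mfx^2 = c (X'X)^-1 c' sigma_w^2 + c c' sigma_b^2`, and the ratio
#' of total to within-subject SD,
#' `sqrt(sigma_mfx^2 / (c (X'X)^-1 c' sigma_w^2))`.
#'
#' @param design A `mid_design`.
#' @param weights Named contrast weights.
#' @param sigma_within Within-subject noise SD.
#' @param sigma_between Between-subject SD.
#' @return A list with `sigma2_mfx`, `sd_ratio`, `within` (the
#'   within-subject variance component) and `between`.
#' @examples
#' run <- simulate_mid_run(seed = 1)
#' d <- build_design(run, "saturated", drift_cutoff = 128)
#' mixed_variance(d, c(cue_LargeWin = 1, cue_Neutral = -1))
#' @export
mixed_variance <- function(design, weights, sigma_within = 1,
                           sigma_between = 1.5) {
  cvec <- contrast_vector(design, weights)
  Ginv <- gram_inverse(design$values)
  within <- drop(cvec %*% Ginv %*% cvec) * sigma_within^2
  between <- sum(cvec^2) * sigma_between^2
  sigma2 <- within + between
  list(sigma2_mfx = sigma2, sd_ratio = sqrt(sigma2 / within),
       within = within, between = between)
}

# simulate one subject's two chained runs and return their designs
simulate_subject <- function(seed_pair, params = mid_behavior_params(),
                             tr = 0.8, hrf = hrf_spec(),
                             drift_cutoff = 128,
                             models = c("saturated", "cuefeedback")) {
  run1 <- simulate_mid_run(params, run_id = 1L, seed = seed_pair[1])
  run2 <- simulate_mid_run(params, run_id = 2L, seed = seed_pair[2],
                           probe_init = attr(run1, "staircase_probe"),
                           prev_outcomes = attr(run1, "staircase_outcomes"))
  out <- list()
  build <- function(model) {
    concatenate_runs(lapply(list(run1, run2), function(r) {
      suppressWarnings(
        build_design(r, model = model, tr = tr, hrf = hrf,
                     drift_cutoff = drift_cutoff)
      )
    }))
  }
  for (m in models) out[[m]] <- build(m)
  out$runs <- list(run1, run2)
  out
}

#' Simulate per-subject MID designs
#'
#' Generates `n_subjects` synthetic subjects: two 50-trial runs each with
#' the staircase carried across runs, concatenated into one design per
#' fitted model (per-run intercepts and 128 s cosine drift).
#'
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @param models Which designs to build per subject.
#' @param params,tr,hrf,drift_cutoff Passed to the simulator/builders.
#' @return A list of per-subject lists with elements named after `models`
#'   plus `runs`.
#' @export
simulate_subject_designs <- function(n_subjects, seed = 1L,
                                     models = c("saturated",
                                                "cuefeedback"),
                                     params = mid_behavior_params(),
                                     tr = 0.8, hrf = hrf_spec(),
                                     drift_cutoff = 128) {
  seeds <- with_preserved_seed(seed,
    matrix(sample.int(.Machine$integer.max - 1L, 2L * n_subjects),
           ncol = 2L))
  lapply(seq_len(n_subjects), function(i) {
    simulate_subject(seeds[i, ], params = params, tr = tr, hrf = hrf,
                     drift_cutoff = drift_cutoff, models = models)
  })
}

#' Run a bias/type-I-error/power simulation scenario
#'
#' For each replicate dataset, per-subject time series are generated from
#' the Saturated design (`Y = X beta_i + noise`, with subject-level
#' parameters drawn around the scenario means), fitted by ordinary least
#' squares under each requested model, and the per-subject contrast
#' estimates are carried to a two-sided one-sample group t-test. The same
#' noise realization is fitted by every model.
#'
#' Per-subject designs are fixed across replicates, so the OLS contrast
#' estimator rows `c'(X'X)^-1 X'` are precomputed once per subject and
#' each replicate reduces to matrix-vector products (algebraically
#' identical to [fit_ols()]).
#'
#' @param scenario A [simulation_scenario()].
#' @param fit_models Models to fit (`"saturated"`, `"cuefeedback"`).
#' @param contrasts Contrast tibble over design columns; defaults to the
#'   standard MID contrasts.
#' @param designs Optional precomputed [simulate_subject_designs()]
#'   output (must cover `fit_models` and `"saturated"`).
#' @param params Behavioral parameters for the synthetic subjects.
#' @return A tibble of class `scenario_result`: one row per model and
#'   contrast with `true_value`, `is_null`, `mean_estimate`, `bias`
#'   (null contrasts only), `mc_se`, `rejection_rate` (type-I error for
#'   null contrasts, power otherwise), and the one-sided exact binomial
#'   inflation test (`inflation_p`, `inflated`) for null contrasts.
#' @examples
#' \donttest{
#' sc <- simulation_scenario("null", n_subjects = 20, n_reps = 50, seed = 1)
#' res <- run_scenario(sc, fit_models = "saturated")
#' }
#' @export
run_scenario <- function(scenario, fit_models = c("saturated",
                                                  "cuefeedback"),
                         contrasts = NULL, designs = NULL,
                         params = mid_behavior_params()) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (scenario$n_reps < 2) stop("need at least two replicates",
                                call. = FALSE)
  fit_models <- match.arg(fit_models, several.ok = TRUE)
  need <- union(fit_models, "saturated")
  if (is.null(designs)) {
    designs <- simulate_subject_designs(scenario$n_subjects,
                                        seed = scenario$seed,
                                        models = need, params = params)
  }
  n_sub <- scenario$n_subjects
  if (length(designs) < n_sub) {
    stop("designs list is shorter than n_subjects", call. = FALSE)
  }
  designs <- designs[seq_len(n_sub)]
  if (is.null(contrasts)) contrasts <- make_contrasts(designs[[1]]$saturated)
  n_con <- nrow(contrasts)
  sat_cols <- design_columns(designs[[1]]$saturated, "task")

  # per subject: saturated task matrix (generator) and, per fitted model,
  # the contrast estimator rows CA and their product with the generator
  pre <- lapply(designs, function(d) {
    Xs <- d$saturated$values[, intersect(sat_cols,
                                         colnames(d$saturated$values)),
                             drop = FALSE]
    per_model <- lapply(fit_models, function(m) {
      dm <- d[[m]]
      Ginv <- gram_inverse(dm$values)
      C <- t(vapply(contrasts$weights,
                    function(w) contrast_vector(dm, w,
                                                allow_missing = TRUE),
                    numeric(ncol(dm$values))))
      CA <- C %*% Ginv %*% t(dm$values)     # n_con x n_frames
      list(CA = CA, M = CA %*% Xs)          # M: n_con x n_sat_cols
    })
    names(per_model) <- fit_models
    list(per_model = per_model, sat_names = colnames(Xs),
         n_frames = nrow(Xs))
  })

  true_con <- vapply(contrasts$weights, function(w) {
    sum(w * scenario$true_means[names(w)], na.rm = TRUE)
  }, numeric(1))

  res <- with_preserved_seed(scenario$seed + 1L, {
    est_mean <- array(0, c(scenario$n_reps, length(fit_models), n_con))
    reject <- array(FALSE, c(scenario$n_reps, length(fit_models), n_con))
    for (r in seq_len(scenario$n_reps)) {
      est <- array(0, c(n_sub, length(fit_models), n_con))
      for (s in seq_len(n_sub)) {
        p <- pre[[s]]
        beta <- draw_subject_truth(scenario, p$sat_names)
        eps <- stats::rnorm(p$n_frames, 0, scenario$sigma_within)
        for (mi in seq_along(fit_models)) {
          pm <- p$per_model[[mi]]
          est[s, mi, ] <- drop(pm$M %*% beta) + drop(pm$CA %*% eps)
        }
      }
      for (mi in seq_along(fit_models)) {
        for (ci in seq_len(n_con)) {
          x <- est[, mi, ci]
          tt <- mean(x) / (stats::sd(x) / sqrt(n_sub))
          pval <- 2 * stats::pt(-abs(tt), df = n_sub - 1)
          est_mean[r, mi, ci] <- mean(x)
          reject[r, mi, ci] <- pval < scenario$alpha
        }
      }
    }
    list(est_mean = est_mean, reject = reject)
  })

  out <- tidyr::expand_grid(model = fit_models, contrast = contrasts$name)
  rows <- purrr::pmap_dfr(out, function(model, contrast) {
    mi <- match(model, fit_models)
    ci <- match(contrast, contrasts$name)
    em <- res$est_mean[, mi, ci]
    rj <- res$reject[, mi, ci]
    is_null <- true_con[ci] == 0
    n_rej <- sum(rj)
    infl_p <- if (is_null) {
      stats::binom.test(n_rej, scenario$n_reps, p = scenario$alpha,
                        alternative = "greater")$p.value
    } else NA_real_
    scenario_name <- scenario$name  # `scenario` is masked inside tibble()
    tibble::tibble(
      scenario = scenario_name, model = model, contrast = contrast,
      true_value = true_con[ci], is_null = is_null,
      mean_estimate = mean(em),
      bias = if (is_null) mean(em) - true_con[ci] else NA_real_,
      mc_se = stats::sd(em) / sqrt(length(em)),
      rejection_rate = mean(rj),
      inflation_p = infl_p,
      inflated = if (is_null) infl_p < 0.05 else NA
    )
  })
  class(rows) <- c("scenario_result", class(rows))
  attr(rows, "scenario") <- scenario
  rows
}
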