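#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a design matrix into a long tibble
#'
#' @param x A `mid_design`.
#' @param ... Unused.
#' @return A tibble with `frame_time`, `column`, `role`, `value`.
#' @exportS3Method generics::tidy
tidy.mid_design <- function(x, ...) {
  vals <- tibble::as_tibble(as.data.frame(x$values))
  vals$frame_time <- x$frame_times
  out <- tidyr::pivot_longer(vals, cols = -"frame_time",
                             names_to = "column", values_to = "value")
  out$role <- unname(x$roles[out$column])
  out[, c("frame_time", "column", "role", "value")]
}

#' @exportS3Method generics::glance
glance.mid_design <- function(x, ...) {
  tibble::tibble(model = x$model, n_frames = nrow(x$values),
                 tr = x$tr,
                 n_task = sum(x$roles == "task"),
                 n_derivative = sum(x$roles == "derivative"),
                 n_nuisance = sum(x$roles == "nuisance"),
                 n_intercept = sum(x$roles == "intercept"),
                 n_dropped = length(x$dropped))
}

#' Tidy an OLS fit
#'
#' @param x A `mid_ols_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` (contrast rows carry
#'   `std.error` too when contrasts were requested).
#' @exportS3Method generics::tidy
tidy.mid_ols_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$coefficients),
                        estimate = unname(x$coefficients),
                        type = "coefficient", std.error = NA_real_)
  if (!is.null(x$contrasts)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = x$contrasts$name, estimate = x$contrasts$estimate,
      type = "contrast", std.error = sqrt(x$contrasts$variance)))
  }
  out
}

#' @exportS3Method generics::glance
glance.mid_ols_fit <- function(x, ...) {
  tibble::tibble(sigma2 = x$sigma2, df_residual = x$df_residual,
                 n_terms = length(x$coefficients))
}

#' @exportS3Method generics::glance
glance.group_perm_result <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 n_permutations = x$n_permutations,
                 cf_threshold = x$cf_threshold, alpha = x$alpha,
                 cluster_size_threshold = x$cluster_size_threshold,
                 n_clusters = nrow(x$clusters),
                 n_significant = sum(x$clusters$significant))
}

#' @exportS3Method generics::tidy
tidy.group_perm_result <- function(x, ...) {
  dplyr::select(x$clusters, -"voxels")
}

#' Plot the task regressors of a design matrix
#'
#' @param object A `mid_design`.
#' @param roles Column roles to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mid_design <- function(object, roles = c("task", "derivative"),
                                ...) {
  df <- dplyr::filter(tidy(object), .data$role %in% roles)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame_time,
                                   y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~column, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "regressor value") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot a collinearity report
#'
#' Bar chart of cVIF per contrast and tVIF per column, with the flag
#' threshold marked.
#'
#' @param object A `collinearity_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.collinearity_report <- function(object, ...) {
  thr <- attr(object, "flag_threshold") %||% 5
  df <- dplyr::mutate(object,
                      value = dplyr::coalesce(.data$cvif, .data$tvif),
                      metric = ifelse(.data$type == "contrast", "cVIF",
                                      "tVIF"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$term,
                                                      .data$value),
                                   y = .data$value,
                                   fill = .data$flagged)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = "variance inflation") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Plot scenario bias and rejection rates
#'
#' Mean contrast estimate with Monte-Carlo standard error bars, by fitted
#' model, against the true contrast value.
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.scenario_result <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$contrast,
                               y = .data$mean_estimate,
                               color = .data$model)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_estimate - 2 * .data$mc_se,
                   ymax = .data$mean_estimate + 2 * .data$mc_se),
      width = 0.2, position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$true_value),
                        shape = 4, color = "black") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean contrast estimate",
                  title = unique(object$scenario)) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Save and load collinearity reports and designs
#'
#' `write_design()` writes the numeric design as CSV (frame times plus
#' named columns) with a JSON sidecar holding roles, tr and dropped
#' columns; `read_design()` reconstructs the `mid_design`.
#'
#' @param design A `mid_design`.
#' @param path CSV path; the sidecar uses the same path with `.json`.
#' @return `read_design()` returns a `mid_design`; `write_design()` its
#'   input, invisibly.
#' @export
write_design <- function(design, path) {
  df <- tibble::as_tibble(as.data.frame(design$values))
  df <- dplyr::bind_cols(tibble::tibble(frame_time = design$frame_times),
                         df)
  readr::write_csv(df, path)
  side <- list(tr = design$tr, roles = as.list(design$roles),
               dropped = design$dropped, model = design$model,
               run_frames = design$run_frames)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(design)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ft <- df$frame_time
  X <- as.matrix(df[, setdiff(names(df), "frame_time")])
  new_mid_design(X, ft, side$tr, unlist(side$roles)[colnames(X)],
                 dropped = side$dropped %||% character(),
                 model = side$model %||% "custom",
                 run_frames = side$run_frames %||% nrow(X))
}
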