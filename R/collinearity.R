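#' @keywords internal
# inverse Gram matrix with a rank check naming dependent columns
gram_inverse <- function(X, tol = 1e-10) {
  qrx <- qr(X, tol = tol)
  p <- ncol(X)
  if (qrx$rank < p) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop("design is rank deficient; linearly dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  sv <- svd(X, nu = 0, nv = 0)$d
  if (sv[length(sv)] / sv[1] < tol) {
    stop("design is numerically singular (condition check failed)",
         call. = FALSE)
  }
  chol2inv(chol(crossprod(X)))
}

#' Contrast estimation efficiency
#'
#' Efficiency of a contrast `c` under a design `X`:
#' `1 / (c (X'X)^-1 c')`. The variance of the contrast estimate equals the
#' residual variance divided by the efficiency, so doubling efficiency
#' halves the contrast variance. The computation uses the full design
#' (nuisance and intercept columns carry zero weights).
#'
#' @param design A `mid_design`.
#' @param weights Named numeric contrast weights over design columns
#'   (columns not named get weight 0).
#' @return Efficiency, a positive scalar.
#' @examples
#' run <- simulate_mid_run(seed = 1)
#' d <- build_design(run, "saturated")
#' efficiency(d, c(cue_LargeWin = 1, cue_Neutral = -1))
#' @export
efficiency <- function(design, weights) {
  cvec <- contrast_vector(design, weights)
  if (all(cvec == 0)) stop("contrast is all zero", call. = FALSE)
  Ginv <- gram_inverse(design$values)
  drop(1 / (cvec %*% Ginv %*% cvec))
}

#' Traditional variance inflation factor of a design column
#'
#' Ratio of the parameter variance in the full model to that in a reduced
#' model containing only the column and an intercept:
#' `[(X'X)^-1]_jj * (x~_j' x~_j)` with `x~_j` the mean-centered column.
#' Equals 1 when the column is orthogonal to all other (centered)
#' columns.
#'
#' @param design A `mid_design`.
#' @param column Name of a task or derivative column.
#' @return The tVIF, at least 1 for full-rank designs.
#' @export
tvif <- function(design, column) {
  roles <- design$roles
  if (!column %in% names(roles)) {
    stop("no column named `", column, "`", call. = FALSE)
  }
  if (roles[[column]] %in% c("nuisance", "intercept")) {
    stop("`", column, "` is a ", roles[[column]],
         " column; tVIF applies to task columns", call. = FALSE)
  }
  Ginv <- gram_inverse(design$values)
  j <- match(column, colnames(design$values))
  xj <- design$values[, j]
  xc <- xj - mean(xj)
  drop(Ginv[j, j] * sum(xc^2))
}

#' Reparameterize a design into a condition basis
#'
#' Two parameterizations of the same column space are statistically
#' equivalent: if the model's task columns satisfy `X_model = X_cond %*%
#' transform`, then the condition-basis design is `X_cond = X_model %*%
#' solve(transform)` and the contrast expressing the same estimand is
#' `c_cond = c_model %*% solve(transform)`. The contrast variance
#' `c (X'X)^-1 c'` is preserved exactly, which is what makes a
#' condition-basis VIF parameterization-invariant.
#'
#' @param design A `mid_design` whose task/derivative columns are the
#'   model basis.
#' @param transform Invertible square matrix with `X_model = X_cond %*%
#'   transform` over the task columns.
#' @param weights Named contrast weights in the model basis.
#' @param condition_names Optional names for the condition-basis columns.
#' @return A list with `design` (condition-basis `mid_design`) and
#'   `weights` (full-length named contrast vector in the condition basis).
#' @export
map_to_condition_basis <- function(design, transform, weights,
                                   condition_names = NULL) {
  task_cols <- design_columns(design)
  k <- length(task_cols)
  if (!is.matrix(transform) || nrow(transform) != ncol(transform)) {
    stop("transform must be a square matrix", call. = FALSE)
  }
  if (nrow(transform) != k) {
    stop("transform must be ", k, " x ", k, " to match the task columns",
         call. = FALSE)
  }
  rc <- rcond(transform)
  if (!is.finite(rc) || rc < 1e-12) {
    stop("transform is singular", call. = FALSE)
  }
  Tinv <- solve(transform)
  cvec <- contrast_vector(design, weights)
  Xm <- design$values[, task_cols, drop = FALSE]
  Xc <- Xm %*% Tinv
  cond_names <- condition_names %||% paste0("condition_", seq_len(k))
  colnames(Xc) <- cond_names
  c_cond <- drop(cvec[task_cols] %*% Tinv)
  names(c_cond) <- cond_names
  other <- setdiff(colnames(design$values), task_cols)
  vals <- cbind(Xc, design$values[, other, drop = FALSE])
  roles <- c(stats::setNames(rep("task", k), cond_names),
             design$roles[other])
  out <- new_mid_design(vals, design$frame_times, design$tr,
                        roles[colnames(vals)], dropped = design$dropped,
                        model = design$model,
                        run_frames = design$run_frames)
  full_w <- stats::setNames(numeric(ncol(vals)), colnames(vals))
  full_w[cond_names] <- c_cond
  full_w[other] <- cvec[other]
  list(design = out, weights = full_w)
}

# residualize task columns against intercept + nuisance; returns the Gram
# matrix of the residualized columns and the full-design pieces for cVIF
condition_gram <- function(design) {
  task_cols <- design_columns(design)
  Xt <- design$values[, task_cols, drop = FALSE]
  nuis_cols <- names(design$roles)[design$roles %in%
                                     c("nuisance", "intercept")]
  # residualize against the model's own intercept/nuisance space; a model
  # with neither keeps its raw Gram (no implicit centering)
  if (length(nuis_cols)) {
    Z <- design$values[, nuis_cols, drop = FALSE]
    Xt <- Xt - Z %*% qr.coef(qr(Z), Xt)
  }
  G <- crossprod(Xt)
  dimnames(G) <- list(task_cols, task_cols)
  G
}

#' Contrast-based variance inflation factor (cVIF)
#'
#' The cVIF measures variance inflation for a *contrast* rather than a
#' single parameter: the actual contrast variance factor `c G^-1 c'` is
#' divided by the variance factor `sum_j c_j^2 / G_jj` that the same
#' contrast would have in an ideal reference design with identical
#' per-condition signal energy and no cross-condition overlap (diagonal
#' Gram). Task columns are first residualized against intercept and
#' nuisance columns so drift-explainable variance is not credited to the
#' reference, and `G` is the Gram matrix of the residualized condition
#' columns.
#'
#' Unlike the traditional VIF, cVIF is invariant to invertible
#' reparameterizations of the design (compute it in the condition basis;
#' see [map_to_condition_basis()]) and reduces to [tvif()] for elementary
#' contrasts. Values above 5 for a contrast of interest warrant scrutiny;
#' cVIF may fall below 1 for difference contrasts on negatively correlated
#' columns.
#'
#' @param design A `mid_design` in the condition basis (one task column
#'   per condition signal).
#' @param weights Named contrast weights over the task columns.
#' @return The cVIF, a positive scalar.
#' @examples
#' run <- simulate_mid_run(seed = 1)
#' d <- build_design(run, "saturated")
#' cvif(d, c(cue_LargeWin = 1, cue_Neutral = -1))
#' @export
cvif <- function(design, weights) {
  cvec <- contrast_vector(design, weights)
  task_cols <- design_columns(design)
  cw <- cvec[task_cols]
  if (all(cw == 0)) stop("contrast is all zero on task columns",
                         call. = FALSE)
  nz <- cvec[setdiff(names(cvec), task_cols)]
  if (any(nz != 0)) {
    stop("cVIF contrasts may not weight nuisance or intercept columns",
         call. = FALSE)
  }
  G <- condition_gram(design)
  Ginv <- tryCatch(chol2inv(chol(G)), error = function(e) {
    stop("condition-basis design is rank deficient after residualization",
         call. = FALSE)
  })
  sv <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (sv[length(sv)] / sv[1] < 1e-10) {
    stop("condition-basis design is numerically singular", call. = FALSE)
  }
  actual <- drop(cw %*% Ginv %*% cw)
  ideal <- sum(cw^2 / diag(G))
  actual / ideal
}

#' Collinearity report for a design and its contrasts
#'
#' Per-contrast efficiency and cVIF (with the conventional `cvif > 5`
#' flag) and per-task-column traditional VIF, gathered into one tibble.
#'
#' @param design A `mid_design`.
#' @param contrasts A contrast tibble as from [make_contrasts()], or a
#'   named list of weight vectors; may be empty for column tVIFs only.
#' @param flag_threshold cVIF threshold above which a contrast is flagged.
#' @return A tibble of class `collinearity_report` with columns `term`,
#'   `type` (`"contrast"` or `"column"`), `efficiency`, `tvif`, `cvif`,
#'   `flagged`.
#' @examples
#' run <- simulate_mid_run(seed = 1)
#' d <- build_design(run, "saturated")
#' collinearity_report(d, make_contrasts(d))
#' @export
collinearity_report <- function(design, contrasts = make_contrasts(design),
                                flag_threshold = 5) {
  if (is.data.frame(contrasts)) {
    wlist <- stats::setNames(contrasts$weights, contrasts$name)
  } else {
    wlist <- contrasts
  }
  rows <- purrr::imap_dfr(wlist %||% list(), function(w, nm) {
    tibble::tibble(term = nm, type = "contrast",
                   efficiency = efficiency(design, w),
                   tvif = NA_real_, cvif = cvif(design, w))
  })
  cols <- design_columns(design)
  col_rows <- purrr::map_dfr(cols, function(cl) {
    tibble::tibble(term = cl, type = "column", efficiency = NA_real_,
                   tvif = tvif(design, cl), cvif = NA_real_)
  })
  out <- dplyr::bind_rows(rows, col_rows)
  out$flagged <- !is.na(out$cvif) & out$cvif > flag_threshold
  class(out) <- c("collinearity_report", class(out))
  attr(out, "flag_threshold") <- flag_threshold
  out
}
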