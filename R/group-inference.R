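#' Precision-weighted fixed-effects combination across runs
#'
#' Inverse-variance weighted average of per-run contrast estimates:
#' `estimate = sum(b_i / v_i) / sum(1 / v_i)`, `variance = 1 / sum(1/v_i)`.
#' This is the minimum-variance linear unbiased combination.
#'
#' @param estimates Per-run contrast estimates.
#' @param variances Per-run estimate variances (positive).
#' @return A list with `estimate` and `variance`.
#' @examples
#' fixed_effects_combine(c(0, 4), c(1, 3))  # estimate 1, variance 0.75
#' @export
fixed_effects_combine <- function(estimates, variances) {
  if (!length(estimates) || length(estimates) != length(variances)) {
    stop("estimates and variances must be nonempty and equal length",
         call. = FALSE)
  }
  if (any(variances <= 0)) stop("variances must be positive",
                                call. = FALSE)
  w <- 1 / variances
  list(estimate = sum(estimates * w) / sum(w), variance = 1 / sum(w))
}

#' Scale a contrast estimate to percent signal change
#'
#' Multiplies the estimate by the peak height of the HRF response to a
#' unit boxcar whose duration equals the mean duration of the stimulus
#' type (e.g., 1.97 s for cue and 1.67 s for feedback in the ABCD MID),
#' then converts to percent of baseline.
#'
#' @param estimate Contrast parameter estimate.
#' @param mean_duration Mean stimulus duration, seconds (positive).
#' @param hrf An [hrf_spec()].
#' @param baseline Baseline signal level (positive); percent signal change
#'   is `100 * scaled / baseline`.
#' @return The percent-signal-change value.
#' @export
psc_scale <- function(estimate, mean_duration, hrf = hrf_spec(),
                      baseline = 100) {
  if (mean_duration <= 0) stop("mean_duration must be positive",
                               call. = FALSE)
  if (baseline <= 0) stop("baseline must be positive", call. = FALSE)
  k <- hrf_kernel(hrf)
  cum_k <- cumsum(k$kernel) * k$dt
  tt <- seq(0, hrf$kernel_length + mean_duration, by = k$dt)
  resp <- interp_grid(cum_k, tt, k$dt, left = 0, right = 1) -
    interp_grid(cum_k, tt - mean_duration, k$dt, left = 0, right = 1)
  estimate * max(resp) * 100 / baseline
}

#' Cohen's d from a one-sample t statistic
#'
#' `d = t / sqrt(n)`.
#'
#' @param t t statistic (vectorized).
#' @param n Number of subjects.
#' @return Cohen's d.
#' @examples
#' cohens_d(3.1, 500)
#' @export
cohens_d <- function(t, n) {
  if (any(n <= 0)) stop("n must be positive", call. = FALSE)
  t / sqrt(n)
}

# linear voxel indices of the 6-connected (face-adjacent) neighbors;
# cached per grid shape since the permutation loop reuses it heavily
neighbor_cache <- new.env(parent = emptyenv())
neighbor_pairs_3d <- function(dim3) {
  key <- paste(dim3, collapse = "x")
  if (!is.null(neighbor_cache[[key]])) return(neighbor_cache[[key]])
  idx <- array(seq_len(prod(dim3)), dim = dim3)
  pairs <- list()
  if (dim3[1] > 1) {
    pairs[[1]] <- cbind(as.vector(idx[-dim3[1], , ]),
                        as.vector(idx[-1, , ]))
  }
  if (dim3[2] > 1) {
    pairs[[2]] <- cbind(as.vector(idx[, -dim3[2], ]),
                        as.vector(idx[, -1, ]))
  }
  if (dim3[3] > 1) {
    pairs[[3]] <- cbind(as.vector(idx[, , -dim3[3]]),
                        as.vector(idx[, , -1]))
  }
  out <- do.call(rbind, pairs)
  neighbor_cache[[key]] <- out
  out
}

# union-find labeling of supra-threshold voxels; returns integer component
# labels aligned with which(supra)
label_components <- function(supra, pairs) {
  vox <- which(supra)
  n <- length(vox)
  if (!n) return(integer(0))
  rank_of <- integer(length(supra))
  rank_of[vox] <- seq_len(n)
  keep <- supra[pairs[, 1]] & supra[pairs[, 2]]
  a <- rank_of[pairs[keep, 1]]
  b <- rank_of[pairs[keep, 2]]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(a)) {
    ra <- find(a[k])
    rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# largest supra-threshold cluster over both signs (fast path of
# extract_clusters for the permutation loop)
max_cluster_size_fast <- function(tvec, dim3, threshold) {
  pairs <- neighbor_pairs_3d(dim3)
  best <- 0L
  for (supra in list(!is.na(tvec) & tvec > threshold,
                     !is.na(tvec) & tvec < -threshold)) {
    lab <- label_components(supra, pairs)
    if (length(lab)) best <- max(best, max(tabulate(lab)))
  }
  best
}

#' Extract supra-threshold clusters from a 3D statistic map
#'
#' Connected components (6-connectivity: face-adjacent voxels) of the
#' voxels exceeding the cluster-forming threshold. Two-sided extraction
#' clusters positive (`t > threshold`) and negative (`t < -threshold`)
#' voxels separately; both contribute clusters.
#'
#' @param map 3D numeric array.
#' @param threshold Cluster-forming threshold on the statistic.
#' @param two_sided Also cluster the negative tail.
#' @param mask Optional 3D logical array restricting the search.
#' @return A tibble with one row per cluster: `cluster`, `sign`, `size`,
#'   `peak` (most extreme statistic) and `voxels` (list of linear voxel
#'   indices).
#' @export
extract_clusters <- function(map, threshold, two_sided = TRUE,
                             mask = NULL) {
  stopifnot(length(dim(map)) == 3)
  if (is.null(mask)) mask <- array(TRUE, dim(map))
  one_sign <- function(supra, sign_label) {
    vox <- which(supra)
    if (!length(vox)) {
      return(tibble::tibble(cluster = integer(), sign = character(),
                            size = integer(), peak = numeric(),
                            voxels = list()))
    }
    membership <- label_components(supra, neighbor_pairs_3d(dim(map)))
    purrr::map_dfr(seq_len(max(membership)), function(k) {
      v <- vox[membership == k]
      tibble::tibble(cluster = k, sign = sign_label,
                     size = length(v),
                     peak = map[v][which.max(abs(map[v]))],
                     voxels = list(v))
    })
  }
  supra_pos <- mask & !is.na(map) & map > threshold
  out <- one_sign(supra_pos, "positive")
  if (two_sided) {
    supra_neg <- mask & !is.na(map) & map < -threshold
    neg <- one_sign(supra_neg, "negative")
    if (nrow(neg)) neg$cluster <- neg$cluster + nrow(out)
    out <- dplyr::bind_rows(out, neg)
  }
  out
}

# one-sample t map across subjects; zero-variance voxels -> NA
group_t_map <- function(stack) {
  n <- dim(stack)[1]
  m <- colMeans(stack)
  s <- sqrt(colMeans(stack^2) - m^2) * sqrt(n / (n - 1))
  t <- m / (s / sqrt(n))
  t[s == 0] <- NA_real_
  t
}

#' Site-stratified sign-flip cluster-extent permutation test
#'
#' One-sample group test with family-wise error control by cluster size:
#' the observed map of one-sample t statistics is thresholded at the
#' cluster-forming threshold (two-sided) and its clusters are compared to
#' a null distribution of maximum cluster sizes obtained by sign-flipping
#' permutations stratified by scanner site — all subjects within a site
#' flip jointly, preserving the multi-site structure. With S sites all
#' `2^S` flips are enumerated when feasible (13 sites yields 8192), else a
#' seeded Monte-Carlo subset (always including the identity flip) is
#' used. Positive and negative clusters contribute to a single max-size
#' null per flip. The significance threshold is the 95th-percentile
#' (ceiling rule) of the null; observed clusters strictly larger are
#' significant.
#'
#' @param subject_maps List of 3D arrays (one per subject) or a
#'   subjects-by-voxels matrix plus `dim3`.
#' @param site_labels Per-subject site labels (at least 2 distinct).
#' @param cf_threshold Cluster-forming t threshold.
#' @param alpha FWER level.
#' @param max_perms Cap on permutations before Monte-Carlo sampling.
#' @param seed Seed for the Monte-Carlo subset.
#' @param dim3 Map dimensions when `subject_maps` is a matrix.
#' @param mask Optional 3D logical array.
#' @return A list of class `group_perm_result`: `t_map` (3D array),
#'   `clusters` (tibble with `significant` column),
#'   `null_max_cluster_sizes`, `cluster_size_threshold`, `n_permutations`,
#'   `n_subjects`.
#' @export
sign_flip_cluster_test <- function(subject_maps, site_labels,
                                   cf_threshold = 3.1, alpha = 0.05,
                                   max_perms = 10000, seed = 1L,
                                   dim3 = NULL, mask = NULL) {
  if (is.list(subject_maps)) {
    dims <- unique(lapply(subject_maps, dim))
    if (length(dims) != 1L) stop("subject maps must share a grid",
                                 call. = FALSE)
    dim3 <- dims[[1]]
    stack <- t(vapply(subject_maps, as.vector,
                      numeric(prod(dim3))))
  } else {
    stack <- subject_maps
    if (is.null(dim3)) stop("supply dim3 with a matrix input",
                            call. = FALSE)
  }
  n <- nrow(stack)
  if (length(site_labels) != n) {
    stop("need one site label per subject", call. = FALSE)
  }
  sites <- unique(site_labels)
  S <- length(sites)
  if (S < 2) stop("need at least two sites", call. = FALSE)
  if (!is.null(mask)) stack[, !as.vector(mask)] <- NA_real_

  flips <- if (2^S <= max_perms) {
    m <- as.matrix(expand.grid(rep(list(c(1, -1)), S)))
    colnames(m) <- NULL
    m
  } else {
    with_preserved_seed(seed, {
      m <- matrix(sample(c(1, -1), (max_perms - 1L) * S, replace = TRUE),
                  ncol = S)
      rbind(rep(1, S), m)  # identity flip always included
    })
  }
  site_index <- match(site_labels, sites)

  null_sizes <- integer(nrow(flips))
  obs_t <- NULL
  for (i in seq_len(nrow(flips))) {
    signs <- flips[i, site_index]
    tvec <- group_t_map(stack * signs)
    if (all(signs == 1) && is.null(obs_t)) obs_t <- tvec
    null_sizes[i] <- max_cluster_size_fast(tvec, dim3, cf_threshold)
  }
  if (is.null(obs_t)) obs_t <- group_t_map(stack)

  sorted <- sort(null_sizes)
  thr <- sorted[ceiling((1 - alpha) * length(sorted))]
  t_map <- array(obs_t, dim = dim3)
  clusters <- extract_clusters(t_map, cf_threshold, two_sided = TRUE)
  clusters$significant <- clusters$size > thr

  structure(
    list(t_map = t_map, clusters = clusters,
         null_max_cluster_sizes = null_sizes,
         cluster_size_threshold = thr,
         n_permutations = nrow(flips), n_subjects = n,
         cf_threshold = cf_threshold, alpha = alpha),
    class = "group_perm_result"
  )
}

#' @export
print.group_perm_result <- function(x, ...) {
  cat(sprintf(
    "<group_perm_result> %d subjects, %d permutations, CFT %g\n",
    x$n_subjects, x$n_permutations, x$cf_threshold))
  cat(sprintf("  cluster-size threshold (alpha %g): %d voxels\n",
              x$alpha, x$cluster_size_threshold))
  cat(sprintf("  %d cluster(s), %d significant\n", nrow(x$clusters),
              sum(x$clusters$significant)))
  invisible(x)
}

#' Flag subjects with outlying contrast maps
#'
#' Voxelwise, a subject is marked where its estimate deviates from the
#' across-subject mean by more than `k` across-subject standard
#' deviations (zero-SD voxels never mark); a subject is flagged when the
#' marked fraction of in-mask voxels exceeds `voxel_fraction_threshold`.
#' Recommended when a contrast of interest has cVIF above 5.
#'
#' @param subject_maps List of 3D arrays or subjects-by-voxels matrix.
#' @param k SD multiplier, conventionally 2 or 3.
#' @param voxel_fraction_threshold Fraction of in-mask voxels that must be
#'   marked to flag a subject.
#' @param mask Optional 3D logical array.
#' @return A tibble with `subject`, `fraction_outlying`, `flagged`.
#' @export
flag_outliers <- function(subject_maps, k = 3,
                          voxel_fraction_threshold = 0.1, mask = NULL) {
  if (is.list(subject_maps)) {
    stack <- t(vapply(subject_maps, as.vector,
                      numeric(length(subject_maps[[1]]))))
  } else stack <- subject_maps
  n <- nrow(stack)
  if (n < 3) stop("need at least three subjects", call. = FALSE)
  keep <- if (is.null(mask)) rep(TRUE, ncol(stack)) else as.vector(mask)
  sub <- stack[, keep, drop = FALSE]
  m <- colMeans(sub)
  s <- apply(sub, 2, stats::sd)
  marked <- abs(sweep(sub, 2, m)) > k * rep(s, each = n) &
    rep(s > 0, each = n)
  frac <- rowMeans(marked)
  tibble::tibble(subject = seq_len(n), fraction_outlying = frac,
                 flagged = frac > voxel_fraction_threshold)
}

#' Read and write 3D statistic maps as NIfTI
#'
#' Thin wrappers over the RNifti package for moving statistic maps in and
#' out of the group-inference functions, which operate on plain 3D
#' arrays.
#'
#' @param path NIfTI file path.
#' @param map 3D numeric array.
#' @return `read_stat_map()` returns a 3D array; `write_stat_map()` its
#'   input, invisibly.
#' @export
read_stat_map <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI maps requires the RNifti package", call. = FALSE)
  }
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3) stop("expected a 3D volume", call. = FALSE)
  arr
}

#' @rdname read_stat_map
#' @export
write_stat_map <- function(map, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI maps requires the RNifti package", call. = FALSE)
  }
  RNifti::writeNifti(RNifti::asNifti(map), path)
  invisible(map)
}
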