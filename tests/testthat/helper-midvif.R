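# shared fixtures and independent oracles

# deterministic run fixture (memoized per seed)
fixture_run <- local({
  cache <- list()
  function(seed = 1L) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) cache[[key]] <<- simulate_mid_run(seed = seed)
    cache[[key]]
  }
})

# run in which every cue condition has at least one Hit and one Miss
fixture_complete_run <- function() {
  for (s in 1:50) {
    run <- fixture_run(s)
    tab <- table(run$condition, run$outcome == "Hit")
    if (all(dim(tab) == c(5, 2)) && all(tab > 0)) return(run)
  }
  stop("no complete run found in 50 seeds")
}

# hand-built design from explicit columns (for algebraic checks)
toy_design <- function(X, roles = rep("task", ncol(X)), tr = 1) {
  as_mid_design(X, tr = tr, roles = roles)
}

# brute-force discrete convolution on a fine grid: independent oracle for
# the semi-analytic regressor construction
oracle_convolve <- function(frame_times, onsets, durations, hrf,
                            dt = 0.002) {
  tmax <- max(frame_times) + hrf$kernel_length + 1
  grid <- seq(0, tmax, by = dt)
  neural <- numeric(length(grid))
  durations <- rep_len(durations, length(onsets))
  for (i in seq_along(onsets)) {
    if (durations[i] > 0) {
      on <- neural
      sel <- grid >= onsets[i] & grid < onsets[i] + durations[i]
      neural[sel] <- neural[sel] + 1
    } else {
      j <- which.min(abs(grid - onsets[i]))
      neural[j] <- neural[j] + 1 / dt  # unit-area spike
    }
  }
  kt <- seq(0, hrf$kernel_length - dt, by = dt)
  kern <- midvif:::double_gamma(kt, hrf)
  kern <- kern / (sum(kern) * dt)
  conv <- stats::convolve(neural, rev(kern), type = "open")[
    seq_along(grid)] * dt
  stats::approx(grid, conv, xout = frame_times)$y
}

# independent flood-fill labeling oracle (breadth-first over face
# neighbors), deliberately distinct from the union-find implementation
oracle_flood_fill <- function(supra) {
  d <- dim(supra)
  labels <- array(0L, d)
  nxt <- 0L
  coords <- which(supra, arr.ind = TRUE)
  for (r in seq_len(nrow(coords))) {
    start <- coords[r, ]
    if (labels[start[1], start[2], start[3]] != 0L) next
    nxt <- nxt + 1L
    queue <- list(start)
    labels[start[1], start[2], start[3]] <- nxt
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (step in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
        w <- v + step
        if (any(w < 1) || any(w > d)) next
        if (supra[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- nxt
          queue[[length(queue) + 1]] <- w
        }
      }
    }
  }
  labels
}

# separable smoothing for synthetic "smooth Gaussian noise" maps
smooth3 <- function(a, w = c(0.25, 0.5, 0.25)) {
  for (d in 1:3) {
    a <- aperm(a, c(d, setdiff(1:3, d)))
    a2 <- a * w[2]
    a2[-1, , ] <- a2[-1, , ] + a[-dim(a)[1], , ] * w[1]
    a2[-dim(a)[1], , ] <- a2[-dim(a)[1], , ] + a[-1, , ] * w[3]
    a <- aperm(a2, order(c(d, setdiff(1:3, d))))
  }
  a
}

# random full-rank centered design for property tests
random_centered_design <- function(n = 40, p = 4, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  X <- scale(X, center = TRUE, scale = FALSE)
  colnames(X) <- paste0("c", seq_len(p))
  toy_design(X)
}
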