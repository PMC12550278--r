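#' Hemodynamic response function specification
#'
#' Parameters of the canonical double-gamma hemodynamic response function
#' (HRF): the BOLD impulse response is modeled as the difference of two
#' gamma densities, a positive peak followed by a delayed undershoot.
#'
#' The kernel is normalized to unit integral, so a sustained (long) boxcar
#' stimulus of amplitude 1 converges to a plateau of height 1. All
#' convolution in the package samples the kernel on a microtime grid of
#' spacing `microtime_dt` and evaluates regressors semi-analytically from
#' its cumulative integral.
#'
#' @param peak_delay Delay of the positive peak, seconds.
#' @param undershoot_delay Delay of the undershoot, seconds.
#' @param peak_dispersion Dispersion (gamma scale) of the peak, seconds.
#' @param undershoot_dispersion Dispersion of the undershoot, seconds.
#' @param undershoot_ratio Ratio of undershoot to peak amplitude.
#' @param kernel_length Length of the sampled kernel, seconds.
#' @param microtime_dt Microtime resolution, seconds.
#'
#' @return An object of class `hrf_spec`.
#' @examples
#' spec <- hrf_spec()
#' k <- hrf_kernel(spec)
#' @export
hrf_spec <- function(peak_delay = 6,
                     undershoot_delay = 16,
                     peak_dispersion = 1,
                     undershoot_dispersion = 1,
                     undershoot_ratio = 1 / 6,
                     kernel_length = 32,
                     microtime_dt = 0.016) {
  vals <- c(peak_delay, undershoot_delay, peak_dispersion,
            undershoot_dispersion, undershoot_ratio, kernel_length,
            microtime_dt)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all `hrf_spec` parameters must be finite and positive",
         call. = FALSE)
  }
  structure(
    list(peak_delay = peak_delay,
         undershoot_delay = undershoot_delay,
         peak_dispersion = peak_dispersion,
         undershoot_dispersion = undershoot_dispersion,
         undershoot_ratio = undershoot_ratio,
         kernel_length = kernel_length,
         microtime_dt = microtime_dt),
    class = "hrf_spec"
  )
}

#' @export
print.hrf_spec <- function(x, ...) {
  cat("<hrf_spec> double-gamma HRF\n")
  cat(sprintf("  peak %g s (disp %g), undershoot %g s (disp %g, ratio %g)\n",
              x$peak_delay, x$peak_dispersion, x$undershoot_delay,
              x$undershoot_dispersion, x$undershoot_ratio))
  cat(sprintf("  kernel %g s @ dt %g s\n", x$kernel_length, x$microtime_dt))
  invisible(x)
}

# unnormalized double-gamma value at times t (vectorized)
double_gamma <- function(t, spec) {
  a1 <- spec$peak_delay / spec$peak_dispersion
  a2 <- spec$undershoot_delay / spec$undershoot_dispersion
  stats::dgamma(t, shape = a1, scale = spec$peak_dispersion) -
    spec$undershoot_ratio *
      stats::dgamma(t, shape = a2, scale = spec$undershoot_dispersion)
}

# analytic time derivative of the double gamma:
# d/dt dgamma(t; a, s) = dgamma(t; a, s) * ((a - 1)/t - 1/s)
double_gamma_deriv <- function(t, spec) {
  a1 <- spec$peak_delay / spec$peak_dispersion
  a2 <- spec$undershoot_delay / spec$undershoot_dispersion
  d1 <- stats::dgamma(t, shape = a1, scale = spec$peak_dispersion)
  d2 <- stats::dgamma(t, shape = a2, scale = spec$undershoot_dispersion)
  out <- d1 * ((a1 - 1) / t - 1 / spec$peak_dispersion) -
    spec$undershoot_ratio *
      d2 * ((a2 - 1) / t - 1 / spec$undershoot_dispersion)
  out[t <= 0] <- 0
  out
}

#' Sample the double-gamma HRF kernel and its temporal derivative
#'
#' @param spec An [hrf_spec()].
#' @return A list with components `time` (microtime grid), `kernel`
#'   (unit-integral HRF values), `derivative` (analytic time derivative of
#'   the normalized kernel), and `dt`.
#' @examples
#' k <- hrf_kernel(hrf_spec())
#' k$time[which.max(k$kernel)]  # peak near 5 s
#' @export
hrf_kernel <- function(spec = hrf_spec()) {
  if (!inherits(spec, "hrf_spec")) spec <- do.call(hrf_spec, as.list(spec))
  if (spec$microtime_dt <= 0) stop("microtime_dt must be positive",
                                   call. = FALSE)
  tt <- seq(0, spec$kernel_length - spec$microtime_dt,
            by = spec$microtime_dt)
  raw <- double_gamma(tt, spec)
  norm <- sum(raw) * spec$microtime_dt  # trapezoid-free Riemann integral
  if (!is.finite(norm) || norm <= 0) {
    stop("HRF kernel does not integrate to a positive value", call. = FALSE)
  }
  list(time = tt,
       kernel = raw / norm,
       derivative = double_gamma_deriv(tt, spec) / norm,
       dt = spec$microtime_dt)
}
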