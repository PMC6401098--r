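#' Canonical double-gamma haemodynamic response function
#'
#' The ground-truth impulse response used by the simulators: a gamma
#' density peaking near 5 s minus a later undershoot gamma (peak 16 s)
#' scaled by 1/6, normalised to a unit peak. The analysis side never
#' assumes this shape -- responses are estimated with FIR bins -- so the
#' HRF only needs to be a realistic generator.
#'
#' @param times numeric vector of non-negative, sorted, uniformly spaced
#'   times in seconds.
#' @param peak_delay,undershoot_delay gamma shape parameters for the
#'   response and undershoot components (defaults 6 and 16, unit rate).
#' @param undershoot_ratio response/undershoot amplitude ratio (default 6).
#' @return numeric vector of responses; the continuous curve has maximum 1,
#'   value 0 at t = 0 and is back near 0 by 30 s.
#' @export
double_gamma_hrf <- function(times, peak_delay = 6, undershoot_delay = 16,
                             undershoot_ratio = 6) {
  if (length(times) == 0) return(numeric(0))
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative")
  if (is.unsorted(times)) stop("times must be sorted increasingly")
  if (length(times) > 2) {
    d <- diff(times)
    if (max(d) - min(d) > 1e-8 * max(d)) stop("times must be uniformly spaced")
  }
  shape <- function(t) {
    stats::dgamma(t, shape = peak_delay, rate = 1) -
      stats::dgamma(t, shape = undershoot_delay, rate = 1) / undershoot_ratio
  }
  peak <- stats::optimize(shape, c(0, 12), maximum = TRUE)$objective
  shape(times) / peak
}
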