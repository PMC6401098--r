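# Shared fixture builders: small grids keep simulation cheap while
# preserving the default signal region (4^3 voxels) and trial structure.

tiny_acq <- function(run_length = 300, grid = c(6L, 6L, 6L))
  acq_spec(voxel_grid = grid, run_length_seconds = run_length)

quiet_noise <- function(sd = 0) noise_spec(white_sd = sd,
                                           ar1_coefficient = 0,
                                           drift_amplitude = 0)

# A clean single-subject session: deterministic, low-noise.
tiny_session <- function(n_runs = 3, seed = 42, white_sd = 1, ...) {
  acq <- tiny_acq()
  sig <- random_signal_spec(acq, seed = seed, ...)
  runs <- simulate_subject_imagery(acq, sig,
                                   noise_spec(white_sd = white_sd,
                                              ar1_coefficient = 0.2,
                                              drift_amplitude = 1),
                                   choice_policy(), n_runs, seed + 1)
  list(acq = acq, signal = sig, runs = runs)
}

# Direct discrete convolution of a trial boxcar with the HRF, written
# independently of the package's convolution path (plain double loop on
# the volume grid) for use as an oracle.
oracle_convolved <- function(events, acq, onset_lag, duration,
                             amplitudes = NULL) {
  dt <- 0.1
  tt <- seq(0, acq$run_length - dt, by = dt)
  h <- double_gamma_hrf(seq(0, 32, by = dt))
  neural <- numeric(length(tt))
  amplitudes <- amplitudes %||% rep(1, nrow(events))
  for (i in seq_len(nrow(events))) {
    on <- events$press_time[i] + onset_lag
    sel <- tt >= max(0, on) & tt < min(acq$run_length, on + duration)
    neural[sel] <- neural[sel] + amplitudes[i]
  }
  out <- numeric(length(tt))
  for (k in seq_along(h)) {
    idx <- seq_along(tt) - (k - 1)
    ok <- idx >= 1
    out[ok] <- out[ok] + h[k] * neural[idx[ok]] * dt
  }
  vt <- (seq_len(round(acq$run_length / acq$tr)) - 1) * acq$tr
  out[round(vt / dt) + 1]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
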