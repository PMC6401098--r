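# Phase-encoded retinotopic mapping: voxel-wise Fourier phase and SNR at
# the stimulation frequency.

#' Voxel-wise FFT phase and SNR at the stimulation frequency
#'
#' Computes, per voxel, the discrete Fourier coefficient at the grid
#' frequency nearest `stim_freq`. Phase is reported in sine convention --
#' a noiseless `sin(2*pi*f*t + phi)` voxel recovers `phi` -- wrapped to
#' `[0, 2*pi)`. SNR is the amplitude at the stimulation frequency divided
#' by the mean amplitude over all other non-DC frequencies excluding the
#' two immediate neighbours of the stimulation bin (a one-bin guard band).
#'
#' @param series time-by-voxel matrix (or a retinotopy `sim_run`).
#' @param tr sampling interval in seconds.
#' @param stim_freq stimulation frequency in Hz; must fall within half a
#'   frequency bin of an FFT grid frequency.
#' @return object of class `phase_map`: list with `phase` (radians),
#'   `snr`, `amplitude`, `stim_freq`, `mask` (NULL until thresholded).
#' @export
fft_phase_snr <- function(series, tr = 2, stim_freq = 1 / 30) {
  x <- if (inherits(series, "sim_run")) bold_matrix(series) else
    as.matrix(series)
  nt <- nrow(x)
  if (nt * tr < 2 / stim_freq) stop("series shorter than 2 cycles")
  freqs <- (seq_len(nt) - 1) / (nt * tr)
  half <- floor(nt / 2)
  k <- which.min(abs(freqs[2:(half + 1)] - stim_freq)) + 1L  # index into freqs
  if (abs(freqs[k] - stim_freq) > 1 / (2 * nt * tr) + 1e-12)
    stop("stim_freq not resolvable on the FFT grid")
  co <- mvfft(x)
  amp <- Mod(co[2:(half + 1), , drop = FALSE])
  phase <- unname((Arg(co[k, ]) + pi / 2) %% (2 * pi))
  drop_rows <- (k - 1) + (-1:1)          # rows of `amp` around the stim bin
  drop_rows <- drop_rows[drop_rows >= 1 & drop_rows <= half]
  denom <- colMeans(amp[-drop_rows, , drop = FALSE])
  structure(list(phase = phase, snr = unname(amp[k - 1, ] / denom),
                 amplitude = unname(amp[k - 1, ]), stim_freq = freqs[k],
                 mask = NULL, threshold = NULL),
            class = "phase_map")
}

#' Threshold a phase map by SNR
#'
#' Keeps every voxel's phase but records which voxels pass the SNR
#' criterion (default 2, the conventional amplitude threshold for
#' phase-encoded maps).
#'
#' @param map a `phase_map`.
#' @param snr_threshold minimum SNR (default 2).
#' @return the map with `mask` (logical) and `threshold` filled in.
#' @export
threshold_phase_map <- function(map, snr_threshold = 2) {
  map$mask <- map$snr >= snr_threshold
  map$threshold <- snr_threshold
  map
}
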