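#' Acquisition specification
#'
#' Describes the scanner sampling grid used by all simulators: repetition
#' time, voxel grid, run length and the standard lead-in fixation. The first
#' `discard_initial_volumes` volumes exist only as burn-in; the retained
#' time axis starts at second 0 with the first kept volume, and all event
#' times are expressed on that axis.
#'
#' @param tr_seconds repetition time in seconds (default 2).
#' @param voxel_grid integer vector of 3 positive grid dimensions.
#' @param run_length_seconds retained task duration; must be a positive
#'   multiple of `tr_seconds` (default 300, a 5-minute imagery run).
#' @param discard_initial_volumes number of burn-in volumes simulated and
#'   dropped before the retained time axis (default 4).
#' @param lead_in_fixation_seconds fixation period at the start of the
#'   retained axis before the first trial (default 10).
#' @param voxel_size_mm isotropic voxel size in mm (default 3).
#' @return an object of class `acq_spec`.
#' @export
acq_spec <- function(tr_seconds = 2, voxel_grid = c(12L, 12L, 12L),
                     run_length_seconds = 300,
                     discard_initial_volumes = 4L,
                     lead_in_fixation_seconds = 10,
                     voxel_size_mm = 3) {
  stopifnot(tr_seconds > 0, length(voxel_grid) == 3L, all(voxel_grid >= 1),
            run_length_seconds > 0, discard_initial_volumes >= 0,
            lead_in_fixation_seconds >= 0)
  if (abs(run_length_seconds / tr_seconds -
          round(run_length_seconds / tr_seconds)) > 1e-9)
    stop("run_length_seconds must be a positive multiple of tr_seconds")
  structure(list(tr = tr_seconds, dim = as.integer(voxel_grid),
                 run_length = run_length_seconds,
                 discard = as.integer(discard_initial_volumes),
                 lead_in = lead_in_fixation_seconds,
                 voxel_mm = voxel_size_mm),
            class = "acq_spec")
}

n_volumes <- function(acq) as.integer(round(acq$run_length / acq$tr))
n_voxels <- function(acq) prod(acq$dim)
volume_times <- function(acq) (seq_len(n_volumes(acq)) - 1) * acq$tr

#' FIR estimation grid
#'
#' Time bins for finite-impulse-response deconvolution anchored at the
#' button press. Bin `j` covers the half-open interval
#' `[window_start + (j-1)*bin_width, window_start + j*bin_width)`; bins are
#' labelled by their start time, so the default 14 bins of 2 s span
#' -13 s to +15 s and carry the labels -13, -11, ..., +13.
#'
#' @param window_start start of the first bin relative to the press (s).
#' @param n_bins number of bins (default 14).
#' @param bin_width width of each bin in seconds (default 2, one TR).
#' @return an object of class `fir_grid`.
#' @export
fir_grid <- function(window_start = -13, n_bins = 14L, bin_width = 2) {
  stopifnot(n_bins >= 1, bin_width > 0)
  structure(list(window_start = window_start, n_bins = as.integer(n_bins),
                 bin_width = bin_width,
                 bin_times = window_start + (seq_len(n_bins) - 1) * bin_width),
            class = "fir_grid")
}

#' Ground-truth signal specification
#'
#' Describes the discriminative multivoxel signal injected by the
#' simulators: two voxel-weight patterns over a designated signal region,
#' the lag (relative to the press) at which the chosen pattern turns on,
#' its duration and amplitude, plus two knobs mirroring the pipeline's
#' control analyses: `carryover_fraction` (how much of the previous trial's
#' pattern lingers into the next trial's pre-imagery period) and
#' `perception_overlap` (cosine similarity between the patterns driven by
#' perceptual blocks and the imagery patterns).
#'
#' @param region integer vector of linear voxel indices carrying signal.
#' @param pattern_A,pattern_B numeric weight vectors, same length as
#'   `region`.
#' @param onset_lag_seconds signed lag of pattern onset relative to the
#'   press; negative means the pattern is active before the press
#'   (default -11, the regime of interest for pre-decision decoding).
#' @param signal_duration_seconds how long the pattern stays on
#'   (default 21: from -11 s through the 10-s imagery period).
#' @param amplitude unitless scale of the injected pattern (default 1).
#' @param amplitude_sd per-trial multiplicative amplitude variability
#'   (default 0.3); trial amplitude is `amplitude * max(0, 1 + sd * z)`.
#' @param carryover_fraction fraction (0-1) of the previous trial's pattern
#'   re-injected during the next trial's pre-imagery period (default 0).
#' @param perception_overlap cosine similarity (0-1) between perception
#'   block patterns and the imagery patterns (default 1).
#' @param strength_fraction scale (relative to `amplitude`) of a
#'   label-independent "engagement" pattern, orthogonal to both class
#'   patterns, injected with the per-trial amplitude (default 1). This
#'   component carries the trial's overall imagery strength, so that
#'   vividness -- a monotone readout of trial amplitude -- is linearly
#'   decodable without informing the content classification. The default
#'   of 4 puts future-vividness decoding at full coupling near 60
#'   percent, the strength-decoding regime reported for early visual
#'   cortex.
#' @return an object of class `signal_spec`.
#' @export
signal_spec <- function(region, pattern_A, pattern_B,
                        onset_lag_seconds = -11,
                        signal_duration_seconds = 21,
                        amplitude = 1, amplitude_sd = 0.3,
                        carryover_fraction = 0, perception_overlap = 1,
                        strength_fraction = 4) {
  stopifnot(length(pattern_A) == length(region),
            length(pattern_B) == length(region),
            amplitude >= 0, amplitude_sd >= 0,
            signal_duration_seconds > 0,
            carryover_fraction >= 0, carryover_fraction <= 1,
            perception_overlap >= 0, perception_overlap <= 1,
            strength_fraction >= 0)
  structure(list(region = as.integer(region),
                 pattern_A = as.numeric(pattern_A),
                 pattern_B = as.numeric(pattern_B),
                 onset_lag = onset_lag_seconds,
                 duration = signal_duration_seconds,
                 amplitude = amplitude, amplitude_sd = amplitude_sd,
                 carryover = carryover_fraction,
                 perception_overlap = perception_overlap,
                 strength_fraction = strength_fraction),
            class = "signal_spec")
}

#' Random signal specification on a central cube
#'
#' Convenience constructor: places the signal region on a central cube of
#' the acquisition grid and draws two orthogonal unit-norm zero-mean
#' patterns. The patterns have zero spatial mean so the injected signal is
#' purely multivariate: the region-average response is identical for the
#' two labels, as in a univariate-null construction.
#'
#' @param acq an [acq_spec()].
#' @param side side length (voxels) of the cubic signal region (default 4).
#' @param seed RNG seed for the patterns.
#' @param ... passed on to [signal_spec()].
#' @return a `signal_spec`.
#' @export
random_signal_spec <- function(acq, side = 4L, seed = 1L, ...) {
  stopifnot(all(acq$dim >= side))
  lo <- pmax(1L, (acq$dim - side) %/% 2L + 1L)
  ix <- lapply(1:3, function(k) lo[k]:(lo[k] + side - 1L))
  grid <- as.matrix(expand.grid(ix[[1]], ix[[2]], ix[[3]]))
  region <- grid[, 1] + (grid[, 2] - 1L) * acq$dim[1] +
    (grid[, 3] - 1L) * prod(acq$dim[1:2])
  p <- with_seed(seed, {
    m <- matrix(rnorm(2 * length(region)), ncol = 2)
    m <- sweep(m, 2, colMeans(m))              # zero spatial mean
    q <- qr.Q(qr(m))                           # orthonormal pair
    q
  })
  signal_spec(region = sort(region), pattern_A = p[, 1], pattern_B = p[, 2],
              ...)
}

#' Noise specification
#'
#' Additive noise model for the simulators: white Gaussian innovations
#' driving a first-order autoregressive process per voxel, plus a
#' single-sinusoid low-frequency drift with a random per-voxel phase.
#' Defaults are calibrated so that bin-wise decoding at `amplitude = 1`
#' lands in the mid-50s to mid-60s percent range with the default design.
#'
#' @param white_sd innovation standard deviation (default 5.5).
#' @param ar1_coefficient AR(1) coefficient, |value| < 1 (default 0.3).
#' @param drift_amplitude amplitude of the sinusoidal drift (default 3).
#' @param drift_period_seconds drift period (default 256 s, slower than the
#'   default 128-s high-pass cutoff so the filter must remove it).
#' @param seed optional RNG seed attached to the spec.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 5.5, ar1_coefficient = 0.3,
                       drift_amplitude = 3, drift_period_seconds = 256,
                       seed = NULL) {
  stopifnot(white_sd >= 0, abs(ar1_coefficient) < 1, drift_amplitude >= 0,
            drift_period_seconds > 0)
  structure(list(white_sd = white_sd, ar1 = ar1_coefficient,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period_seconds, seed = seed),
            class = "noise_spec")
}

#' Free-choice policy
#'
#' Behavioural model for the self-paced imagery task: a first choice drawn
#' fairly, subsequent choices switching with probability `p_switch`;
#' decision times from a gamma distribution right-truncated at
#' `max_decision_seconds`; and a 1-4 vividness rating obtained by binning a
#' latent mixture of the trial's signal amplitude (weight
#' `vividness_coupling`) and independent noise.
#'
#' @param p_switch probability of switching label between consecutive
#'   trials (default 0.586, a typical empirical switch rate).
#' @param decision_mean_seconds mean pre-truncation decision time
#'   (default 5.48 s).
#' @param decision_shape gamma shape parameter (default 2).
#' @param max_decision_seconds truncation bound (default 20 s).
#' @param vividness_coupling 0-1 weight of the trial amplitude in the
#'   latent vividness score (default 0.5).
#' @return an object of class `choice_policy`.
#' @export
choice_policy <- function(p_switch = 0.586, decision_mean_seconds = 5.48,
                          decision_shape = 2, max_decision_seconds = 20,
                          vividness_coupling = 0.5) {
  stopifnot(p_switch >= 0, p_switch <= 1, decision_mean_seconds > 0,
            decision_shape > 0, max_decision_seconds > 0,
            vividness_coupling >= 0, vividness_coupling <= 1)
  structure(list(p_switch = p_switch, decision_mean = decision_mean_seconds,
                 decision_shape = decision_shape,
                 max_decision = max_decision_seconds,
                 vividness_coupling = vividness_coupling),
            class = "choice_policy")
}
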