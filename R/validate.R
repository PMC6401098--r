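# Simulation validation experiments. Each function runs one calibrated
# property study of the pipeline on synthetic data with known ground
# truth: null calibration of the permutation machinery, onset-lag
# recovery, generalization specificity, the spillover control, counting-
# test family-wise error, retinotopic phase recovery and future-vividness
# decoding. Problem sizes default to desk scale (minutes on one CPU);
# the methods vignette discusses the choices.

#' Null calibration of the permutation decoding pipeline
#'
#' Simulates a no-signal group (amplitude 0), builds the within-run
#' label-shuffle permutation null through the full GLM + decoding
#' pipeline, and reports the ensemble grand mean (expected 50 percent)
#' together with the pointwise type-I rate of the parametric group test
#' applied to every null iteration and bin at level `alpha`.
#'
#' @param n_subjects,n_runs group size (defaults 8 subjects, 5 runs).
#' @param n_iter permutation iterations (default 200).
#' @param acq acquisition spec (default 12^3 grid, 5-minute runs).
#' @param alpha pointwise level for the type-I rate (default 0.05).
#' @param seed master seed.
#' @return list with `grand_mean`, `type1_rate`, `ensemble`, `bias`.
#' @export
null_calibration_experiment <- function(n_subjects = 8, n_runs = 5,
                                        n_iter = 200,
                                        acq = acq_spec(), alpha = 0.05,
                                        seed = 1) {
  group <- simulate_group(n_subjects, n_runs, acq, seed = seed,
                          signal_args = list(amplitude = 0))
  caches <- lapply(group, function(su)
    lapply(su$runs, fir_permutation_cache, grid = fir_grid(),
           cutoff_seconds = 128, voxels = su$signal$region))
  ens <- permutation_null(caches, n_iter = n_iter, seed = seed + 1)
  ps <- pointwise_pvalues(ens$subject_acc)
  list(grand_mean = mean(ens$acc), type1_rate = mean(ps < alpha),
       ensemble = ens, bias = null_bias_check(ens))
}

#' Onset-lag recovery study
#'
#' Injects the discriminative pattern at known pre-press lags aligned to
#' the FIR bin grid, runs the group decoding pipeline, estimates the
#' onset as the earliest significant bin (requiring 2 consecutive
#' significant bins), and scores recovery against the true lag.
#'
#' @param n_replicates number of simulated group experiments.
#' @param n_subjects,n_runs group size per replicate.
#' @param lags pre-press onsets (s) cycled over replicates; defaults to
#'   the FIR bin starts spanning -11..-1.
#' @param tolerance_bins allowed |recovered - true| in bins (default 1).
#' @param acq acquisition spec (default: compact 6^3 grid).
#' @param seed master seed.
#' @return list with `results` (per replicate: lag, true_bin, recovered,
#'   hit) and `success_rate`.
#' @export
onset_recovery_experiment <- function(n_replicates = 10, n_subjects = 14,
                                      n_runs = 6,
                                      lags = seq(-11, -1, by = 2),
                                      tolerance_bins = 1,
                                      acq = acq_spec(voxel_grid =
                                                       c(6L, 6L, 6L)),
                                      seed = 1) {
  grid <- fir_grid()
  seeds <- derive_seeds(seed, n_replicates)
  res <- do.call(rbind, lapply(seq_len(n_replicates), function(rep) {
    lag <- lags[(rep - 1) %% length(lags) + 1]
    group <- simulate_group(
      n_subjects, n_runs, acq, seed = seeds[rep],
      signal_args = list(onset_lag_seconds = lag,
                         signal_duration_seconds = abs(lag) + 10))
    bs <- lapply(group, function(su)
      fir_beta_series(su$runs, grid, 128, voxels = su$signal$region))
    sig <- curve_significance(group_decode_curve(bs))
    rec <- earliest_significant_bin(sig)
    true_bin <- grid$bin_times[findInterval(lag, grid$bin_times)]
    data.frame(lag = lag, true_bin = true_bin, recovered = rec,
               hit = !is.na(rec) &&
                 abs(rec - true_bin) <= tolerance_bins * grid$bin_width)
  }))
  list(results = res, success_rate = mean(res$hit))
}

#' Perception-to-imagery generalization specificity study
#'
#' Sweeps the overlap between perception and imagery patterns and
#' measures cross-decoding accuracy (classifier trained on perception
#' block betas, tested on imagery FIR betas averaged over the
#' signal-carrying bins). Orthogonal patterns should decode at chance;
#' accuracy should rise monotonically with overlap.
#'
#' @param n_replicates simulated subjects per overlap level.
#' @param overlaps cosine-similarity levels (default 0, 0.5, 1).
#' @param n_perception_runs,n_imagery_runs runs per subject.
#' @param acq acquisition spec for imagery runs; perception runs use the
#'   same grid with 180-s length.
#' @param seed master seed.
#' @return list with `accuracy` (replicates x overlaps matrix of mean
#'   signal-bin accuracies) and `means`.
#' @export
generalization_overlap_experiment <- function(n_replicates = 50,
                                              overlaps = c(0, 0.5, 1),
                                              n_perception_runs = 3,
                                              n_imagery_runs = 5,
                                              acq = acq_spec(voxel_grid =
                                                               c(6L, 6L, 6L)),
                                              seed = 1) {
  acq_perc <- acq_spec(tr_seconds = acq$tr, voxel_grid = acq$dim,
                       run_length_seconds = 180)
  grid <- fir_grid()
  seeds <- derive_seeds(seed, n_replicates)
  signal_bins <- which(grid$bin_times >= -5)
  acc <- sapply(overlaps, function(ov) {
    vapply(seq_len(n_replicates), function(rep) {
      sig <- random_signal_spec(acq, seed = seeds[rep] + round(ov * 7),
                                perception_overlap = ov)
      perc <- simulate_subject_perception(acq_perc, sig,
                                          n_runs = n_perception_runs,
                                          seed = seeds[rep] + 1)
      imag <- simulate_subject_imagery(acq, sig,
                                       n_runs = n_imagery_runs,
                                       seed = seeds[rep] + 2)
      train <- pool_samples(lapply(perc, block_beta_samples,
                                   voxels = sig$region))
      bs <- fir_beta_series(imag, grid, 128, voxels = sig$region)
      mean(cross_decode(train, bs)$accuracy[signal_bins])
    }, numeric(1))
  })
  colnames(acc) <- paste0("overlap_", overlaps)
  list(accuracy = acc, means = colMeans(acc))
}

#' Spillover (N-1) control validity study
#'
#' Simulates groups with and without trial-to-trial pattern carryover and
#' runs the N-1 relabelled decoding. The current trial's own pattern
#' starts at the press (no predictive component), so any pre-press
#' decodability under N-1 labels can only reflect carryover -- the exact
#' logic of the published control. Without carryover the N-1 analysis
#' must sit at chance; with strong carryover it must find the previous
#' trial's pattern before the press.
#'
#' @param n_subjects subjects per condition.
#' @param n_runs imagery runs per subject.
#' @param carryovers carryover fractions to test (default 0 and 0.8).
#' @param acq acquisition spec.
#' @param seed master seed.
#' @return list per carryover level: per-subject mean accuracy over the
#'   pre-press bins (-13..-1 s, the span of the lingering pattern), the
#'   group mean, and the group test.
#' @export
spillover_experiment <- function(n_subjects = 16, n_runs = 5,
                                 carryovers = c(0, 0.8),
                                 acq = acq_spec(voxel_grid = c(6L, 6L, 6L)),
                                 seed = 1) {
  grid <- fir_grid()
  peri <- which(grid$bin_times <= -1)  # all pre-press bins
  out <- lapply(carryovers, function(cf) {
    group <- simulate_group(n_subjects, n_runs, acq, seed = seed + cf * 100,
                            signal_args = list(carryover_fraction = cf,
                                               onset_lag_seconds = 0,
                                               signal_duration_seconds = 10))
    subj_acc <- vapply(group, function(su) {
      shifted <- lapply(su$runs, function(r) spillover_shift(r$events))
      bs <- fir_beta_series(su$runs, grid, 128, voxels = su$signal$region,
                            events_list = shifted)
      mean(decode_curve(bs)$accuracy[peri])
    }, numeric(1))
    list(carryover = cf, subject_accuracy = subj_acc,
         mean = mean(subj_acc), test = group_accuracy_test(subj_acc))
  })
  names(out) <- paste0("carryover_", carryovers)
  out
}

# Draw null subject-by-bin decoding accuracies with leave-one-run-out
# granularity: per fold, `n_test` test samples at chance.
draw_null_accuracies <- function(n, n_folds = 6, n_test = 2) {
  matrix(100 * rbinom(n * n_folds, n_test, 0.5) / n_test,
         ncol = n_folds) |> rowMeans()
}

#' Family-wise error calibration of the counting test
#'
#' Monte-Carlo calibration of [fwer_count_pvalue()] under the global
#' null: each simulated experiment draws fold-granular chance-level
#' accuracies for the observed group and for every null-ensemble
#' iteration, applies the pointwise group test, and records whether the
#' familywise p-value rejects. Operating at the accuracy level keeps 500
#' experiments x 200 ensembles tractable while exercising the counting
#' rule exactly as the pipeline applies it.
#'
#' @param n_experiments simulated experiments (default 500).
#' @param n_subjects,n_bins,n_folds,n_test group and granularity shape.
#' @param n_iter ensemble iterations per experiment (default 200).
#' @param alpha nominal familywise level (default 0.05).
#' @param alpha_pointwise pointwise level inside the count.
#' @param seed master seed.
#' @return list with `fp_rate` and the vector of familywise p-values.
#' @export
fwer_calibration_experiment <- function(n_experiments = 500,
                                        n_subjects = 10, n_bins = 14,
                                        n_folds = 6, n_test = 2,
                                        n_iter = 200, alpha = 0.05,
                                        alpha_pointwise = 0.05,
                                        seed = 1) {
  with_seed(seed, {
    ps <- vapply(seq_len(n_experiments), function(e) {
      obs <- matrix(draw_null_accuracies(n_subjects * n_bins, n_folds,
                                         n_test), n_subjects, n_bins)
      obs_p <- pointwise_pvalues(array(obs, c(1, dim(obs))))
      sacc <- array(draw_null_accuracies(n_iter * n_subjects * n_bins,
                                         n_folds, n_test),
                    c(n_iter, n_subjects, n_bins))
      ens <- structure(list(acc = apply(sacc, c(1, 3), mean),
                            subject_acc = sacc, n_iter = n_iter,
                            bin_times = seq_len(n_bins)),
                       class = "null_ensemble")
      fwer_count_pvalue(obs_p < alpha_pointwise, ens, alpha_pointwise)$p
    }, numeric(1))
    list(fp_rate = mean(ps <= alpha), pvalues = ps)
  })
}

#' Retinotopic phase-recovery study
#'
#' Simulates voxels with known preferred phases, a unit-amplitude
#' periodic response (the strong signal regime typical of phase-encoded
#' mapping) and AR(1)+drift noise, plus silent voxels; recovers phase and
#' SNR with [fft_phase_snr()], thresholds at SNR 2, and reports the mean
#' absolute circular phase error over passing responsive voxels and the
#' silent-voxel exclusion rate.
#'
#' @param n_voxels responsive voxels (default 1000).
#' @param n_silent additional amplitude-0 voxels (default 200).
#' @param white_sd,ar1 noise parameters for the mapping run.
#' @param seed master seed.
#' @return list with `mean_abs_error_rad`, `pass_fraction`,
#'   `silent_excluded_fraction`, `phase_map`, `truth`.
#' @export
retinotopy_phase_experiment <- function(n_voxels = 1000, n_silent = 200,
                                        white_sd = 1, ar1 = 0.3,
                                        seed = 1) {
  nv <- n_voxels + n_silent
  side <- ceiling(nv^(1 / 3))
  acq <- acq_spec(voxel_grid = c(side, side, side),
                  run_length_seconds = 600)
  with_seed(seed, {
    phase <- runif(n_voxels(acq), 0, 2 * pi)
    amp <- c(rep(1, n_voxels), rep(0, n_voxels(acq) - n_voxels))
    run <- simulate_retinotopy_run(
      acq, cycles = 20, phase_map = phase, snr_amplitude = amp,
      noise = noise_spec(white_sd = white_sd, ar1_coefficient = ar1),
      seed = seed + 1)
    pm <- threshold_phase_map(fft_phase_snr(run, acq$tr, 20 / 600))
    resp <- seq_len(n_voxels)
    silent <- n_voxels + seq_len(n_silent)
    pass <- which(pm$mask[resp])
    err <- abs(circ_diff(pm$phase[pass], phase[pass]))
    list(mean_abs_error_rad = mean(err),
         pass_fraction = length(pass) / n_voxels,
         silent_excluded_fraction = mean(!pm$mask[silent]),
         phase_map = pm, truth = list(phase = phase, amplitude = amp))
  })
}

# Wrapped difference of two angles into (-pi, pi].
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Future-vividness decoding study
#'
#' Sweeps the coupling between trial amplitude and reported vividness and
#' decodes high vs low vividness from per-trial pre-press (-10..0 s)
#' window betas. At zero coupling decoding must be at chance; accuracy
#' should increase with coupling strength.
#'
#' @param couplings amplitude-vividness coupling levels.
#' @param n_subjects simulated subjects per level.
#' @param n_runs imagery runs per subject.
#' @param acq acquisition spec.
#' @param seed master seed.
#' @return list with `accuracy` (subjects x couplings), `means`, `tests`
#'   (group test vs chance per level).
#' @export
future_vividness_experiment <- function(couplings = c(0, 0.5, 1),
                                        n_subjects = 20, n_runs = 6,
                                        acq = acq_spec(voxel_grid =
                                                         c(6L, 6L, 6L)),
                                        seed = 1) {
  seeds <- derive_seeds(seed, n_subjects)
  acc <- sapply(couplings, function(cp) {
    vapply(seq_len(n_subjects), function(s) {
      sig <- random_signal_spec(acq, seed = seeds[s])
      runs <- simulate_subject_imagery(
        acq, sig, policy = choice_policy(vividness_coupling = cp),
        n_runs = n_runs, seed = seeds[s] + round(100 * cp) + 1)
      samples <- lapply(runs, function(r) {
        ev <- vividness_partition(r$events)
        window_beta_samples(r, c(-10, 0), per_trial = TRUE,
                            label_by = "viv_class", voxels = sig$region,
                            events = ev)
      })
      tryCatch(
        suppressWarnings(decode_future_vividness(samples,
                                                 seed = seeds[s] + 7)),
        error = function(e) NA_real_)
    }, numeric(1))
  })
  colnames(acc) <- paste0("coupling_", couplings)
  tests <- apply(acc, 2, function(v)
    group_accuracy_test(v[is.finite(v)]))
  list(accuracy = acc, means = colMeans(acc, na.rm = TRUE),
       tests = tests)
}
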