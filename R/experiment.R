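# The end-to-end driver: simulate a group, estimate beta series, decode,
# run the permutation inference, and write a reproducible result bundle.

config_objects <- function(config) {
  acq <- do.call(acq_spec, config$acquisition)
  noise <- do.call(noise_spec, config$noise)
  policy <- do.call(choice_policy, config$policy)
  grid <- do.call(fir_grid, config$glm$fir)
  list(acq = acq, noise = noise, policy = policy, grid = grid)
}

#' Simulate one subject's imagery session
#'
#' @param acq,signal,noise,policy module specifications.
#' @param n_runs number of imagery runs.
#' @param seed subject-level seed; per-run seeds are derived from it.
#' @return list of `sim_run`s.
#' @export
simulate_subject_imagery <- function(acq, signal, noise = noise_spec(),
                                     policy = choice_policy(),
                                     n_runs = 7, seed = NULL) {
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), n_runs)
  lapply(seeds, function(s)
    simulate_imagery_run(acq, signal, noise, policy, seed = s))
}

#' Simulate a group of subjects
#'
#' Each subject gets their own voxel patterns (drawn from a
#' subject-derived seed) on a common signal region, mirroring
#' within-subject decoding on a shared grid.
#'
#' @param n_subjects number of subjects.
#' @param n_runs imagery runs per subject.
#' @param acq,noise,policy shared specifications.
#' @param seed master seed.
#' @param signal_args arguments passed to [random_signal_spec()].
#' @return list per subject of list(runs, signal).
#' @export
simulate_group <- function(n_subjects, n_runs, acq,
                           noise = noise_spec(),
                           policy = choice_policy(), seed = 1,
                           signal_args = list()) {
  seeds <- derive_seeds(seed, n_subjects)
  lapply(seeds, function(s) {
    signal <- do.call(random_signal_spec,
                      c(list(acq = acq, seed = s), signal_args))
    list(runs = simulate_subject_imagery(acq, signal, noise, policy,
                                         n_runs, seed = s + 1),
         signal = signal)
  })
}

#' Pointwise group significance of a decoding curve
#'
#' @param group_curve data.frame from [group_decode_curve()].
#' @param alpha pointwise level.
#' @return data.frame per bin: bin_time, mean accuracy, t, p, significant.
#' @export
curve_significance <- function(group_curve, alpha = 0.05) {
  bins <- sort(unique(group_curve$bin_time))
  out <- do.call(rbind, lapply(bins, function(b) {
    a <- group_curve$accuracy[group_curve$bin_time == b]
    if (length(a) < 3)   # too few subjects for group inference
      return(data.frame(bin_time = b, accuracy = mean(a), t = NA_real_,
                        p = NA_real_))
    gt <- group_accuracy_test(a)
    data.frame(bin_time = b, accuracy = gt$mean, t = gt$t, p = gt$p)
  }))
  out$significant <- !is.na(out$p) & out$p < alpha
  out
}

#' Earliest significant bin of a group decoding curve
#'
#' Onset latency estimate: the start time of the earliest bin that opens
#' a run of at least `consecutive` pointwise-significant bins. Requiring
#' consecutive bins guards the estimate against isolated false positives
#' among the many pre-decision bins.
#'
#' @param sig data.frame from [curve_significance()].
#' @param consecutive required run length (default 2).
#' @return bin start time in seconds, or `NA` if no such run exists.
#' @export
earliest_significant_bin <- function(sig, consecutive = 2) {
  s <- sig$significant
  n <- length(s)
  for (i in seq_len(n - consecutive + 1))
    if (all(s[i:(i + consecutive - 1)])) return(sig$bin_time[i])
  NA_real_
}

#' Run the full experiment described by a configuration
#'
#' Simulates the group, fits FIR beta series on the signal region ROI,
#' computes the group decoding curve with pointwise tests, the univariate
#' ROI contrast control, the within-run label-shuffle permutation null
#' with percentile band, family-wise error counting test and bias check.
#' With an output directory, writes tidy TSVs plus a manifest with MD5
#' hashes; outputs are staged and moved into place only on success, so a
#' failed run never leaves partial results mixed with complete ones.
#' Re-running with the same configuration reproduces the bundle.
#'
#' @param config list from [default_config()] (possibly edited).
#' @param out_dir optional output directory.
#' @return result list (invisibly when writing to disk).
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL) {
  obj <- config_objects(config)
  group <- simulate_group(config$n_subjects, config$n_runs, obj$acq,
                          obj$noise, obj$policy, seed = config$seed,
                          signal_args = list(
                            side = config$signal$region_side,
                            onset_lag_seconds = config$signal$onset_lag_seconds,
                            signal_duration_seconds =
                              config$signal$signal_duration_seconds,
                            amplitude = config$signal$amplitude,
                            amplitude_sd = config$signal$amplitude_sd,
                            carryover_fraction =
                              config$signal$carryover_fraction,
                            perception_overlap =
                              config$signal$perception_overlap))
  cutoff <- config$glm$highpass_cutoff_seconds
  cost <- config$decoding$svm_cost
  bs_list <- lapply(group, function(su)
    fir_beta_series(su$runs, obj$grid, cutoff, voxels = su$signal$region))
  curve <- group_decode_curve(bs_list, cost)
  sig <- curve_significance(curve, config$stats$alpha_pointwise)
  contrast <- mean_signal_contrast(bs_list, seq_along(group[[1]]$signal$region))
  caches <- lapply(group, function(su)
    lapply(su$runs, fir_permutation_cache, grid = obj$grid,
           cutoff_seconds = cutoff, voxels = su$signal$region))
  ens <- permutation_null(caches, n_iter = config$stats$n_permutations,
                          seed = config$seed + 1L, cost = cost)
  res <- list(
    config = config,
    curve = curve, significance = sig, contrast = contrast,
    onset_seconds = earliest_significant_bin(sig),
    null_band = percentile_interval(ens),
    fwer = fwer_count_pvalue(sig$significant, ens,
                             config$stats$alpha_pointwise),
    null_bias = null_bias_check(ens))
  if (is.null(out_dir)) return(res)
  write_result_bundle(res, out_dir)
  invisible(res)
}

write_result_bundle <- function(res, out_dir) {
  stage <- tempfile("firmvpa_stage_")
  dir.create(stage, recursive = TRUE)
  tsv <- function(df, name) {
    p <- file.path(stage, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  tsv(res$curve, "decoding_curve.tsv")
  tsv(res$significance, "curve_significance.tsv")
  tsv(res$contrast, "univariate_contrast.tsv")
  tsv(res$null_band, "null_percentile_band.tsv")
  summary <- list(onset_seconds = res$onset_seconds,
                  fwer_p = res$fwer$p,
                  fwer_observed_count = res$fwer$observed_count,
                  null_grand_mean = res$null_bias$grand_mean,
                  null_biased = res$null_bias$biased)
  jsonlite::write_json(summary, file.path(stage, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_config(res$config, file.path(stage, "config.json"))
  files <- list.files(stage)
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(stage, files))))
  write.table(manifest, file.path(stage, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (f in list.files(stage))
    file.copy(file.path(stage, f), file.path(out_dir, f), overwrite = TRUE)
  unlink(stage, recursive = TRUE)
  invisible(out_dir)
}

#' Simulate one subject's perception session
#'
#' @param acq an [acq_spec()]; the conventional perception run is 180 s.
#' @param signal,noise specifications shared with the imagery runs.
#' @param n_runs number of perception runs (default 3).
#' @param seed subject-level seed.
#' @return list of perception `sim_run`s.
#' @export
simulate_subject_perception <- function(acq, signal,
                                        noise = noise_spec(), n_runs = 3,
                                        seed = NULL) {
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), n_runs)
  lapply(seeds, function(s)
    simulate_perception_run(acq, signal, noise, seed = s))
}
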