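# File interfaces: NIfTI volumes, BIDS-style event tables, tidy results
# and JSON configuration. Conventions used throughout: voxel indices are
# reported 1-based in R and written 0-based where a format requires it;
# event onsets are seconds from the first retained volume; all intervals
# are half-open.

#' Write a simulated run to disk
#'
#' Writes the BOLD volume as NIfTI (isotropic affine from the acquisition
#' spec), the event table as a BIDS-style TSV and the ground truth as a
#' sidecar JSON.
#'
#' @param run a `sim_run`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return invisibly, the named vector of file paths written.
#' @export
write_run <- function(run, dir, prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- RNifti::asNifti(run$bold)
  RNifti::pixdim(img) <- c(rep(run$acq$voxel_mm, 3), run$acq$tr)
  paths <- c(bold = file.path(dir, paste0(prefix, "_bold.nii.gz")),
             events = file.path(dir, paste0(prefix, "_events.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.json")))
  RNifti::writeNifti(img, paths["bold"])
  if (!is.null(run$events)) {
    ev <- if (run$type == "imagery") events_to_bids(run$events) else
      run$events
    write.table(ev, paths["events"], sep = "\t", quote = FALSE,
                row.names = FALSE, na = "n/a")
  }
  truth <- run$truth
  truth$convolved <- NULL  # volumes carry the realised signal already
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(paths)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file.
#' @return numeric array with a `pixdim` attribute.
#' @export
read_bold <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' Convert a trial event table to BIDS-style long format
#'
#' Each trial expands to cue, imagery_<label> and rest rows with columns
#' onset, duration, trial_type, response_time, vividness.
#'
#' @param events trial table from [simulate_imagery_run()].
#' @param imagery_seconds,rest_seconds epoch durations.
#' @return BIDS-style data.frame ordered by onset.
#' @export
events_to_bids <- function(events, imagery_seconds = 10,
                           rest_seconds = 10) {
  rows <- lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    data.frame(
      onset = c(e$cue_onset, e$press_time,
                e$press_time + imagery_seconds),
      duration = c(2, imagery_seconds, rest_seconds),
      trial_type = c("cue", paste0("imagery_", e$chosen_label), "rest"),
      response_time = c(e$decision_time, NA, NA),
      vividness = c(NA, e$vividness, NA))
  })
  out <- do.call(rbind, rows)
  out[order(out$onset), ]
}

#' Read and validate a BIDS-style events TSV
#'
#' @param path TSV file with columns onset, duration, trial_type,
#'   response_time, vividness.
#' @param run_length_seconds if given, onsets beyond the run are an error.
#' @return data.frame of events.
#' @export
read_events <- function(path, run_length_seconds = NULL) {
  ev <- read.delim(path, na.strings = c("n/a", "NA"))
  required <- c("onset", "duration", "trial_type", "response_time",
                "vividness")
  missing <- setdiff(required, names(ev))
  if (length(missing))
    stop("events file lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (is.unsorted(ev$onset)) stop("event onsets must be non-decreasing")
  if (!is.null(run_length_seconds) &&
      any(ev$onset > run_length_seconds))
    stop("event onset beyond the end of the run")
  ev
}

#' Reconstruct a trial table from BIDS-style events
#'
#' @param bids data.frame from [read_events()].
#' @return trial table with cue_onset, decision_time, press_time,
#'   chosen_label, reported_label, vividness.
#' @export
bids_to_events <- function(bids) {
  img <- bids[grepl("^imagery_", bids$trial_type), , drop = FALSE]
  cue <- bids[bids$trial_type == "cue", , drop = FALSE]
  if (nrow(img) == 0 || nrow(img) != nrow(cue))
    stop("events table does not pair one cue with one imagery row per trial")
  lab <- sub("^imagery_", "", img$trial_type)
  data.frame(trial_index = seq_len(nrow(img)), cue_onset = cue$onset,
             decision_time = cue$response_time, press_time = img$onset,
             chosen_label = lab, reported_label = lab,
             vividness = img$vividness)
}

#' Default experiment configuration
#'
#' A fully serialisable list mirroring the module parameters: acquisition,
#' signal, noise, FIR grid, decoding and inference settings plus the
#' master seed. Sizes default to a small smoke-test scale.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    n_subjects = 2L, n_runs = 3L,
    acquisition = list(tr_seconds = 2, voxel_grid = c(12L, 12L, 12L),
                       run_length_seconds = 300,
                       discard_initial_volumes = 4L,
                       lead_in_fixation_seconds = 10, voxel_size_mm = 3),
    signal = list(region_side = 4L, onset_lag_seconds = -11,
                  signal_duration_seconds = 21, amplitude = 1,
                  amplitude_sd = 0.3, carryover_fraction = 0,
                  perception_overlap = 1),
    noise = list(white_sd = 5.5, ar1_coefficient = 0.3,
                 drift_amplitude = 3, drift_period_seconds = 256),
    policy = list(p_switch = 0.586, decision_mean_seconds = 5.48,
                  decision_shape = 2, max_decision_seconds = 20,
                  vividness_coupling = 0.5),
    glm = list(highpass_cutoff_seconds = 128,
               fir = list(window_start = -13, n_bins = 14L, bin_width = 2)),
    decoding = list(svm_cost = 1),
    stats = list(n_permutations = 100L, alpha_pointwise = 0.05))
}

#' Write / read a configuration as JSON
#'
#' @param config a configuration list.
#' @param path JSON file path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
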