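# High-pass filtering and FIR / boxcar response estimation. The beta
# series produced here (one estimate per run x condition x time bin x
# voxel) are the unit of all downstream decoding.

#' Discrete-cosine high-pass filter
#'
#' Projects out slow components with period longer than `cutoff_seconds`
#' using an orthonormal discrete-cosine basis (the standard fMRI drift
#' model); the temporal mean is retained. The number of basis functions is
#' `floor(2 * T * tr / cutoff)` where `T` is the number of volumes.
#'
#' @param series numeric vector or time-by-voxel matrix.
#' @param cutoff_seconds period cutoff in seconds (default 128).
#' @param tr sampling interval in seconds.
#' @return filtered series, same shape as the input.
#' @export
dct_highpass <- function(series, cutoff_seconds = 128, tr = 2) {
  x <- as.matrix(series)
  nt <- nrow(x)
  if (nt < 8) stop("need at least 8 time points")
  if (cutoff_seconds <= 2 * tr)
    stop("cutoff must exceed twice the sampling interval")
  k <- floor(2 * nt * tr / cutoff_seconds)
  if (k >= 1) {
    d <- dct_basis(nt, k)
    x <- x - d %*% crossprod(d, x)
  }
  if (is.vector(series)) drop(x) else x
}

# Orthonormal DCT-II basis, columns 1..k (DC excluded).
dct_basis <- function(nt, k) {
  tt <- seq_len(nt)
  sapply(seq_len(k), function(j)
    sqrt(2 / nt) * cos(pi * (2 * tt - 1) * j / (2 * nt)))
}

#' Build an FIR design matrix for self-paced events
#'
#' One indicator column per (label, bin): the column for label L, bin j is
#' the number of events with that label whose bin-j interval (anchored at
#' the press, see [fir_grid()]) contains the volume's acquisition onset.
#' Overlapping bins from consecutive same-label trials sum. Columns for
#' both labels are always present; columns with no supporting volumes are
#' flagged inestimable rather than dropped.
#'
#' @param events data.frame with `press_time` and `chosen_label`.
#' @param grid a [fir_grid()].
#' @param n_volumes number of volumes in the run.
#' @param tr repetition time (s).
#' @param labels the label set (default c("A", "B")).
#' @return list with `matrix` (volumes x columns), `columns` (data.frame
#'   label, bin, bin_time) and logical `estimable`.
#' @export
build_fir_design <- function(events, grid, n_volumes, tr = 2,
                             labels = c("A", "B")) {
  if (nrow(events) == 0) stop("no events")
  run_end <- n_volumes * tr
  if (any(events$press_time < 0 | events$press_time > run_end))
    stop("press times must lie within the run")
  tv <- (seq_len(n_volumes) - 1) * tr
  cols <- expand.grid(bin = seq_len(grid$n_bins), label = labels,
                      stringsAsFactors = FALSE)[, c("label", "bin")]
  x <- matrix(0, n_volumes, nrow(cols))
  for (e in seq_len(nrow(events))) {
    li <- match(events$chosen_label[e], labels)
    if (is.na(li)) stop("event label outside the label set")
    rel <- tv - events$press_time[e]
    bin <- floor((rel - grid$window_start) / grid$bin_width) + 1
    ok <- bin >= 1 & bin <= grid$n_bins
    ci <- (li - 1) * grid$n_bins + bin[ok]
    for (j in seq_along(ci)) x[which(ok)[j], ci[j]] <- x[which(ok)[j], ci[j]] + 1
  }
  cols$bin_time <- grid$bin_times[cols$bin]
  list(matrix = x, columns = cols, estimable = colSums(abs(x)) > 0)
}

# Per-trial FIR design: one column per (trial, bin). Aggregating its
# columns by trial label reproduces build_fir_design exactly; used to
# cache cross-products for label permutations.
build_trial_fir_design <- function(events, grid, n_volumes, tr = 2) {
  n <- nrow(events)
  tv <- (seq_len(n_volumes) - 1) * tr
  x <- matrix(0, n_volumes, n * grid$n_bins)
  for (e in seq_len(n)) {
    rel <- tv - events$press_time[e]
    bin <- floor((rel - grid$window_start) / grid$bin_width) + 1
    ok <- bin >= 1 & bin <= grid$n_bins
    x[cbind(which(ok), (e - 1) * grid$n_bins + bin[ok])] <- 1
  }
  x
}

# 0/1 aggregation matrix mapping (trial, bin) columns to (label, bin)
# columns for a given label assignment.
label_aggregation <- function(trial_labels, n_bins, labels = c("A", "B")) {
  n <- length(trial_labels)
  a <- matrix(0, n * n_bins, length(labels) * n_bins)
  for (e in seq_len(n)) {
    li <- match(trial_labels[e], labels)
    rows <- (e - 1) * n_bins + seq_len(n_bins)
    a[cbind(rows, (li - 1) * n_bins + seq_len(n_bins))] <- 1
  }
  a
}

#' Build a boxcar (1st-order FIR) design for blocks or windows
#'
#' A volume belongs to a block if its acquisition onset lies in
#' `[onset, onset + duration)`. With `per_block = FALSE` all blocks
#' sharing a label are pooled into one column per label; with
#' `per_block = TRUE` each block gets its own column (used e.g. for
#' per-trial window betas).
#'
#' @param blocks data.frame with `onset`, `duration`, `label`.
#' @param n_volumes number of volumes.
#' @param tr repetition time (s).
#' @param per_block one column per block instead of per label.
#' @return as [build_fir_design()]; `columns` has `label` (and `block`).
#' @export
build_block_design <- function(blocks, n_volumes, tr = 2,
                               per_block = FALSE) {
  if (nrow(blocks) == 0) stop("no blocks")
  if (any(blocks$duration < 0)) stop("negative block duration")
  run_end <- n_volumes * tr
  if (any(blocks$onset + blocks$duration > run_end + 1e-9))
    warning("block extends past run end; truncated")
  tv <- (seq_len(n_volumes) - 1) * tr
  if (per_block) {
    x <- sapply(seq_len(nrow(blocks)), function(b)
      as.numeric(tv >= blocks$onset[b] & tv < blocks$onset[b] +
                   blocks$duration[b]))
    cols <- data.frame(label = blocks$label, block = seq_len(nrow(blocks)))
  } else {
    labels <- unique(blocks$label)
    x <- sapply(labels, function(l) {
      ind <- rep(0, n_volumes)
      for (b in which(blocks$label == l))
        ind <- ind + (tv >= blocks$onset[b] &
                        tv < blocks$onset[b] + blocks$duration[b])
      pmin(ind, 1)
    })
    cols <- data.frame(label = labels)
  }
  x <- matrix(x, nrow = n_volumes)
  list(matrix = x, columns = cols, estimable = colSums(abs(x)) > 0)
}

#' Estimate betas by filtered ordinary least squares
#'
#' Both the data and the design columns are high-pass filtered with the
#' same cutoff (residual-forming-matrix equivalence), a run constant is
#' appended, and betas are estimated per voxel by OLS. Columns flagged
#' inestimable, or aliased by rank deficiency, yield `NA` betas -- never
#' silent zeros.
#'
#' @param data time-by-voxel matrix (or a `sim_run`).
#' @param design a design list from [build_fir_design()] or
#'   [build_block_design()].
#' @param cutoff_seconds high-pass cutoff; `NULL` disables filtering.
#' @param tr repetition time (s).
#' @return list with `betas` (columns x voxels), `columns`, `estimable`.
#' @export
fit_betas <- function(data, design, cutoff_seconds = 128, tr = 2) {
  y <- if (inherits(data, "sim_run")) bold_matrix(data) else as.matrix(data)
  x <- design$matrix
  if (all(x == 0)) stop("all-zero design")
  stopifnot(nrow(x) == nrow(y))
  if (!is.null(cutoff_seconds)) {
    y <- dct_highpass(y, cutoff_seconds, tr)
    x <- dct_highpass(x, cutoff_seconds, tr)
  }
  xc <- cbind(x, 1)
  keep <- c(design$estimable, TRUE)
  fit <- stats::lm.fit(xc[, keep, drop = FALSE], y)
  betas <- matrix(NA_real_, ncol(xc), ncol(y))
  betas[keep, ] <- fit$coefficients            # NA for aliased columns
  betas <- betas[-nrow(betas), , drop = FALSE] # drop run constant
  list(betas = betas, columns = design$columns,
       estimable = design$estimable & rowSums(is.na(betas)) == 0)
}

# ---- cached cross-product machinery -----------------------------------
# For label permutations only the trial -> label assignment changes, so
# the filtered per-trial design cross-products can be computed once per
# run and each permutation's OLS reduces to a small solve. The result is
# algebraically identical to refitting (tested).

#' Precompute filtered cross-products for fast label permutation
#'
#' @param run a `sim_run` (imagery) or time-by-voxel matrix with events.
#' @param grid a [fir_grid()].
#' @param cutoff_seconds high-pass cutoff.
#' @param events event table (defaults to `run$events`).
#' @param voxels optional column subset of the data (e.g. an ROI).
#' @return an opaque cache object for [betas_for_labels()].
#' @export
fir_permutation_cache <- function(run, grid, cutoff_seconds = 128,
                                  events = NULL, voxels = NULL) {
  events <- events %||% run$events
  y <- if (inherits(run, "sim_run")) bold_matrix(run) else as.matrix(run)
  if (!is.null(voxels)) y <- y[, voxels, drop = FALSE]
  tr <- if (inherits(run, "sim_run")) run$acq$tr else
    stop("matrix input requires a sim_run")
  x <- build_trial_fir_design(events, grid, nrow(y), tr)
  if (!is.null(cutoff_seconds)) {
    y <- dct_highpass(y, cutoff_seconds, tr)
    x <- dct_highpass(x, cutoff_seconds, tr)
  }
  xc <- cbind(x, 1)
  list(xtx = crossprod(xc), xty = crossprod(xc, y),
       n_trials = nrow(events), grid = grid,
       labels_obs = events$chosen_label)
}

#' Betas for an arbitrary label assignment from a cache
#'
#' @param cache from [fir_permutation_cache()].
#' @param trial_labels character vector, one label per trial.
#' @param labels the label set.
#' @return list as [fit_betas()] (without the run constant row).
#' @export
betas_for_labels <- function(cache, trial_labels, labels = c("A", "B")) {
  nb <- cache$grid$n_bins
  a <- label_aggregation(trial_labels, nb, labels)
  ac <- rbind(cbind(a, 0), c(rep(0, ncol(a)), 1))  # keep run constant
  m <- crossprod(ac, cache$xtx %*% ac)
  v <- crossprod(ac, cache$xty)
  est <- diag(m) > 1e-12
  betas <- matrix(NA_real_, ncol(ac), ncol(v))
  sol <- tryCatch(solve(m[est, est, drop = FALSE], v[est, , drop = FALSE]),
                  error = function(e) {
                    q <- qr(m[est, est, drop = FALSE])
                    qr.coef(q, v[est, , drop = FALSE])
                  })
  betas[est, ] <- sol
  betas <- betas[-nrow(betas), , drop = FALSE]
  cols <- expand.grid(bin = seq_len(nb), label = labels,
                      stringsAsFactors = FALSE)[, c("label", "bin")]
  cols$bin_time <- cache$grid$bin_times[cols$bin]
  list(betas = betas, columns = cols,
       estimable = est[-length(est)] & rowSums(is.na(betas)) == 0)
}

# ---- beta series over runs --------------------------------------------

#' FIR beta series for one subject
#'
#' Fits the FIR model run by run and returns the per-run
#' label-by-bin-by-voxel beta arrays that all decoding consumes.
#'
#' @param runs list of imagery `sim_run`s (or list(data, events, acq)).
#' @param grid a [fir_grid()].
#' @param cutoff_seconds high-pass cutoff.
#' @param voxels optional voxel (column) subset, e.g. an ROI.
#' @param events_list optional per-run replacement event tables (e.g.
#'   after [spillover_shift()]); `NULL` entries drop the run.
#' @return object of class `beta_series`: list of per-run lists with
#'   `betas` (label x bin x voxel array) and `estimable` (label x bin).
#' @export
fir_beta_series <- function(runs, grid = fir_grid(), cutoff_seconds = 128,
                            voxels = NULL, events_list = NULL) {
  labels <- c("A", "B")
  per_run <- lapply(seq_along(runs), function(r) {
    ev <- if (is.null(events_list)) runs[[r]]$events else events_list[[r]]
    if (is.null(ev) || nrow(ev) == 0) return(NULL)
    y <- bold_matrix(runs[[r]])
    if (!is.null(voxels)) y <- y[, voxels, drop = FALSE]
    d <- build_fir_design(ev, grid, nrow(y), runs[[r]]$acq$tr, labels)
    f <- fit_betas(y, d, cutoff_seconds, runs[[r]]$acq$tr)
    arr <- array(NA_real_, c(2, grid$n_bins, ncol(y)))
    for (li in 1:2) for (b in seq_len(grid$n_bins))
      arr[li, b, ] <- f$betas[(li - 1) * grid$n_bins + b, ]
    est <- matrix(f$estimable, grid$n_bins, 2)
    list(betas = arr, estimable = t(est))
  })
  structure(list(runs = per_run[!vapply(per_run, is.null, TRUE)],
                 grid = grid, labels = labels),
            class = "beta_series")
}

#' Labelled samples for one FIR bin
#'
#' @param bs a `beta_series`.
#' @param bin bin index.
#' @return list per run of list(x = samples-by-voxel matrix, y = labels);
#'   inestimable samples are dropped.
#' @export
beta_samples_for_bin <- function(bs, bin) {
  lapply(bs$runs, function(r) {
    ok <- r$estimable[, bin] & apply(!is.na(r$betas[, bin, , drop = FALSE]),
                                     1, all)
    list(x = matrix(r$betas[ok, bin, ], nrow = sum(ok)),
         y = bs$labels[ok])
  })
}

#' Difference of ROI-mean responses between labels (univariate control)
#'
#' The univariate counterpart to decoding: per subject, the mean over ROI
#' voxels of `beta_A - beta_B` per bin, averaged over runs, with a
#' two-sided one-sample group t-test per bin (uncorrected).
#'
#' @param bs_list list of `beta_series`, one per subject.
#' @param roi voxel indices within the beta-series voxel set.
#' @return data.frame with bin_time, mean contrast, t and p per bin.
#' @export
mean_signal_contrast <- function(bs_list, roi) {
  if (length(roi) == 0) stop("empty ROI")
  grid <- bs_list[[1]]$grid
  subj <- vapply(bs_list, function(bs) {
    per_bin <- vapply(seq_len(grid$n_bins), function(b) {
      d <- vapply(bs$runs, function(r)
        mean(r$betas[1, b, roi]) - mean(r$betas[2, b, roi]), numeric(1))
      mean(d, na.rm = TRUE)
    }, numeric(1))
    per_bin
  }, numeric(grid$n_bins))
  subj <- matrix(subj, nrow = grid$n_bins)
  out <- data.frame(bin_time = grid$bin_times,
                    contrast = rowMeans(subj))
  tests <- apply(subj, 1, function(v) {
    if (length(v) < 2 || is.na(sd(v)) || sd(v) == 0) return(c(NA, NA))
    tt <- t.test(v)
    c(tt$statistic, tt$p.value)
  })
  out$t <- tests[1, ]
  out$p <- tests[2, ]
  out
}

#' Beta samples from perception blocks
#'
#' Fits the boxcar model to one perception run and returns labelled
#' samples for classifier training: by default one beta pattern per block
#' (6 samples per 3-minute run), the higher-sample-count reading of
#' block-design training data; `per_block = FALSE` pools the blocks of a
#' label into a single regressor (2 samples per run).
#'
#' @param run a perception `sim_run`.
#' @param cutoff_seconds high-pass cutoff.
#' @param per_block one sample per block (default) or per label.
#' @param voxels optional voxel subset.
#' @return list(x = samples-by-voxel matrix, y = labels).
#' @export
block_beta_samples <- function(run, cutoff_seconds = 128,
                               per_block = TRUE, voxels = NULL) {
  y <- bold_matrix(run)
  if (!is.null(voxels)) y <- y[, voxels, drop = FALSE]
  d <- build_block_design(run$events, nrow(y), run$acq$tr,
                          per_block = per_block)
  f <- fit_betas(y, d, cutoff_seconds, run$acq$tr)
  ok <- f$estimable
  list(x = f$betas[ok, , drop = FALSE], y = f$columns$label[ok])
}

#' Beta samples from a press-anchored window
#'
#' Fits 1st-order (boxcar) regressors spanning a window relative to each
#' press, e.g. the pre-decision window -10..0 s or the post-decision
#' window 0..10 s. With `per_trial = FALSE` trials sharing a label pool
#' into one regressor per run (2 samples); with `per_trial = TRUE` each
#' trial gets its own beta pattern, labelled by `label_by`.
#'
#' @param run an imagery `sim_run`.
#' @param window numeric length-2, seconds relative to the press.
#' @param cutoff_seconds high-pass cutoff.
#' @param per_trial per-trial betas instead of per-label betas.
#' @param label_by column of the event table used as the sample label
#'   (default "chosen_label"; e.g. "viv_class" after
#'   [vividness_partition()]).
#' @param voxels optional voxel subset.
#' @param events optional replacement event table.
#' @param nuisance_windows list of further press-anchored windows
#'   modelled alongside the target window (their betas are discarded), so
#'   that response in neighbouring epochs is not absorbed by the run
#'   baseline. Default: the complementary half of the -10..+10 s
#'   peri-decision span.
#' @return list(x, y) as [block_beta_samples()].
#' @export
window_beta_samples <- function(run, window = c(-10, 0),
                                cutoff_seconds = 128, per_trial = FALSE,
                                label_by = "chosen_label", voxels = NULL,
                                events = NULL,
                                nuisance_windows = NULL) {
  stopifnot(length(window) == 2, window[2] > window[1])
  if (is.null(nuisance_windows))
    nuisance_windows <- if (isTRUE(all.equal(window, c(-10, 0))))
      list(c(0, 10), c(10, 15)) else if (isTRUE(all.equal(window, c(0, 10))))
        list(c(-10, 0), c(10, 15)) else list()
  ev <- events %||% run$events
  y <- bold_matrix(run)
  if (!is.null(voxels)) y <- y[, voxels, drop = FALSE]
  mk <- function(w, tag) data.frame(
    onset = pmax(0, ev$press_time + w[1]),
    duration = w[2] - w[1],
    label = if (tag == "target") as.character(ev[[label_by]]) else
      paste0(".nuisance_", tag, "_", seq_len(nrow(ev))))
  blocks <- mk(window, "target")
  n_target <- nrow(blocks)
  for (k in seq_along(nuisance_windows))
    blocks <- rbind(blocks, mk(nuisance_windows[[k]], as.character(k)))
  d <- build_block_design(blocks, nrow(y), run$acq$tr,
                          per_block = per_trial)
  if (!per_trial && length(nuisance_windows)) {
    # pooled target columns per label; nuisance stays per trial
    tcols <- d$columns$label %in% unique(as.character(ev[[label_by]]))
  } else tcols <- c(rep(TRUE, n_target),
                    rep(FALSE, nrow(blocks) - n_target))
  f <- fit_betas(y, d, cutoff_seconds, run$acq$tr)
  ok <- f$estimable & tcols
  list(x = f$betas[ok, , drop = FALSE], y = f$columns$label[ok])
}
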