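# Synthetic BOLD generators. All times are seconds on the retained axis
# (second 0 = first kept volume); `discard` burn-in volumes plus extra AR
# warm-up are simulated and dropped so the retained noise is stationary.

FINE_DT <- 0.1  # fine grid for neural -> BOLD convolution (s)

# Convolve a fine-grid neural series with the canonical HRF and sample it
# at volume acquisition times.
convolve_sample <- function(neural, acq) {
  h <- double_gamma_hrf(seq(0, 32, by = FINE_DT))
  full <- convolve(neural, rev(h), type = "open")[seq_along(neural)] * FINE_DT
  idx <- round(volume_times(acq) / FINE_DT) + 1
  full[pmin(idx, length(full))]
}

# Add `value` over the half-open interval [from, to) on the fine grid.
add_boxcar <- function(series, from, to, value, run_length) {
  from <- max(0, from); to <- min(run_length, to)
  if (to <= from) return(series)
  tt <- (seq_along(series) - 1) * FINE_DT
  sel <- tt >= from - 1e-9 & tt < to - 1e-9
  series[sel] <- series[sel] + value
  series
}

# White + AR(1) + sinusoidal drift noise, voxels x volumes.
noise_matrix <- function(acq, noise) {
  nt <- n_volumes(acq); nv <- n_voxels(acq)
  burn <- acq$discard + 50L
  out <- matrix(0, nv, nt)
  if (noise$white_sd > 0) {
    eps <- matrix(rnorm((nt + burn) * nv, sd = noise$white_sd), nt + burn, nv)
    if (noise$ar1 != 0)
      eps <- apply(eps, 2, function(e)
        as.numeric(stats::filter(e, noise$ar1, method = "recursive")))
    out <- t(eps[(burn + 1):(nt + burn), , drop = FALSE])
  }
  if (noise$drift_amplitude > 0) {
    phase <- runif(nv, 0, 2 * pi)
    tt <- volume_times(acq)
    out <- out + noise$drift_amplitude *
      sin(outer(phase, 2 * pi * tt / noise$drift_period, `+`))
  }
  out
}

as_bold_array <- function(mat, acq) {
  array(mat, dim = c(acq$dim, ncol(mat)))
}

#' Extract the time-by-voxel matrix from a simulated run
#'
#' @param run a `sim_run` object.
#' @return numeric matrix, volumes in rows, voxels (x fastest) in columns.
#' @export
bold_matrix <- function(run) {
  d <- dim(run$bold)
  t(matrix(run$bold, prod(d[1:3]), d[4]))
}

draw_decision_times <- function(n, policy) {
  scale <- policy$decision_mean / policy$decision_shape
  dt <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rgamma(1, shape = policy$decision_shape, scale = scale)
      if (x > 0 && x <= policy$max_decision) { dt[i] <- x; break }
    }
  }
  dt
}

vividness_from_amplitude <- function(m, coupling) {
  z <- if (sd(m) > 0) (m - mean(m)) / sd(m) else rep(0, length(m))
  latent <- coupling * z + sqrt(1 - coupling^2) * rnorm(length(m))
  as.integer(cut(latent, c(-Inf, qnorm(c(0.25, 0.5, 0.75)), Inf)))
}

#' Simulate one free-decision imagery run
#'
#' Packs self-paced trials into the run: 10 s of lead-in fixation, then for
#' each trial a 2-s choice prompt, a gamma-distributed decision time
#' (truncated at 20 s), the button press, 10 s of imagery, the report
#' prompts, and a 10-s rest interval. The chosen label's voxel pattern is
#' injected from `press + onset_lag` for `signal_duration` seconds,
#' HRF-convolved and scaled by the trial amplitude; optionally a fraction
#' of the previous trial's pattern is re-injected during the next trial's
#' pre-imagery period (spillover ground truth). Vividness ratings are a
#' monotone binning of the trial amplitude mixed with noise.
#'
#' @param acq an [acq_spec()].
#' @param signal a [signal_spec()].
#' @param noise a [noise_spec()].
#' @param policy a [choice_policy()].
#' @param seed RNG seed (falls back to `noise$seed`).
#' @param question_seconds time taken by the two report prompts
#'   (default 3.7 s, making the expected trial span about 31 s).
#' @return a `sim_run`: list with `bold` (4-D array x,y,z,t), `events`
#'   (one row per trial), `truth` (specs and per-trial ground truth) and
#'   `acq`.
#' @export
simulate_imagery_run <- function(acq, signal, noise = noise_spec(),
                                 policy = choice_policy(), seed = NULL,
                                 question_seconds = 3.7) {
  seed <- seed %||% noise$seed
  with_seed(seed, {
    run_len <- acq$run_length
    trial_tail <- 10 + question_seconds + 10  # imagery + prompts + rest
    if (acq$lead_in + 2 + trial_tail > run_len)
      stop("run too short for a single trial")
    cue <- acq$lead_in
    cues <- press <- dts <- numeric(0)
    repeat {
      dt <- draw_decision_times(1, policy)
      p <- cue + 2 + dt
      if (p + trial_tail > run_len) break
      cues <- c(cues, cue); press <- c(press, p); dts <- c(dts, dt)
      cue <- p + trial_tail
    }
    n <- length(cues)
    labels <- character(n)
    labels[1] <- sample(c("A", "B"), 1)
    if (n > 1) {
      sw <- runif(n - 1) < policy$p_switch
      for (i in 2:n)
        labels[i] <- if (sw[i - 1]) setdiff(c("A", "B"), labels[i - 1]) else
          labels[i - 1]
    }
    m <- pmax(0, 1 + signal$amplitude_sd * rnorm(n))
    viv <- vividness_from_amplitude(m, policy$vividness_coupling)

    fine_len <- ceiling(run_len / FINE_DT)
    neural <- list(A = numeric(fine_len), B = numeric(fine_len),
                   S = numeric(fine_len))
    for (i in seq_len(n)) {
      on <- press[i] + signal$onset_lag
      neural[[labels[i]]] <- add_boxcar(neural[[labels[i]]], on,
                                        on + signal$duration,
                                        signal$amplitude * m[i], run_len)
      # label-independent strength component: pre-volitional buildup
      # from pattern onset to the press, scaled by the trial amplitude
      neural$S <- add_boxcar(neural$S, on, press[i],
                             signal$strength_fraction *
                               signal$amplitude * m[i], run_len)
      if (i > 1 && signal$carryover > 0) {
        # previous trial's pattern lingers from the end of its signal
        # epoch until the current press
        lng_from <- max(0, press[i - 1] + signal$onset_lag + signal$duration)
        neural[[labels[i - 1]]] <- add_boxcar(neural[[labels[i - 1]]],
                                              lng_from, press[i],
                                              signal$carryover *
                                                signal$amplitude * m[i - 1],
                                              run_len)
      }
    }
    sig <- lapply(neural, convolve_sample, acq = acq)
    p_strength <- orthogonal_complements(signal$pattern_A,
                                         signal$pattern_B)[[3]]
    bold <- noise_matrix(acq, noise)
    bold[signal$region, ] <- bold[signal$region, ] +
      outer(signal$pattern_A, sig$A) + outer(signal$pattern_B, sig$B) +
      outer(p_strength, sig$S)

    events <- data.frame(trial_index = seq_len(n), cue_onset = cues,
                         decision_time = dts, press_time = press,
                         chosen_label = labels, reported_label = labels,
                         vividness = viv)
    structure(list(bold = as_bold_array(bold, acq), events = events,
                   truth = list(signal = signal, noise = noise,
                                policy = policy, trial_amplitude = m,
                                convolved = sig, seed = seed),
                   acq = acq, type = "imagery"),
              class = "sim_run")
  })
}

# Deterministic unit vectors orthogonal to the two imagery patterns (and
# to each other): [[1]] and [[2]] dilute perception patterns to a target
# overlap, [[3]] carries the label-independent strength component.
orthogonal_complements <- function(pA, pB) {
  nv <- length(pA)
  stopifnot(nv >= 5)
  basis <- cbind(pA, pB, diag(nv)[, 1:3])
  q <- qr.Q(qr(basis))
  list(q[, 3], q[, 4], q[, 5])
}

#' Simulate one perception block run
#'
#' Alternates 15-s fixation and 15-s stimulation blocks, fixation first
#' (so every run starts with at least 10 s of fixation); a 3-minute run
#' yields 6 stimulation blocks with pseudo-random balanced labels (3 per
#' grating). Block patterns are overlap-blended versions of the imagery
#' patterns: cosine similarity to the corresponding imagery pattern equals
#' `signal$perception_overlap`.
#'
#' @param acq an [acq_spec()]; default run length for perception is 180 s.
#' @param signal a [signal_spec()].
#' @param noise a [noise_spec()].
#' @param seed RNG seed.
#' @return a `sim_run` with `events` holding the block schedule
#'   (onset, duration, label).
#' @export
simulate_perception_run <- function(acq, signal, noise = noise_spec(),
                                    seed = NULL) {
  seed <- seed %||% noise$seed
  with_seed(seed, {
    n_blocks <- floor(acq$run_length / 30)
    if (n_blocks < 1) stop("run too short for one on/off cycle")
    onsets <- 15 + (seq_len(n_blocks) - 1) * 30
    labels <- sample(rep_len(c("A", "B"), n_blocks))
    ov <- signal$perception_overlap
    comp <- orthogonal_complements(signal$pattern_A, signal$pattern_B)
    qA <- ov * signal$pattern_A + sqrt(1 - ov^2) * comp[[1]]
    qB <- ov * signal$pattern_B + sqrt(1 - ov^2) * comp[[2]]

    fine_len <- ceiling(acq$run_length / FINE_DT)
    neural <- list(A = numeric(fine_len), B = numeric(fine_len))
    for (k in seq_len(n_blocks))
      neural[[labels[k]]] <- add_boxcar(neural[[labels[k]]], onsets[k],
                                        onsets[k] + 15, signal$amplitude,
                                        acq$run_length)
    sig <- lapply(neural, convolve_sample, acq = acq)
    bold <- noise_matrix(acq, noise)
    bold[signal$region, ] <- bold[signal$region, ] +
      outer(qA, sig$A) + outer(qB, sig$B)

    events <- data.frame(onset = onsets, duration = 15, label = labels)
    structure(list(bold = as_bold_array(bold, acq), events = events,
                   truth = list(signal = signal, noise = noise,
                                pattern_A = qA, pattern_B = qB,
                                convolved = sig, seed = seed),
                   acq = acq, type = "perception"),
              class = "sim_run")
  })
}

#' Simulate one phase-encoded retinotopy run
#'
#' Each voxel's series is `amplitude * sin(2*pi*f*t + phase)` plus noise,
#' with `f = cycles / run_length`. With the default 20 cycles in a
#' 10-minute run (a double wedge completing 10 rotations stimulates each
#' location twice per rotation) the stimulation frequency is 0.033 Hz.
#'
#' @param acq an [acq_spec()] (default run length 600 s recommended).
#' @param cycles number of stimulation cycles in the run (>= 2).
#' @param phase_map per-voxel preferred phase in radians (default: uniform
#'   random in `[0, 2*pi)`).
#' @param snr_amplitude per-voxel (or scalar) response amplitude.
#' @param noise a [noise_spec()].
#' @param seed RNG seed.
#' @return a `sim_run`; `truth` holds the phase map, amplitude and
#'   stimulation frequency.
#' @export
simulate_retinotopy_run <- function(acq, cycles = 20, phase_map = NULL,
                                    snr_amplitude = 1,
                                    noise = noise_spec(), seed = NULL) {
  stopifnot(cycles >= 2)
  seed <- seed %||% noise$seed
  with_seed(seed, {
    nv <- n_voxels(acq)
    phase <- phase_map %||% runif(nv, 0, 2 * pi)
    amp <- rep_len(snr_amplitude, nv)
    f <- cycles / acq$run_length
    tt <- volume_times(acq)
    bold <- noise_matrix(acq, noise) +
      amp * sin(outer(phase, 2 * pi * f * tt, `+`))
    structure(list(bold = as_bold_array(bold, acq), events = NULL,
                   truth = list(phase = phase, amplitude = amp,
                                stim_freq = f, noise = noise, seed = seed),
                   acq = acq, type = "retinotopy"),
              class = "sim_run")
  })
}

#' Simulate a binocular-rivalry priming session
#'
#' Generates the trial table of the imagery-onset reliability experiment:
#' free-decision and cued conditions crossed with imagery durations of
#' 3.33, 6.67 and 10 s. On non-catch trials the rivalry outcome is mixed
#' with probability `mixed_rate`, otherwise congruent with the imagined
#' grating with probability `baseline + slope * imagery_time` for the
#' trial's condition. Catch trials (physically fused gratings) are added as
#' a fraction of the non-catch count, evenly split over imagery times, and
#' report "mixed" with probability `catch_mixed_rate`. Vividness increases
#' with imagery time through a latent linear model binned to 1-4.
#'
#' @param n_trials_per_cell non-catch trials per condition-by-time cell
#'   (default 40, i.e. 120 trials per condition).
#' @param priming_model list with numeric vectors `baseline` and `slope`
#'   (per second), each named `free` and `cued`.
#' @param mixed_rate probability of a mixed outcome on non-catch trials.
#' @param catch_fraction catch trials as a fraction of non-catch trials
#'   (default 0.2: 240 non-catch trials yield 48 catch trials).
#' @param catch_mixed_rate probability a catch trial is reported mixed.
#' @param vividness_model list(intercept, slope, sd) for the latent
#'   vividness score as a function of imagery time.
#' @param seed RNG seed.
#' @return data.frame with columns condition, imagery_time, imagined,
#'   dominant, vividness, is_catch.
#' @export
simulate_rivalry_session <- function(
    n_trials_per_cell = 40,
    priming_model = list(baseline = c(free = 0.50, cued = 0.57),
                         slope = c(free = 0.02, cued = 0.02)),
    mixed_rate = 0.15, catch_fraction = 0.2, catch_mixed_rate = 0.838,
    vividness_model = list(intercept = 1.7, slope = 0.12, sd = 0.8),
    seed = NULL) {
  stopifnot(n_trials_per_cell >= 1, mixed_rate >= 0, mixed_rate <= 1,
            catch_fraction >= 0, catch_fraction <= 1,
            catch_mixed_rate >= 0, catch_mixed_rate <= 1)
  times <- c(3.33, 6.67, 10)
  conds <- c("free", "cued")
  p_dom <- outer(conds, times, function(cn, tm)
    priming_model$baseline[cn] + priming_model$slope[cn] * tm)
  if (any(p_dom < 0 | p_dom > 1))
    stop("priming model yields probabilities outside [0, 1]")
  with_seed(seed, {
    rows <- list()
    for (ci in seq_along(conds)) for (ti in seq_along(times)) {
      n <- n_trials_per_cell
      imagined <- sample(rep_len(c("A", "B"), n))
      mixed <- runif(n) < mixed_rate
      congr <- runif(n) < p_dom[ci, ti]
      dominant <- ifelse(mixed, "mixed",
                         ifelse(congr, imagined,
                                ifelse(imagined == "A", "B", "A")))
      lat <- vividness_model$intercept + vividness_model$slope * times[ti] +
        vividness_model$sd * rnorm(n)
      rows[[length(rows) + 1]] <- data.frame(
        condition = conds[ci], imagery_time = times[ti], imagined = imagined,
        dominant = dominant,
        vividness = pmin(4L, pmax(1L, as.integer(round(lat)))),
        is_catch = FALSE)
    }
    n_catch <- round(catch_fraction * n_trials_per_cell * 6)
    if (n_catch > 0) {
      tm <- rep_len(rep(times, each = ceiling(n_catch / 3)), n_catch)
      imagined <- sample(rep_len(c("A", "B"), n_catch))
      mixed <- runif(n_catch) < catch_mixed_rate
      lat <- vividness_model$intercept + vividness_model$slope * tm +
        vividness_model$sd * rnorm(n_catch)
      rows[[length(rows) + 1]] <- data.frame(
        condition = sample(rep_len(conds, n_catch)), imagery_time = tm,
        imagined = imagined,
        dominant = ifelse(mixed, "mixed", sample(c("A", "B"), n_catch,
                                                 replace = TRUE)),
        vividness = pmin(4L, pmax(1L, as.integer(round(lat)))),
        is_catch = TRUE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
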