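# The BOLD generators: HRF shape, trial packing, reproducibility,
# behavioural statistics of the choice policy, signal conservation, and
# the perception / retinotopy / rivalry simulators.

test_that("double-gamma HRF has the canonical shape", {
  tt <- seq(0, 32, by = 0.1)
  h <- double_gamma_hrf(tt)
  expect_lt(abs(h[1]), 1e-6)
  expect_equal(max(h), 1, tolerance = 1e-6)
  peak <- tt[which.max(h)]
  expect_gte(peak, 4)
  expect_lte(peak, 7)
  expect_lt(abs(h[tt == 30]), 0.01)
  expect_equal(double_gamma_hrf(0), 0)
  expect_error(double_gamma_hrf(c(-1, 0, 1)), "non-negative")
  expect_error(double_gamma_hrf(c(3, 2, 1)), "sorted")
  expect_error(double_gamma_hrf(c(0, 1, 3)), "uniform")
})

test_that("a default 5-minute run packs about nine trials", {
  acq <- tiny_acq(grid = c(2L, 2L, 2L))
  sig <- random_signal_spec(acq, side = 2L, seed = 1)
  counts <- vapply(1:20, function(s)
    nrow(simulate_imagery_run(acq, sig, quiet_noise(), seed = s)$events),
    numeric(1))
  expect_true(all(counts >= 7 & counts <= 11))
  expect_gte(mean(counts), 8)
  expect_lte(mean(counts), 10)
})

test_that("trial events satisfy their timing invariants across seeds", {
  acq <- acq_spec(voxel_grid = c(2L, 2L, 2L))
  sig <- random_signal_spec(acq, side = 2L, seed = 1)
  for (s in 1:300) {
    ev <- simulate_imagery_run(acq, sig, quiet_noise(), seed = s)$events
    expect_true(all(ev$decision_time > 0 & ev$decision_time <= 20))
    expect_equal(ev$press_time, ev$cue_onset + 2 + ev$decision_time)
    expect_true(all(ev$press_time + 20 <= acq$run_length))
    if (nrow(ev) > 1)
      expect_true(all(ev$press_time[-nrow(ev)] + 20 <=
                        ev$cue_onset[-1] + 1e-9))
    expect_true(all(ev$vividness %in% 1:4))
    expect_identical(ev$reported_label, ev$chosen_label)
  }
})

test_that("identical spec and seed reproduce the run bit for bit", {
  ses <- tiny_session(n_runs = 1, seed = 7)
  r1 <- simulate_imagery_run(ses$acq, ses$signal, noise_spec(), seed = 99)
  r2 <- simulate_imagery_run(ses$acq, ses$signal, noise_spec(), seed = 99)
  expect_identical(r1$bold, r2$bold)
  expect_identical(r1$events, r2$events)
})

test_that("choice policy hits its label balance and switch rate", {
  acq <- acq_spec(voxel_grid = c(2L, 2L, 2L))
  sig <- random_signal_spec(acq, side = 2L, seed = 1)
  labs <- lapply(1:200, function(s)
    simulate_imagery_run(acq, sig, quiet_noise(), seed = 1000 + s)$
      events$chosen_label)
  st <- choice_statistics(labs)
  expect_equal(st$p_A, 0.5, tolerance = 0.04)
  expect_equal(st$p_switch, 0.586, tolerance = 0.04)
  expect_gt(st$entropy_bits, 0.99)
})

test_that("injected signal energy is conserved without noise", {
  acq <- tiny_acq(run_length = 120)
  sig <- random_signal_spec(acq, seed = 3, onset_lag_seconds = 0,
                            signal_duration_seconds = 10,
                            amplitude_sd = 0, strength_fraction = 0)
  run <- simulate_imagery_run(acq, sig, quiet_noise(), seed = 5)
  ev <- run$events
  expect_gte(nrow(ev), 1)
  convA <- oracle_convolved(ev[ev$chosen_label == "A", , drop = FALSE],
                            acq, 0, 10)
  convB <- oracle_convolved(ev[ev$chosen_label == "B", , drop = FALSE],
                            acq, 0, 10)
  # patterns are orthonormal, so label energies add
  injected <- sum(bold_matrix(run)^2)
  expect_equal(injected, sum(convA^2) + sum(convB^2), tolerance = 1e-4)
  # and the noiseless volume matches the oracle time course voxel-wise
  vox <- which.max(abs(sig$pattern_A))
  expect_equal(bold_matrix(run)[, sig$region[vox]],
               convA * sig$pattern_A[vox] + convB * sig$pattern_B[vox],
               tolerance = 1e-6)
})

test_that("pure-noise runs carry no label information", {
  ses <- tiny_session(n_runs = 4, seed = 11, amplitude = 0, white_sd = 2)
  bs <- fir_beta_series(ses$runs, fir_grid(), 128, voxels = ses$signal$region)
  acc <- decode_curve(bs)$accuracy
  expect_true(all(acc >= 0 & acc <= 100))
  expect_lt(abs(mean(acc) - 50), 12)
})

test_that("perception runs have six balanced blocks and overlap control", {
  acq <- acq_spec(voxel_grid = c(6L, 6L, 6L), run_length_seconds = 180)
  sig1 <- random_signal_spec(acq, seed = 2, perception_overlap = 1)
  run <- simulate_perception_run(acq, sig1, quiet_noise(), seed = 4)
  expect_equal(nrow(run$events), 6)
  expect_equal(sum(run$events$label == "A"), 3)
  expect_gte(min(run$events$onset), 15)  # fixation-first
  # overlap 1, noiseless: block response aligned with imagery pattern
  y <- bold_matrix(run)[, sig1$region]
  blkA <- run$events$onset[run$events$label == "A"][1]
  tv <- volume_times(acq)
  snap <- colMeans(y[tv >= blkA + 6 & tv < blkA + 15, , drop = FALSE])
  alignment <- sum(snap * sig1$pattern_A) /
    sqrt(sum(snap^2) * sum(sig1$pattern_A^2))
  expect_gt(alignment, 0.99)
  # overlap 0: orthogonal to both imagery patterns
  sig0 <- random_signal_spec(acq, seed = 2, perception_overlap = 0)
  run0 <- simulate_perception_run(acq, sig0, quiet_noise(), seed = 4)
  y0 <- bold_matrix(run0)[, sig0$region]
  snap0 <- colMeans(y0[tv >= blkA + 6 & tv < blkA + 15, , drop = FALSE])
  expect_lt(abs(sum(snap0 * sig0$pattern_A)) / sqrt(sum(snap0^2)), 1e-6)
  expect_lt(abs(sum(snap0 * sig0$pattern_B)) / sqrt(sum(snap0^2)), 1e-6)
  expect_error(simulate_perception_run(
    acq_spec(voxel_grid = c(6L, 6L, 6L), run_length_seconds = 20),
    sig1, quiet_noise()), "too short")
})

test_that("retinotopy simulator realises the 0.033 Hz double-wedge cycle", {
  acq <- acq_spec(voxel_grid = c(3L, 3L, 3L), run_length_seconds = 600)
  run <- simulate_retinotopy_run(acq, cycles = 20,
                                 phase_map = rep(1, 27),
                                 noise = quiet_noise(), seed = 1)
  expect_lt(abs(run$truth$stim_freq - 0.033), 0.001)
  expect_error(simulate_retinotopy_run(acq, cycles = 1), "cycles")
})

test_that("rivalry sessions realise catch counts and priming structure", {
  tr <- simulate_rivalry_session(n_trials_per_cell = 40, seed = 9)
  expect_equal(sum(!tr$is_catch), 240)
  expect_equal(sum(tr$is_catch), 48)
  expect_setequal(unique(tr$imagery_time), c(3.33, 6.67, 10))
  # flat priming when slope is zero
  flat <- simulate_rivalry_session(
    n_trials_per_cell = 400,
    priming_model = list(baseline = c(free = 0.6, cued = 0.6),
                         slope = c(free = 0, cued = 0)), seed = 10)
  ps <- priming_summary(flat)
  expect_lt(max(ps$priming) - min(ps$priming), 0.12)
  expect_equal(mean(ps$priming), 0.6, tolerance = 0.05)
  # cued > free baseline ordering is recovered
  ord <- simulate_rivalry_session(n_trials_per_cell = 200, seed = 11)
  po <- priming_summary(ord)
  expect_gt(mean(po$priming[po$condition == "cued"]),
            mean(po$priming[po$condition == "free"]))
  expect_error(simulate_rivalry_session(
    priming_model = list(baseline = c(free = 0.99, cued = 0.99),
                         slope = c(free = 0.1, cued = 0.1))),
    "outside")
})
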