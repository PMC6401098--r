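# High-pass filtering, FIR/boxcar design construction and OLS beta
# estimation, including the cached cross-product permutation path.

test_that("DCT high-pass keeps the mean, removes drift, keeps task band", {
  tr <- 2; nt <- 300
  tt <- (seq_len(nt) - 1) * tr
  # constant series unchanged
  expect_equal(dct_highpass(rep(3.7, nt), 128, tr), rep(3.7, nt))
  # independent projection oracle: residual of lm on a cosine basis
  basis <- sapply(1:floor(2 * nt * tr / 128), function(j)
    cos(pi * (2 * seq_len(nt) - 1) * j / (2 * nt)))
  slow <- cos(2 * pi * tt / 256)
  oracle_res <- stats::lm.fit(cbind(1, basis), slow)$residuals
  filtered <- dct_highpass(slow, 128, tr)
  expect_equal(filtered - mean(slow), oracle_res, tolerance = 1e-10)
  # the basis leaks a little at the series edges for off-grid periods;
  # the oracle puts the overall attenuation at ~6% RMS
  expect_lt(sd(filtered), 0.1 * sd(slow))
  # 32-s sinusoid passes nearly unchanged
  fast <- cos(2 * pi * tt / 32)
  expect_equal(sd(dct_highpass(fast, 128, tr)), sd(fast), tolerance = 0.01)
  # idempotence
  x <- matrix(rnorm(nt * 3), nt)
  once <- dct_highpass(x, 128, tr)
  expect_equal(dct_highpass(once, 128, tr), once, tolerance = 1e-12)
  expect_error(dct_highpass(x, 4, tr), "cutoff")
  expect_error(dct_highpass(x[1:5, ], 128, tr), "8 time points")
})

test_that("FIR design indicators match a brute-force event-volume loop", {
  grid <- fir_grid()
  # press at a volume boundary: one volume per bin, 14 ones in the block
  ev <- data.frame(press_time = 40, chosen_label = "A")
  d <- build_fir_design(ev, grid, n_volumes = 50, tr = 2)
  a_cols <- d$columns$label == "A"
  expect_equal(sum(d$matrix[, a_cols]), 14)
  expect_true(all(colSums(d$matrix[, a_cols]) == 1))
  expect_equal(sum(d$matrix[, !a_cols]), 0)
  expect_false(any(d$estimable[!a_cols]))
  # two distant trials with different labels occupy disjoint volumes
  ev2 <- data.frame(press_time = c(30, 90), chosen_label = c("A", "B"))
  d2 <- build_fir_design(ev2, grid, 75, 2)
  occ_a <- rowSums(d2$matrix[, d2$columns$label == "A"]) > 0
  occ_b <- rowSums(d2$matrix[, d2$columns$label == "B"]) > 0
  expect_false(any(occ_a & occ_b))
  # brute-force oracle on random event sets
  set.seed(1)
  for (k in 1:10) {
    n_vol <- 60
    ev3 <- data.frame(press_time = sort(runif(4, 15, 100)),
                      chosen_label = sample(c("A", "B"), 4, replace = TRUE))
    d3 <- build_fir_design(ev3, grid, n_vol, 2)
    brute <- matrix(0, n_vol, nrow(d3$columns))
    for (e in seq_len(nrow(ev3))) for (v in seq_len(n_vol)) {
      rel <- (v - 1) * 2 - ev3$press_time[e]
      for (j in seq_len(grid$n_bins)) {
        lo <- grid$window_start + (j - 1) * grid$bin_width
        if (rel >= lo && rel < lo + grid$bin_width) {
          ci <- which(d3$columns$label == ev3$chosen_label[e] &
                        d3$columns$bin == j)
          brute[v, ci] <- brute[v, ci] + 1
        }
      }
    }
    expect_equal(d3$matrix, brute)
  }
  expect_error(build_fir_design(ev[0, ], grid, 50, 2), "no events")
  expect_error(build_fir_design(data.frame(press_time = 500,
                                           chosen_label = "A"),
                                grid, 50, 2), "within the run")
})

test_that("boxcar designs follow the left-closed volume rule", {
  blocks <- data.frame(onset = 30, duration = 15, label = "A")
  d <- build_block_design(blocks, 60, 2)
  expect_equal(sum(d$matrix), 8)  # volumes at 30,32,...,44
  # a pooled 10-s pre-window flags 5 volumes
  pre <- data.frame(onset = 40, duration = 10, label = "pre")
  expect_equal(sum(build_block_design(pre, 60, 2)$matrix), 5)
  expect_warning(build_block_design(
    data.frame(onset = 110, duration = 15, label = "A"), 60, 2),
    "truncated")
  expect_error(build_block_design(
    data.frame(onset = 10, duration = -2, label = "A"), 60, 2),
    "negative")
  # per-block mode gives one column per block
  b2 <- data.frame(onset = c(15, 45), duration = 15, label = c("A", "B"))
  expect_equal(ncol(build_block_design(b2, 60, 2, per_block = TRUE)$matrix),
               2)
})

test_that("OLS betas recover a noiseless construction and match lm", {
  grid <- fir_grid()
  ev <- data.frame(press_time = c(30, 80, 130),
                   chosen_label = c("A", "B", "A"))
  d <- build_fir_design(ev, grid, 100, 2)
  truth <- rnorm(ncol(d$matrix))
  y <- cbind(d$matrix %*% truth + 5)   # constant offset absorbed
  f <- fit_betas(y, d, cutoff_seconds = NULL, tr = 2)
  est <- d$estimable
  expect_equal(f$betas[est, 1], truth[est], tolerance = 1e-8)
  # single-voxel, single-column toy without filtering
  toy <- list(matrix = matrix(c(0, 1, 0, 0), 4), columns =
                data.frame(label = "A"), estimable = TRUE)
  expect_equal(fit_betas(matrix(c(0, 1, 0, 0), 4), toy, NULL, 2)$betas[1, 1],
               1)
  # oracle equivalence against lm() on random instances, with filtering
  set.seed(2)
  for (k in 1:20) {
    n <- 60
    x <- matrix(rbinom(n * 4, 1, 0.3), n, 4)
    des <- list(matrix = x, columns = data.frame(label = letters[1:4]),
                estimable = colSums(x) > 0)
    y <- matrix(rnorm(n * 2), n, 2)
    f2 <- fit_betas(y, des, 128, 2)
    xf <- dct_highpass(x, 128, 2)
    yf <- dct_highpass(y, 128, 2)
    ref <- stats::lm(yf ~ xf)
    expect_equal(unname(f2$betas[des$estimable, ]),
                 unname(coef(ref)[-1, , drop = FALSE][des$estimable, ]),
                 tolerance = 1e-8)
  }
  expect_error(fit_betas(matrix(0, 4, 1),
                         list(matrix = matrix(0, 4, 1),
                              columns = data.frame(label = "A"),
                              estimable = FALSE), NULL, 2), "all-zero")
})

test_that("beta estimates are unbiased over noise realisations", {
  grid <- fir_grid()
  ev <- data.frame(press_time = c(30, 80), chosen_label = c("A", "B"))
  d <- build_fir_design(ev, grid, 80, 2)
  truth <- rnorm(ncol(d$matrix))
  est <- d$estimable
  set.seed(3)
  betas <- replicate(400, {
    y <- cbind(d$matrix %*% truth + rnorm(80, sd = 0.2))
    fit_betas(y, d, 128, 2)$betas[, 1]
  })
  bias <- rowMeans(betas)[est] - truth[est]
  expect_lt(max(abs(bias)), 0.02 * max(abs(truth)))
})

test_that("runs missing a label yield NA betas and skipped folds", {
  ses <- tiny_session(n_runs = 2, seed = 20)
  # force run 1 to contain only label A
  ses$runs[[1]]$events$chosen_label <- "A"
  ses$runs[[1]]$events$reported_label <- "A"
  bs <- fir_beta_series(ses$runs, fir_grid(), 128,
                        voxels = ses$signal$region)
  expect_true(all(is.na(bs$runs[[1]]$betas[2, , ])))
  expect_false(any(bs$runs[[1]]$estimable[2, ]))
  expect_true(all(bs$runs[[2]]$estimable))
  samples <- beta_samples_for_bin(bs, 7)
  expect_equal(length(samples[[1]]$y), 1)  # only label A survives
  # the fold training on the single-label run must be skipped
  expect_warning(acc <- loro_decode(samples), "skipped")
  expect_true(is.finite(acc))
})

test_that("cached cross-products reproduce the full refit exactly", {
  ses <- tiny_session(n_runs = 2, seed = 30)
  run <- ses$runs[[1]]
  cache <- fir_permutation_cache(run, fir_grid(), 128,
                                 voxels = ses$signal$region)
  # observed labels
  ref <- fit_betas(bold_matrix(run)[, ses$signal$region],
                   build_fir_design(run$events, fir_grid(),
                                    n_volumes(run$acq), run$acq$tr),
                   128, run$acq$tr)
  got <- betas_for_labels(cache, run$events$chosen_label)
  expect_equal(got$betas, ref$betas, tolerance = 1e-9)
  # a within-run permutation
  set.seed(4)
  perm <- sample(run$events$chosen_label)
  ev2 <- run$events
  ev2$chosen_label <- perm
  ref2 <- fit_betas(bold_matrix(run)[, ses$signal$region],
                    build_fir_design(ev2, fir_grid(),
                                     n_volumes(run$acq), run$acq$tr),
                    128, run$acq$tr)
  got2 <- betas_for_labels(cache, perm)
  expect_equal(got2$betas, ref2$betas, tolerance = 1e-9)
})

test_that("univariate contrast is null for zero-sum multivariate patterns", {
  ses_list <- lapply(1:4, function(s) tiny_session(3, seed = 40 + s,
                                                   white_sd = 2))
  bs_list <- lapply(ses_list, function(ses)
    fir_beta_series(ses$runs, fir_grid(), 128, voxels = ses$signal$region))
  con <- mean_signal_contrast(bs_list, seq_len(64))
  # patterns have zero spatial mean: ROI-average difference stays small
  # even at bins where decoding is far above chance
  peak <- which.max(abs(con$contrast))
  expect_lt(max(abs(con$contrast)), 0.2)
  acc <- mean(vapply(bs_list, function(b)
    loro_decode(beta_samples_for_bin(b, 8)), numeric(1)))
  expect_gt(acc, 75)  # low-noise sessions decode far above chance
  # identical label betas give an exactly zero contrast
  bs0 <- bs_list[[1]]
  for (r in seq_along(bs0$runs)) bs0$runs[[r]]$betas[2, , ] <-
    bs0$runs[[r]]$betas[1, , ]
  con0 <- mean_signal_contrast(list(bs0), seq_len(64))
  expect_true(all(abs(con0$contrast) < 1e-12))
  expect_error(mean_signal_contrast(bs_list, integer(0)), "empty ROI")
})
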