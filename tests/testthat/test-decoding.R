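# Leave-one-run-out SVM decoding, cross-classification, spillover
# relabelling, the vividness split and future-vividness decoding.

mk_samples <- function(n_runs, n_per, d, sep = 0, sd = 1, seed = 1) {
  set.seed(seed)
  dir <- rnorm(d); dir <- dir / sqrt(sum(dir^2))
  lapply(seq_len(n_runs), function(r) {
    y <- rep(c("A", "B"), length.out = n_per)
    x <- matrix(rnorm(n_per * d, sd = sd), n_per, d) +
      sep * outer(ifelse(y == "A", 1, -1), dir)
    list(x = x, y = y)
  })
}

test_that("separable patterns decode perfectly, including a 1-voxel toy", {
  expect_equal(loro_decode(mk_samples(4, 6, 10, sep = 5, sd = 0.01)), 100)
  toy <- lapply(1:3, function(r)
    list(x = matrix(c(1, -1), 2, 1), y = c("A", "B")))
  expect_equal(loro_decode(toy), 100)
  expect_error(loro_decode(toy[1]), "at least 2 runs")
})

test_that("pure-noise decoding averages to chance over many seeds", {
  accs <- vapply(1:200, function(s)
    loro_decode(mk_samples(4, 6, 20, sep = 0, seed = s)), numeric(1))
  expect_lt(abs(mean(accs) - 50), 2)
})

test_that("decoding is invariant to voxel order, label swap and offsets", {
  s <- mk_samples(4, 6, 15, sep = 0.8, sd = 1, seed = 5)
  base <- loro_decode(s)
  perm <- sample(15)
  s_perm <- lapply(s, function(r) list(x = r$x[, perm], y = r$y))
  expect_equal(loro_decode(s_perm), base)
  s_swap <- lapply(s, function(r)
    list(x = r$x, y = ifelse(r$y == "A", "B", "A")))
  expect_equal(loro_decode(s_swap), base)
  s_shift <- lapply(s, function(r) list(x = r$x + 7, y = r$y))
  expect_equal(loro_decode(s_shift), base)
})

test_that("held-out runs contribute nothing to training (leakage guard)", {
  s <- mk_samples(4, 6, 15, sep = 0.5, seed = 6)
  # fold 1 computed manually from runs 2..4 only must match the package
  xtr <- do.call(rbind, lapply(s[-1], `[[`, "x"))
  ytr <- unlist(lapply(s[-1], `[[`, "y"))
  m <- e1071::svm(xtr, factor(ytr), kernel = "linear", cost = 1,
                  scale = FALSE)
  manual1 <- 100 * mean(as.character(predict(m, s[[1]]$x)) == s[[1]]$y)
  folds <- vapply(seq_along(s), function(r) {
    xt <- do.call(rbind, lapply(s[-r], `[[`, "x"))
    yt <- unlist(lapply(s[-r], `[[`, "y"))
    mm <- e1071::svm(xt, factor(yt), kernel = "linear", cost = 1,
                     scale = FALSE)
    100 * mean(as.character(predict(mm, s[[r]]$x)) == s[[r]]$y)
  }, numeric(1))
  expect_equal(loro_decode(s), mean(folds))
  expect_equal(folds[1], manual1)
})

test_that("decode_curve localises signal to the bins that carry it", {
  ses <- tiny_session(n_runs = 4, seed = 50, onset_lag_seconds = 0,
                      signal_duration_seconds = 10, white_sd = 1.5)
  bs <- fir_beta_series(ses$runs, fir_grid(), 128,
                        voxels = ses$signal$region)
  cur <- decode_curve(bs)
  pre <- cur$accuracy[cur$bin_time <= -5]
  post <- cur$accuracy[cur$bin_time >= 3 & cur$bin_time <= 11]
  expect_gt(mean(post), 85)
  expect_lt(mean(pre), 65)
  expect_gt(mean(post) - mean(pre), 20)
})

test_that("cross-decoding tracks pattern overlap between tasks", {
  acq <- tiny_acq()
  acq_p <- tiny_acq(run_length = 180)
  for (ov in c(1, 0)) {
    sig <- random_signal_spec(acq, seed = 60, perception_overlap = ov)
    perc <- lapply(1:2, function(r)
      simulate_perception_run(acq_p, sig, quiet_noise(0.5), seed = 70 + r))
    imag <- simulate_subject_imagery(acq, sig, quiet_noise(0.5),
                                     n_runs = 3, seed = 80)
    train <- pool_samples(lapply(perc, block_beta_samples,
                                        voxels = sig$region))
    bs <- fir_beta_series(imag, fir_grid(), 128, voxels = sig$region)
    gen <- cross_decode(train, bs)
    sig_bins <- gen$accuracy[gen$bin_time >= -5 & gen$bin_time <= 9]
    if (ov == 1) expect_gt(mean(sig_bins), 90) else
      expect_lt(abs(mean(sig_bins) - 50), 20)
  }
  bad <- list(x = matrix(rnorm(8), 4), y = c("C", "D", "C", "D"))
  expect_error(cross_decode(bad, bs), "label mismatch")
})

test_that("pooled windows separate pre- and post-decision information", {
  acq <- tiny_acq(); acq_p <- tiny_acq(run_length = 180)
  sig <- random_signal_spec(acq, seed = 90, onset_lag_seconds = 0,
                            signal_duration_seconds = 10,
                            perception_overlap = 1)
  perc <- lapply(1:2, function(r)
    simulate_perception_run(acq_p, sig, quiet_noise(0.5), seed = 90 + r))
  imag <- simulate_subject_imagery(acq, sig, quiet_noise(0.5),
                                   n_runs = 3, seed = 95)
  train <- pool_samples(lapply(perc, block_beta_samples,
                                      voxels = sig$region))
  pre <- lapply(imag, window_beta_samples, window = c(-10, 0),
                voxels = sig$region)
  post <- lapply(imag, window_beta_samples, window = c(0, 10),
                 voxels = sig$region)
  acc <- pooled_window_decode(train, pre, post)
  expect_gt(acc["post"], acc["pre"])
  expect_gt(acc["post"], 80)
  # signal starting before the press raises the pre-window accuracy
  sig2 <- random_signal_spec(acq, seed = 90, onset_lag_seconds = -10,
                             signal_duration_seconds = 20,
                             perception_overlap = 1)
  imag2 <- simulate_subject_imagery(acq, sig2, quiet_noise(0.5),
                                    n_runs = 3, seed = 97)
  perc2 <- lapply(1:2, function(r)
    simulate_perception_run(acq_p, sig2, quiet_noise(0.5), seed = 90 + r))
  train2 <- pool_samples(lapply(perc2, block_beta_samples,
                                       voxels = sig2$region))
  pre2 <- lapply(imag2, window_beta_samples, window = c(-10, 0),
                 voxels = sig2$region)
  post2 <- lapply(imag2, window_beta_samples, window = c(0, 10),
                  voxels = sig2$region)
  acc2 <- pooled_window_decode(train2, pre2, post2)
  expect_gt(acc2["pre"], 80)
})

test_that("spillover relabelling shifts labels and drops first trials", {
  ev <- data.frame(trial_index = 1:4, press_time = c(20, 50, 80, 110),
                   chosen_label = c("A", "B", "B", "A"),
                   vividness = c(1, 2, 3, 4))
  sh <- spillover_shift(ev)
  expect_equal(nrow(sh), 3)
  expect_equal(sh$chosen_label, c("A", "B", "B"))
  expect_equal(sh$press_time, c(50, 80, 110))
  expect_warning(out <- spillover_shift(ev[1, , drop = FALSE]), "dropped")
  expect_null(out)
})

test_that("vividness partition follows the rating rule and flags splits", {
  ev <- data.frame(vividness = c(1, 2, 3, 4))
  p <- vividness_partition(ev)
  expect_equal(p$viv_class, c("low", "low", "high", "high"))
  expect_false(attr(p, "degenerate"))
  all4 <- vividness_partition(data.frame(vividness = rep(4, 5)))
  expect_true(attr(all4, "degenerate"))
  expect_error(vividness_partition(data.frame(vividness = c(0, 5))),
               "1-4")
  # mean-split alternative
  ms <- vividness_partition(data.frame(vividness = c(1, 1, 2, 4)),
                            rule = "mean_split")
  expect_equal(ms$viv_class, c("low", "low", "low", "high"))
})

test_that("future-vividness decoding finds amplitude-coded strength", {
  set.seed(7)
  dir <- rnorm(30); dir <- dir / sqrt(sum(dir^2))
  mk <- function(informative) lapply(1:4, function(r) {
    m <- pmax(0, 1 + 0.4 * rnorm(10))
    cls <- ifelse(m <= stats::median(m), "low", "high")
    x <- matrix(rnorm(10 * 30, sd = 0.2), 10, 30)
    if (informative) x <- x + outer(5 * m, dir)
    list(x = x, y = cls)
  })
  expect_gt(decode_future_vividness(mk(TRUE), seed = 1), 75)
  accs <- vapply(1:40, function(s) {
    set.seed(s)
    decode_future_vividness(mk(FALSE), seed = s)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 5)
})
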