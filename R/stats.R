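# Group inference: the parametric test against chance, permutation-null
# ensembles built by within-run label shuffling through the full
# GLM + decoding pipeline, percentile confidence intervals, the
# across-time-points family-wise error counting test, and null-bias
# diagnostics.

#' One-sample t-test of group decoding accuracy against chance
#'
#' Upper-tailed t-test of per-subject accuracies against 50 percent (two
#' balanced classes). Zero-variance inputs take the degenerate branch:
#' p = 0 if the common value exceeds chance, 1 below it, 0.5 at chance.
#'
#' @param accuracies per-subject accuracies (percent) at one bin.
#' @return list with `t`, `p`, `mean`, `n`.
#' @export
group_accuracy_test <- function(accuracies) {
  n <- length(accuracies)
  if (n < 3) stop("need at least 3 subjects")
  m <- mean(accuracies)
  s <- sd(accuracies)
  if (s == 0) {
    t <- if (m == 50) 0 else ifelse(m > 50, Inf, -Inf)
    p <- if (m == 50) 0.5 else ifelse(m > 50, 0, 1)
  } else {
    t <- (m - 50) / (s / sqrt(n))
    p <- pt(t, df = n - 1, lower.tail = FALSE)
  }
  list(t = t, p = p, mean = m, n = n)
}

#' Permutation-null ensemble by within-run label shuffling
#'
#' For each iteration, trial labels are shuffled independently within
#' every run (preserving the per-run label counts), the FIR regressors are
#' re-derived, the full leave-one-run-out decoding is re-run per subject
#' and bin, and the group-mean accuracy curve is recorded. The GLM step
#' uses cached filtered cross-products, which is algebraically identical
#' to refitting the permuted design from scratch (see
#' [fir_permutation_cache()]).
#'
#' @param subject_caches list per subject of per-run caches from
#'   [fir_permutation_cache()].
#' @param n_iter number of iterations (default 1000).
#' @param seed master seed; each iteration gets a derived seed.
#' @param cost SVM regularization constant.
#' @param keep_subject keep the per-subject accuracy array (needed by
#'   [fwer_count_pvalue()]).
#' @return object of class `null_ensemble`: list with `acc`
#'   (iterations x bins group means), optional `subject_acc`
#'   (iterations x subjects x bins), `bin_times`, `seeds`.
#' @export
permutation_null <- function(subject_caches, n_iter = 1000, seed = NULL,
                             cost = svm_cost_default,
                             keep_subject = TRUE) {
  if (n_iter < 2) stop("need at least 2 iterations")
  n_subj <- length(subject_caches)
  grid <- subject_caches[[1]][[1]]$grid
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), n_iter)
  acc <- matrix(NA_real_, n_iter, grid$n_bins)
  sacc <- if (keep_subject)
    array(NA_real_, c(n_iter, n_subj, grid$n_bins)) else NULL
  for (it in seq_len(n_iter)) {
    with_seed(seeds[it], {
      for (s in seq_len(n_subj)) {
        curves <- decode_from_caches(subject_caches[[s]],
                                     shuffle = TRUE, cost = cost)
        if (keep_subject) sacc[it, s, ] <- curves
        acc[it, ] <- if (s == 1) curves / n_subj else
          acc[it, ] + curves / n_subj
      }
    })
  }
  structure(list(acc = acc, subject_acc = sacc,
                 bin_times = grid$bin_times, seeds = seeds,
                 n_iter = n_iter),
            class = "null_ensemble")
}

# Decode all bins for one subject from per-run caches, optionally
# shuffling labels within each run first (preserving counts).
decode_from_caches <- function(run_caches, shuffle = FALSE,
                               cost = svm_cost_default) {
  grid <- run_caches[[1]]$grid
  per_run <- lapply(run_caches, function(cc) {
    lab <- if (shuffle) sample(cc$labels_obs) else cc$labels_obs
    betas_for_labels(cc, lab)
  })
  vapply(seq_len(grid$n_bins), function(b) {
    samples <- lapply(per_run, function(f) {
      rows <- c(b, grid$n_bins + b)  # (A, bin b), (B, bin b)
      ok <- f$estimable[rows] & rowSums(is.na(f$betas[rows, , drop = FALSE])) == 0
      list(x = f$betas[rows[ok], , drop = FALSE], y = c("A", "B")[ok])
    })
    loro_decode(samples, cost)
  }, numeric(1))
}

#' Percentile confidence band of a null ensemble
#'
#' @param ensemble a `null_ensemble`.
#' @param alpha two-sided level (default 0.05).
#' @return data.frame with bin_time, low, high (empirical alpha/2 and
#'   1 - alpha/2 quantiles per bin).
#' @export
percentile_interval <- function(ensemble, alpha = 0.05) {
  if (ensemble$n_iter < 1 / alpha)
    stop("too few iterations for the requested level")
  qs <- apply(ensemble$acc, 2, quantile,
              probs = c(alpha / 2, 1 - alpha / 2), names = FALSE)
  data.frame(bin_time = ensemble$bin_times, low = qs[1, ], high = qs[2, ])
}

#' Family-wise error of the count of significant time points
#'
#' The observed statistic is the number of bins whose group t-test
#' rejects at `alpha_pointwise`. Each null iteration is scored with the
#' same rule (t-test across the per-subject permuted accuracies), and the
#' familywise p-value is the add-one permutation probability of a null
#' count at least as large.
#'
#' @param observed_sig logical vector of pointwise significance per bin.
#' @param ensemble a `null_ensemble` with `subject_acc` retained.
#' @param alpha_pointwise pointwise level (default 0.05).
#' @return list with `p`, `observed_count`, `null_counts`.
#' @export
fwer_count_pvalue <- function(observed_sig, ensemble,
                              alpha_pointwise = 0.05) {
  if (is.null(ensemble$subject_acc))
    stop("ensemble was built with keep_subject = FALSE")
  obs <- sum(observed_sig)
  ps <- pointwise_pvalues(ensemble$subject_acc)
  counts <- rowSums(ps < alpha_pointwise)
  p <- if (obs == 0) 1 else (1 + sum(counts >= obs)) / (1 + ensemble$n_iter)
  list(p = p, observed_count = obs, null_counts = counts)
}

#' Vectorised upper-tailed group tests against chance
#'
#' Applies the same test as [group_accuracy_test()] to every
#' (iteration, bin) cell of an iterations-by-subjects-by-bins accuracy
#' array at once, including the zero-variance branch.
#'
#' @param subject_acc 3-D array (iterations x subjects x bins).
#' @return iterations-by-bins matrix of one-tailed p-values.
#' @export
pointwise_pvalues <- function(subject_acc) {
  d <- dim(subject_acc)
  n <- d[2]
  flat <- matrix(aperm(subject_acc, c(2, 1, 3)), nrow = n)  # subj x (it*bin)
  m <- colMeans(flat)
  s <- sqrt(colSums((flat - rep(m, each = n))^2) / (n - 1))
  p <- numeric(length(m))
  nz <- s > 0
  p[nz] <- pt((m[nz] - 50) / (s[nz] / sqrt(n)), df = n - 1,
              lower.tail = FALSE)
  p[!nz] <- ifelse(m[!nz] == 50, 0.5, ifelse(m[!nz] > 50, 0, 1))
  matrix(p, d[1], d[3])
}

#' Bias diagnostics of a null ensemble
#'
#' Summarises the distribution of null group-mean accuracies: per-bin
#' mean, skewness, excess kurtosis and a Shapiro-Wilk normality p-value,
#' plus a single `biased` flag raised when the ensemble grand mean
#' deviates from chance by more than two standard errors.
#'
#' @param ensemble a `null_ensemble` (>= 100 iterations recommended).
#' @return list with `per_bin` data.frame, `grand_mean`, `biased`.
#' @export
null_bias_check <- function(ensemble) {
  per_bin <- data.frame(
    bin_time = ensemble$bin_times,
    mean = colMeans(ensemble$acc),
    skewness = apply(ensemble$acc, 2, e1071::skewness),
    excess_kurtosis = apply(ensemble$acc, 2, e1071::kurtosis),
    normality_p = apply(ensemble$acc, 2, function(v)
      tryCatch(shapiro.test(if (length(v) > 5000) sample(v, 5000) else
        v)$p.value, error = function(e) NA_real_)))
  gm <- rowMeans(ensemble$acc)
  se <- sd(gm) / sqrt(length(gm))
  list(per_bin = per_bin, grand_mean = mean(gm),
       biased = is.finite(se) && se > 0 && abs(mean(gm) - 50) > 2 * se)
}
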