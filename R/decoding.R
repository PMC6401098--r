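# Classification analyses on beta series: bin-wise leave-one-run-out
# decoding, perception -> imagery generalization, pooled windows, the N-1
# spillover control, the vividness split and future-vividness decoding.
# Classifier: L2-regularized linear SVM (libsvm via e1071), cost 1, no
# feature scaling, matching the convention that betas are already scaled
# relative to the run mean.

svm_cost_default <- 1

# Fit a two-class linear SVM and return a fast linear predictor.
# libsvm's decision value is positive for the class listed first in
# model$labels; ties at exactly 0 go to the alphabetically first class.
linear_svm <- function(x, y, cost = svm_cost_default) {
  yf <- factor(y)
  m <- e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- crossprod(m$SV, m$coefs)
  pos <- m$levels[m$labels[1]]
  neg <- m$levels[m$labels[2]]
  tie <- min(m$levels)
  function(newx) {
    d <- as.numeric(newx %*% w) - m$rho
    ifelse(d > 0, pos, ifelse(d < 0, neg, tie))
  }
}

#' Leave-one-run-out decoding accuracy for one set of samples
#'
#' Each scanning run is held out in turn; a linear SVM is trained on the
#' samples of all remaining runs and tested on the held-out run. No
#' feature scaling is applied. Folds whose training set lacks a label (or
#' whose test run has no samples) are skipped with a warning; accuracy is
#' percent correct per fold (sample-weighted), averaged over folds.
#'
#' @param samples list per run of `list(x = matrix, y = labels)`, e.g.
#'   from [beta_samples_for_bin()].
#' @param cost SVM regularization constant (default 1).
#' @return accuracy in percent.
#' @export
loro_decode <- function(samples, cost = svm_cost_default) {
  n_runs <- length(samples)
  if (n_runs < 2) stop("need at least 2 runs for cross-validation")
  acc <- rep(NA_real_, n_runs)
  for (r in seq_len(n_runs)) {
    test <- samples[[r]]
    train <- samples[-r]
    xtr <- do.call(rbind, lapply(train, `[[`, "x"))
    ytr <- unlist(lapply(train, `[[`, "y"))
    if (length(test$y) == 0 || length(unique(ytr)) < 2) {
      warning("fold ", r, " skipped: missing label or empty test run")
      next
    }
    pred <- linear_svm(xtr, ytr, cost)(test$x)
    acc[r] <- 100 * mean(pred == test$y)
  }
  if (all(is.na(acc))) stop("all folds skipped")
  mean(acc, na.rm = TRUE)
}

#' Bin-wise decoding curve for one subject
#'
#' Applies [loro_decode()] independently to every FIR bin.
#'
#' @param bs a `beta_series` from [fir_beta_series()].
#' @param cost SVM regularization constant.
#' @return data.frame with `bin_time` and `accuracy` (percent).
#' @export
decode_curve <- function(bs, cost = svm_cost_default) {
  acc <- vapply(seq_len(bs$grid$n_bins), function(b)
    loro_decode(beta_samples_for_bin(bs, b), cost), numeric(1))
  data.frame(bin_time = bs$grid$bin_times, accuracy = acc)
}

#' Group decoding curve across subjects
#'
#' @param bs_list list of `beta_series`, one per subject.
#' @param cost SVM regularization constant.
#' @param condition tag stored in the output (e.g. "imagery").
#' @return data.frame with subject, bin_time, accuracy, condition.
#' @export
group_decode_curve <- function(bs_list, cost = svm_cost_default,
                               condition = "imagery") {
  out <- lapply(seq_along(bs_list), function(s) {
    d <- decode_curve(bs_list[[s]], cost)
    d$subject <- s
    d
  })
  out <- do.call(rbind, out)
  out$condition <- condition
  out[, c("subject", "bin_time", "accuracy", "condition")]
}

#' Pool per-run samples into one matrix and label vector
#'
#' @param samples list per run of `list(x, y)`.
#' @return single `list(x, y)`.
#' @export
pool_samples <- function(samples) {
  list(x = do.call(rbind, lapply(samples, `[[`, "x")),
       y = unlist(lapply(samples, `[[`, "y")))
}

#' Perception-to-imagery generalization curve
#'
#' One classifier is trained once on the pooled perception samples (no
#' cross-validation: training and test data come from disjoint runs) and
#' evaluated on the imagery samples of every FIR bin.
#'
#' @param train_samples perception samples: `list(x, y)` or a per-run list.
#' @param test_bs imagery `beta_series`.
#' @param cost SVM regularization constant.
#' @return data.frame with `bin_time` and `accuracy`.
#' @export
cross_decode <- function(train_samples, test_bs,
                         cost = svm_cost_default) {
  if (is.null(train_samples$x)) train_samples <- pool_samples(train_samples)
  if (!setequal(unique(train_samples$y), test_bs$labels))
    stop("label mismatch between training and test sets")
  pred <- linear_svm(train_samples$x, train_samples$y, cost)
  acc <- vapply(seq_len(test_bs$grid$n_bins), function(b) {
    s <- pool_samples(beta_samples_for_bin(test_bs, b))
    100 * mean(pred(s$x) == s$y)
  }, numeric(1))
  data.frame(bin_time = test_bs$grid$bin_times, accuracy = acc)
}

#' Pooled-window generalization: before vs after the decision
#'
#' Trains on perception samples and tests on imagery betas estimated with
#' single boxcar windows covering -10..0 s (pre) and 0..10 s (post)
#' relative to the press, pooling over time points for sensitivity.
#'
#' @param train_samples perception samples (`list(x, y)` or per-run list).
#' @param pre_samples,post_samples imagery window samples, per-run lists.
#' @param cost SVM regularization constant.
#' @return named numeric vector c(pre = , post = ) in percent.
#' @export
pooled_window_decode <- function(train_samples, pre_samples, post_samples,
                                 cost = svm_cost_default) {
  if (is.null(train_samples$x)) train_samples <- pool_samples(train_samples)
  pred <- linear_svm(train_samples$x, train_samples$y, cost)
  one <- function(s) {
    p <- pool_samples(s)
    100 * mean(pred(p$x) == p$y)
  }
  c(pre = one(pre_samples), post = one(post_samples))
}

#' Shift trial labels to the previous trial (N-1 spillover control)
#'
#' Trial i takes the label of trial i-1 and the first trial of each run is
#' dropped. If real predictive signals were carry-over from the previous
#' trial, decoding with these labels should succeed in the pre-imagery
#' period.
#'
#' @param events one run's event table.
#' @return relabelled event table, or `NULL` (with a warning) for runs
#'   with fewer than 2 trials.
#' @export
spillover_shift <- function(events) {
  if (nrow(events) < 2) {
    warning("run with fewer than 2 trials dropped from N-1 analysis")
    return(NULL)
  }
  out <- events[-1, , drop = FALSE]
  out$chosen_label <- head(events$chosen_label, -1)
  out
}

#' Partition trials into low and high vividness
#'
#' The reporting-scale rule assigns ratings 1-2 to "low" and 3-4 to
#' "high"; `rule = "mean_split"` instead splits at the subject's mean
#' rating. Subjects with an empty class must be excluded by the caller
#' (the function flags this).
#'
#' @param events event table with a `vividness` column (integers 1-4).
#' @param rule "ratings" (1-2 vs 3-4) or "mean_split".
#' @return events with an added `viv_class` column ("low"/"high") and
#'   attribute `degenerate` (TRUE if a class is empty).
#' @export
vividness_partition <- function(events, rule = c("ratings", "mean_split")) {
  rule <- match.arg(rule)
  v <- events$vividness
  if (any(!v %in% 1:4)) stop("vividness ratings must be integers 1-4")
  cls <- if (rule == "ratings") ifelse(v <= 2, "low", "high")
  else ifelse(v <= mean(v), "low", "high")
  events$viv_class <- cls
  attr(events, "degenerate") <- length(unique(cls)) < 2
  events
}

#' Decode future vividness from pre-imagery betas
#'
#' Leave-one-run-out classification of high vs low vividness from
#' per-trial betas of the -10..0 s window before the press. Training
#' folds are balanced by subsampling the larger class (the class split is
#' not balanced by design, unlike the content labels); folds with fewer
#' than 2 training trials in either class are skipped.
#'
#' @param samples list per run of `list(x = trial-by-voxel matrix,
#'   y = "low"/"high")`.
#' @param cost SVM regularization constant.
#' @param seed RNG seed for the balancing subsample.
#' @return accuracy in percent.
#' @export
decode_future_vividness <- function(samples, cost = svm_cost_default,
                                    seed = NULL) {
  n_runs <- length(samples)
  if (n_runs < 2) stop("need at least 2 runs")
  with_seed(seed, {
    acc <- rep(NA_real_, n_runs)
    for (r in seq_len(n_runs)) {
      test <- samples[[r]]
      tr <- pool_samples(samples[-r])
      counts <- table(factor(tr$y, c("low", "high")))
      if (any(counts < 2) || length(test$y) == 0) {
        warning("fold ", r, " skipped: fewer than 2 trials in a class")
        next
      }
      n_keep <- min(counts)
      keep <- unlist(lapply(c("low", "high"), function(cl) {
        i <- which(tr$y == cl)
        if (length(i) > n_keep) sample(i, n_keep) else i
      }))
      pred <- linear_svm(tr$x[keep, , drop = FALSE], tr$y[keep], cost)
      acc[r] <- 100 * mean(pred(test$x) == test$y)
    }
    if (all(is.na(acc))) stop("all folds skipped")
    mean(acc, na.rm = TRUE)
  })
}
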