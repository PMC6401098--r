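# Behavioural analyses: binocular-rivalry priming as an objective index
# of imagery strength, self-report reliability (catch trials), choice
# statistics and signal-detection sensitivity.

#' Raw rivalry priming for one cell
#'
#' Proportion of trials whose dominant rivalry percept was congruent with
#' the imagined grating, among non-mixed non-catch trials of one
#' condition-by-imagery-time cell.
#'
#' @param trials data.frame with `imagined`, `dominant`, `is_catch`.
#' @return proportion in `[0, 1]`, or `NA` (with a warning) if every
#'   usable trial was mixed.
#' @export
raw_priming <- function(trials) {
  t2 <- trials[!trials$is_catch, , drop = FALSE]
  if (nrow(t2) == 0) stop("no non-catch trials")
  usable <- t2$dominant != "mixed"
  if (!any(usable)) {
    warning("all trials mixed; priming undefined")
    return(NA_real_)
  }
  sum(t2$dominant[usable] == t2$imagined[usable]) / sum(usable)
}

#' Priming and vividness summary per condition and imagery time
#'
#' @param trials a rivalry trial table (see
#'   [simulate_rivalry_session()]).
#' @return data.frame per (condition, imagery_time): `priming`,
#'   `mean_vividness` (non-mixed, non-catch trials) and `n`.
#' @export
priming_summary <- function(trials) {
  cells <- unique(trials[!trials$is_catch, c("condition", "imagery_time")])
  cells <- cells[order(cells$condition, cells$imagery_time), ]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- trials$condition == cells$condition[i] &
      trials$imagery_time == cells$imagery_time[i] & !trials$is_catch
    sub <- trials[sel, , drop = FALSE]
    nm <- sub[sub$dominant != "mixed", , drop = FALSE]
    data.frame(condition = cells$condition[i],
               imagery_time = cells$imagery_time[i],
               priming = raw_priming(sub),
               mean_vividness = mean(nm$vividness), n = nrow(sub))
  }))
  rownames(out) <- NULL
  out
}

#' Z-score cell values within a participant
#'
#' Centres and scales (sample sd) one participant's cell values across
#' time points and conditions, removing baseline differences between
#' participants while preserving relative differences among cells.
#'
#' @param values numeric vector of cell values (>= 2 defined).
#' @return z-scored values; all zeros (with a warning) if the sd is 0.
#' @export
zscore_within_participant <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("need at least 2 defined cell values")
  s <- sd(values[ok])
  if (s == 0) {
    warning("zero variance across cells; returning zeros")
    values[ok] <- 0
    return(values)
  }
  values[ok] <- (values[ok] - mean(values[ok])) / s
  values
}

#' One-way ANOVA F from definitional sums of squares
#'
#' Between/within mean-square ratio with k - 1 and N - k degrees of
#' freedom, computed directly from the definitional sums so it can be
#' checked against generic implementations.
#'
#' @param values numeric response vector.
#' @param groups factor (or coercible) of the same length.
#' @return list with `F`, `p`, `df1`, `df2`.
#' @export
one_way_anova_f <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 values")
  grand <- mean(values)
  means <- tapply(values, g, mean)
  ns <- tabulate(g)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((values - means[g])^2)
  df1 <- nlevels(g) - 1
  df2 <- length(values) - nlevels(g)
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Proportion of catch trials reported as mixed
#'
#' Catch trials present physically fused, equally dominant gratings; a
#' high mixed-report rate indicates reliable rivalry self-report.
#'
#' @param trials trial table; only rows with `is_catch` are used.
#' @return proportion in `[0, 1]`.
#' @export
catch_mixed_rate <- function(trials) {
  ct <- trials[trials$is_catch, , drop = FALSE]
  if (nrow(ct) == 0) stop("no catch trials")
  mean(ct$dominant == "mixed")
}

#' Signal-detection sensitivity d-prime
#'
#' `qnorm(hit) - qnorm(fa)`. When trial counts are supplied the
#' log-linear correction `(x + 0.5) / (n + 1)` is applied, keeping rates
#' off 0 and 1; without counts, degenerate rates are an error.
#'
#' @param hit_rate,false_alarm_rate rates in `[0, 1]`.
#' @param n_signal,n_noise optional trial counts for the correction.
#' @return d-prime.
#' @export
dprime <- function(hit_rate, false_alarm_rate, n_signal = NULL,
                   n_noise = NULL) {
  fix <- function(r, n) {
    if (!is.null(n)) return((r * n + 0.5) / (n + 1))
    if (r <= 0 || r >= 1)
      stop("rate of 0 or 1 needs trial counts for the log-linear correction")
    r
  }
  qnorm(fix(hit_rate, n_signal)) - qnorm(fix(false_alarm_rate, n_noise))
}

#' Choice statistics of one participant's label sequences
#'
#' @param runs list of per-run label vectors (elements "A"/"B").
#' @return list with `p_A`, `entropy_bits` (binary Shannon entropy of the
#'   overall choice probability) and `p_switch` (probability of switching
#'   label between consecutive trials within a run).
#' @export
choice_statistics <- function(runs) {
  labels <- unlist(runs)
  if (length(labels) < 2) stop("need at least 2 trials")
  p <- mean(labels == "A")
  h <- if (p %in% c(0, 1)) 0 else -p * log2(p) - (1 - p) * log2(1 - p)
  switches <- unlist(lapply(runs, function(r)
    if (length(r) >= 2) head(r, -1) != tail(r, -1) else logical(0)))
  list(p_A = p, entropy_bits = h,
       p_switch = if (length(switches)) mean(switches) else NA_real_)
}
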