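#' Trial-averaged stimulus responses
#'
#' Averages dF/F0 across all presentations (trials) of a stimulus and
#' retains, per trial, the mean dF/F0 during the stimulus window and
#' during the equally long stretch of gray screen immediately preceding
#' it, for the paired comparison used in activity classification.
#'
#' @param traces an `activity_traces` (or any list with `dff`,
#'   `schedule`, `frame_rate`).
#' @param stimulus schedule label, e.g. `"grating_45"` or `"ni_1"`.
#' @param window seconds of stimulus (from onset) and of preceding gray
#'   (up to onset) entering the means; default 3 s, use 10 for
#'   plasticity sessions.
#' @return object of class `trial_average`: `avg` (neurons x window
#'   frames, mean over trials), `gray_avg` (same for the preceding
#'   gray), `stim_trial_means`, `gray_trial_means` (neurons x trials),
#'   `n_trials`, `dt`, `stimulus`.
#' @export
trial_average <- function(traces, stimulus, window = 3) {
  schedule <- traces$schedule
  fr <- traces$frame_rate
  ep <- schedule_epochs(schedule)
  stim_eps <- which(ep$label == stimulus)
  if (!length(stim_eps)) stop(sprintf("stimulus '%s' not in schedule", stimulus))
  nw <- epoch_frames(window, fr)
  n <- nrow(traces$dff)

  stim_tr <- array(NA_real_, c(n, nw, length(stim_eps)))
  gray_tr <- array(NA_real_, c(n, nw, length(stim_eps)))
  for (k in seq_along(stim_eps)) {
    i <- stim_eps[k]
    s0 <- ep$start[i]
    if (nw > ep$end[i] - s0 + 1L)
      stop("stimulus epoch shorter than requested window")
    stim_tr[, , k] <- traces$dff[, s0:(s0 + nw - 1L), drop = FALSE]
    if (i == 1L || ep$label[i - 1L] != "gray")
      stop("no preceding gray epoch for paired baseline")
    g1 <- ep$end[i - 1L]
    if (g1 - nw + 1L < ep$start[i - 1L])
      stop("preceding gray epoch shorter than requested window")
    gray_tr[, , k] <- traces$dff[, (g1 - nw + 1L):g1, drop = FALSE]
  }
  structure(list(
    avg = apply(stim_tr, c(1L, 2L), mean),
    gray_avg = apply(gray_tr, c(1L, 2L), mean),
    stim_trial_means = apply(stim_tr, c(1L, 3L), mean),
    gray_trial_means = apply(gray_tr, c(1L, 3L), mean),
    n_trials = length(stim_eps), dt = 1 / fr, stimulus = stimulus),
    class = "trial_average")
}

#' @export
print.trial_average <- function(x, ...) {
  cat(sprintf("<trial_average> '%s': %d neurons, %d trials, %d frames\n",
              x$stimulus, nrow(x$avg), x$n_trials, ncol(x$avg)))
  invisible(x)
}

#' Classify neurons as highly/weakly/non-responsive
#'
#' A neuron is active for a stimulus when its trial-averaged stimulus
#' dF/F0 exceeds the threshold AND differs from the preceding gray
#' screen (two-sided paired t test across trials, p < 0.05). The high
#' threshold is a fixed 5% dF/F0; the low threshold is 2 SDs of the
#' baseline (SD across frames of the trial-averaged preceding-gray
#' trace). `active_high` implies `active_low` by construction:
#' classes are `active_high` (passes both thresholds), `weak`
#' (low-threshold only), `nonresponsive`.
#'
#' @param trial_avg a [trial_average()].
#' @param high_threshold fraction, default 0.05 (strict >).
#' @param p_threshold paired-test significance level.
#' @return data frame per neuron: `mean_stim`, `mean_gray`, `p_value`,
#'   `baseline_sd`, `active_high`, `active_low`, `class`, `flagged`
#'   (TRUE when trial variance was zero and the t test undefined, in
#'   which case thresholds alone decide).
#' @export
classify_active <- function(trial_avg, high_threshold = 0.05,
                            p_threshold = 0.05) {
  n <- nrow(trial_avg$stim_trial_means)
  mean_stim <- rowMeans(trial_avg$stim_trial_means)
  mean_gray <- rowMeans(trial_avg$gray_trial_means)
  baseline_sd <- apply(trial_avg$gray_avg, 1L, stats::sd)
  p <- numeric(n); flagged <- logical(n)
  for (i in seq_len(n)) {
    d <- trial_avg$stim_trial_means[i, ] - trial_avg$gray_trial_means[i, ]
    if (length(d) < 2L || stats::sd(d) == 0) {
      ## degenerate trials: t test undefined; identical stim/gray means
      ## are nonresponsive (p = 1), otherwise thresholds alone decide
      flagged[i] <- TRUE
      p[i] <- if (all(d == 0)) 1 else 0
    } else p[i] <- stats::t.test(d)$p.value
  }
  sig <- p < p_threshold
  high <- mean_stim > high_threshold & sig
  low <- mean_stim > 2 * baseline_sd & sig
  high <- high & low
  cls <- ifelse(high, "active_high", ifelse(low, "weak", "nonresponsive"))
  data.frame(mean_stim = mean_stim, mean_gray = mean_gray, p_value = p,
             baseline_sd = baseline_sd, active_high = high,
             active_low = low, class = cls, flagged = flagged)
}

#' Area under a dF/F0 trace
#'
#' Trapezoidal integral of the response over its window, in dF/F0
#' seconds. The sampling interval is the reciprocal frame rate.
#'
#' @param trace numeric vector.
#' @param dt seconds per sample.
#' @return scalar AUC.
#' @export
compute_auc <- function(trace, dt) {
  if (!length(trace)) stop("empty trace")
  if (any(!is.finite(trace))) stop("non-finite trace")
  if (length(trace) == 1L) return(trace * dt)
  pracma::trapz(seq_along(trace) * dt, trace)
}

#' Per-neuron AUC of the trial-averaged response
#'
#' @param trial_avg a [trial_average()].
#' @return numeric vector, one AUC per neuron.
#' @export
response_auc <- function(trial_avg) {
  apply(trial_avg$avg, 1L, compute_auc, dt = trial_avg$dt)
}

#' Fractions of responding neurons
#'
#' Fraction of neurons whose mean window dF/F0 lies strictly above
#' each threshold (e.g. 15% for "high responders"), over the supplied
#' population.
#'
#' @param window_means per-neuron mean dF/F0 over the analysis window.
#' @param thresholds numeric vector of dF/F0 fractions.
#' @return named numeric vector of fractions.
#' @export
response_fractions <- function(window_means, thresholds = 0.15) {
  if (!length(window_means)) stop("empty population")
  out <- vapply(thresholds, function(th) mean(window_means > th), numeric(1))
  names(out) <- paste0("gt_", thresholds)
  out
}

#' Fraction of visually responsive neurons
#'
#' Number of neurons active for at least one stimulus divided by the
#' number of identified neurons.
#'
#' @param active_by_stim logical matrix, neurons x stimuli (or vector).
#' @param n_identified total identified neurons (denominator).
#' @return scalar fraction.
#' @export
active_fraction <- function(active_by_stim, n_identified) {
  act <- if (is.matrix(active_by_stim)) rowSums(active_by_stim) > 0
         else as.logical(active_by_stim)
  sum(act) / n_identified
}
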