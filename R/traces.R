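#' Recording container
#'
#' Bundles raw fluorescence `F`, neuropil fluorescence `Fneu` and a
#' deconvolved-activity matrix `deconv` (all neurons x frames) with the
#' stimulus schedule and frame rate.
#'
#' @param F,Fneu,deconv numeric matrices, neurons x frames, same shape.
#' @param schedule a `stimulus_schedule` covering every frame.
#' @param frame_rate Hz, > 0.
#' @return object of class `recording`.
#' @export
new_recording <- function(F, Fneu, deconv, schedule, frame_rate) {
  stop_if_not_matrix_like(F, "F")
  stop_if_not_matrix_like(Fneu, "Fneu")
  stop_if_not_matrix_like(deconv, "deconv")
  if (!identical(dim(F), dim(Fneu)) || !identical(dim(F), dim(deconv)))
    stop("F, Fneu and deconv must share dimensions")
  if (any(deconv < 0)) stop("deconv must be nonnegative")
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (nrow(schedule) != ncol(F))
    stop(sprintf("schedule covers %d frames but matrices have %d",
                 nrow(schedule), ncol(F)))
  structure(list(F = F, Fneu = Fneu, deconv = deconv, schedule = schedule,
                 frame_rate = frame_rate),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d neurons x %d frames at %.2f Hz\n",
              nrow(x$F), ncol(x$F), x$frame_rate))
  invisible(x)
}

#' Neuropil correction
#'
#' Fcorr = F - coeff * Fneu, removing the scaled surround contamination
#' from the somatic signal. The standard coefficient is 0.5.
#'
#' @param F,Fneu matrices or vectors of equal shape.
#' @param coeff correction factor in [0, 1].
#' @return corrected fluorescence, same shape.
#' @export
neuropil_correct <- function(F, Fneu, coeff = 0.5) {
  if (!identical(dim(F), dim(Fneu)) || length(F) != length(Fneu))
    stop("F and Fneu shapes differ")
  if (coeff < 0 || coeff > 1) stop("coeff must be in [0, 1]")
  F - coeff * Fneu
}

#' Baseline F0 as the mode of the trace density
#'
#' Gaussian KDE (Silverman bandwidth) evaluated on a 512-point grid
#' spanning the trace range; F0 is the grid point of maximum density,
#' ties broken toward the smaller value. Used for sessions without a
#' dedicated pre-stimulus baseline window.
#'
#' @param trace numeric vector, >= 100 finite samples.
#' @return scalar F0.
#' @export
estimate_f0_mode <- function(trace) {
  if (any(!is.finite(trace))) stop("trace contains non-finite values")
  if (length(trace) < 100L) stop("need at least 100 samples")
  if (max(trace) == min(trace)) return(trace[1L])
  d <- stats::density(trace, bw = "nrd0", n = 512L,
                      from = min(trace), to = max(trace))
  d$x[which.max(d$y)]
}

#' Baseline F0 as the pre-stimulus mean
#'
#' Arithmetic mean of the corrected fluorescence over the `window`
#' seconds immediately preceding stimulus onset (plasticity sessions).
#'
#' @param trace numeric vector (single neuron).
#' @param schedule the recording's `stimulus_schedule`.
#' @param window seconds, default 10.
#' @return scalar F0.
#' @export
estimate_f0_window <- function(trace, schedule, window = 10) {
  fr <- schedule_frame_rate(schedule)
  onset <- which(schedule$label != "gray")[1L]
  if (is.na(onset)) stop("schedule has no stimulus")
  nw <- epoch_frames(window, fr)
  if (onset - 1L < nw)
    stop(sprintf("only %d gray frames before onset; window needs %d",
                 onset - 1L, nw))
  mean(trace[(onset - nw):(onset - 1L)])
}

#' Fractional fluorescence change
#'
#' dF/F0 = (Fcorr - F0) / F0, stored as a fraction (0.05 is "5%").
#'
#' @param Fcorr matrix (neurons x frames) or vector.
#' @param f0 per-neuron baseline, > 0 (recycled along frames).
#' @return dF/F0, same shape as `Fcorr`.
#' @export
compute_dff <- function(Fcorr, f0) {
  if (any(f0 <= 0)) stop("F0 must be > 0")
  if (is.matrix(Fcorr)) {
    if (length(f0) != 1L && length(f0) != nrow(Fcorr))
      stop("f0 must be scalar or one value per neuron")
    (Fcorr - f0) / f0
  } else (Fcorr - f0) / f0
}

#' Threshold deconvolved activity into spike events
#'
#' Per neuron, frames whose deconvolved amplitude is strictly greater
#' than mean + 2 SD of that neuron's full trace are kept as events;
#' everything else is zeroed. A zero-variance trace yields no events.
#'
#' @param deconv nonnegative matrix, neurons x frames.
#' @param n_sd SD multiplier, default 2.
#' @return list with `events` (thresholded amplitudes) and `binary`
#'   (0/1 matrix of event frames).
#' @export
threshold_events <- function(deconv, n_sd = 2) {
  stop_if_not_matrix_like(deconv, "deconv")
  if (any(deconv < 0)) stop("deconv must be nonnegative")
  mu <- rowMeans(deconv)
  sdv <- apply(deconv, 1L, stats::sd)
  thr <- mu + n_sd * sdv
  keep <- sweep(deconv, 1L, thr, ">") & sdv > 0
  events <- deconv * keep
  list(events = events, binary = 1 * keep)
}

#' ROI quality-control mask
#'
#' Multistim sessions keep neurons with at least one dF/F0 peak
#' strictly greater than 10% anywhere in the series. Plasticity
#' sessions additionally drop neurons whose F0 lies more than 2
#' population SDs from the population F0 mean, and flag the recording
#' when the mean population dF/F0 to the novel stimulus is below 1%.
#'
#' @param dff dF/F0 matrix, neurons x frames.
#' @param f0 per-neuron baseline vector.
#' @param mode "multistim" or "plasticity".
#' @param peak_threshold minimum peak, fraction (default 0.10).
#' @param novel_dff mean population dF/F0 to the novel stimulus
#'   (plasticity QC flag); `NULL` skips the flag.
#' @return logical keep-mask with attribute `low_quality` (TRUE when
#'   the novel-stimulus criterion fails).
#' @export
qc_filter <- function(dff, f0, mode = c("multistim", "plasticity"),
                      peak_threshold = 0.10, novel_dff = NULL) {
  mode <- match.arg(mode)
  kept <- apply(dff, 1L, max) > peak_threshold
  if (mode == "plasticity") {
    mu <- mean(f0); s <- stats::sd(f0)
    kept <- kept & abs(f0 - mu) <= 2 * s
  }
  low <- FALSE
  if (!is.null(novel_dff)) low <- novel_dff < 0.01
  attr(kept, "low_quality") <- low
  kept
}

#' Preprocess a recording into activity traces
#'
#' Runs neuropil correction, baseline estimation (density mode for
#' multistim, 10-s pre-stimulus mean for plasticity), dF/F0, event
#' thresholding and the ROI quality filter.
#'
#' @param recording a `recording`.
#' @param mode "multistim" or "plasticity".
#' @param neuropil_coeff correction factor, default 0.5.
#' @param baseline_window pre-stimulus window (s) for plasticity F0.
#' @return object of class `activity_traces`: `dff`, `f0`, `events`,
#'   `binary`, `kept`, plus the schedule, frame rate and mode.
#' @export
preprocess_recording <- function(recording, mode = c("multistim", "plasticity"),
                                 neuropil_coeff = 0.5, baseline_window = 10) {
  mode <- match.arg(mode)
  fcorr <- neuropil_correct(recording$F, recording$Fneu, neuropil_coeff)
  f0 <- if (mode == "multistim") {
    apply(fcorr, 1L, estimate_f0_mode)
  } else {
    apply(fcorr, 1L, estimate_f0_window, schedule = recording$schedule,
          window = baseline_window)
  }
  if (any(f0 <= 0))
    warning(sprintf("%d neuron(s) with nonpositive F0 dropped", sum(f0 <= 0)))
  ok <- f0 > 0
  dff <- matrix(0, nrow(fcorr), ncol(fcorr))
  dff[ok, ] <- compute_dff(fcorr[ok, , drop = FALSE], f0[ok])
  ev <- threshold_events(recording$deconv)
  kept <- qc_filter(dff, f0, mode) & ok
  structure(list(dff = dff, f0 = f0, events = ev$events, binary = ev$binary,
                 kept = kept, schedule = recording$schedule,
                 frame_rate = recording$frame_rate, mode = mode),
            class = "activity_traces")
}

#' @export
print.activity_traces <- function(x, ...) {
  cat(sprintf("<activity_traces> %d neurons x %d frames (%s), %d kept by QC\n",
              nrow(x$dff), ncol(x$dff), x$mode, sum(x$kept)))
  invisible(x)
}
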