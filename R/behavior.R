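#' Reconstruct position from force-plate sensors
#'
#' Smooths the four corner-sensor channels with a centred moving
#' average, then takes the force-weighted centroid of the sensor
#' coordinates per sample:
#' x = (X1 f1 + X2 f2 + X3 f3 + X4 f4) / (f1 + f2 + f3 + f4), likewise
#' for y. Samples with zero total force are linearly interpolated from
#' their neighbours and flagged.
#'
#' @param trace a `forceplate_trace` (from [generate_forceplate()]) or
#'   a samples x 4 force matrix.
#' @param smooth_window moving-average window in samples (default 5,
#'   i.e. 50 ms at 100 Hz); 1 disables smoothing.
#' @param sensors 4 x 2 matrix of sensor coordinates (cm); defaults to
#'   the 42-cm plate corners.
#' @return samples x 2 matrix of (x, y) in cm, with attributes `rate`
#'   and `interpolated` (indices of zero-force samples).
#' @export
forces_to_position <- function(trace, smooth_window = 5L, sensors = NULL) {
  if (inherits(trace, "forceplate_trace")) {
    forces <- trace$forces
    if (is.null(sensors)) sensors <- trace$sensors
    rate <- trace$rate
  } else {
    forces <- as.matrix(trace)
    rate <- attr(trace, "rate")
    if (is.null(rate)) rate <- 100
  }
  if (ncol(forces) != 4L) stop("need 4 force channels")
  if (any(forces < 0)) stop("forces must be nonnegative")
  if (is.null(sensors)) sensors <- plate_sensors()
  f <- apply(forces, 2L, moving_average, window = smooth_window)
  tot <- rowSums(f)
  zero <- which(tot == 0)
  x <- (f %*% sensors[, 1L]) / tot
  y <- (f %*% sensors[, 2L]) / tot
  if (length(zero)) {
    ok <- setdiff(seq_along(tot), zero)
    if (!length(ok)) stop("all samples have zero total force")
    x[zero] <- stats::approx(ok, x[ok], zero, rule = 2)$y
    y[zero] <- stats::approx(ok, y[ok], zero, rule = 2)$y
    warning(sprintf("%d zero-force sample(s) interpolated", length(zero)))
  }
  path <- cbind(x = as.numeric(x), y = as.numeric(y))
  attr(path, "rate") <- rate
  attr(path, "interpolated") <- zero
  path
}

#' Down-sample a path by block means
#'
#' Decimates from the acquisition rate (100 Hz) to the analysis rate
#' (2 Hz) by averaging non-overlapping blocks; a trailing partial
#' block is dropped.
#'
#' @param path samples x 2 matrix.
#' @param from,to rates in Hz; `from/to` must be an integer.
#' @return decimated path with attribute `rate = to`.
#' @export
downsample_path <- function(path, from = 100, to = 2) {
  fac <- from / to
  if (abs(fac - round(fac)) > 1e-9) stop("from/to must be an integer factor")
  fac <- as.integer(round(fac))
  n <- nrow(path) %/% fac
  if (n < 1L) stop("path shorter than one block")
  idx <- rep(seq_len(n), each = fac)
  keep <- seq_len(n * fac)
  out <- cbind(x = tapply(path[keep, 1L], idx, mean),
               y = tapply(path[keep, 2L], idx, mean))
  rownames(out) <- NULL
  attr(out, "rate") <- to
  out
}

#' Active-exploration mask
#'
#' Speed at sample i is the displacement from sample i-1 times the
#' sampling rate; the first sample has no defined speed and is never
#' exploratory. Exploration requires speed >= 3 cm/s (inclusive).
#'
#' @param path samples x 2 matrix at the analysis rate.
#' @param speed_threshold cm/s, default 3.
#' @param rate Hz; taken from the path attribute when present.
#' @return logical vector per sample, with attribute `speed`.
#' @export
exploration_mask <- function(path, speed_threshold = 3, rate = NULL) {
  if (is.null(rate)) rate <- attr(path, "rate")
  if (is.null(rate)) stop("sampling rate unknown")
  if (nrow(path) < 2L) stop("need at least 2 samples for speed")
  d <- sqrt(diff(path[, 1L])^2 + diff(path[, 2L])^2) * rate
  speed <- c(0, d)
  mask <- speed >= speed_threshold
  attr(mask, "speed") <- speed
  mask
}

#' Stimulus-zone-preference index
#'
#' SZP = (t_SZ - t_NSZ) / (t_SZ + t_NSZ) over actively explored
#' samples, where the stimulus zone is the half of the 42-cm chamber
#' closest to the stimulus monitor (boundary at the midline; samples
#' exactly on the midline count as non-stimulus zone). +1 means all
#' exploration near the stimulus, negative values indicate avoidance
#' of the familiar stimulus.
#'
#' @param path samples x 2 matrix at the analysis rate.
#' @param mask logical exploration mask from [exploration_mask()].
#' @param stimulus_side "right", "left", "top" or "bottom" (monitor
#'   position along x or y).
#' @param rate Hz; taken from the path attribute when present.
#' @return object of class `szp_result`: `szp`, `time_stim`,
#'   `time_nonstim`, `time_explore`, `flagged` (TRUE when there was no
#'   exploration and the index is undefined).
#' @export
szp_index <- function(path, mask, stimulus_side = c("right", "left", "top", "bottom"),
                      rate = NULL) {
  stimulus_side <- match.arg(stimulus_side)
  if (is.null(rate)) rate <- attr(path, "rate")
  if (is.null(rate)) stop("sampling rate unknown")
  mid <- PLATE_SIDE / 2
  in_stim <- switch(stimulus_side,
                    right = path[, 1L] > mid,
                    left = path[, 1L] < mid,
                    top = path[, 2L] > mid,
                    bottom = path[, 2L] < mid)
  dt <- 1 / rate
  t_s <- sum(mask & in_stim) * dt
  t_n <- sum(mask & !in_stim) * dt
  tot <- t_s + t_n
  structure(list(szp = if (tot > 0) (t_s - t_n) / tot else NA_real_,
                 time_stim = t_s, time_nonstim = t_n, time_explore = tot,
                 flagged = tot == 0, stimulus_side = stimulus_side),
            class = "szp_result")
}

#' @export
print.szp_result <- function(x, ...) {
  cat(sprintf("<szp_result> SZP = %s (stim %.1f s, non-stim %.1f s%s)\n",
              if (is.na(x$szp)) "NA" else sprintf("%+.3f", x$szp),
              x$time_stim, x$time_nonstim,
              if (x$flagged) "; no exploration, flagged" else ""))
  invisible(x)
}
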