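#' Stimulus schedules
#'
#' A `stimulus_schedule` is a data frame with one row per imaging frame
#' and columns `frame`, `label`, `epoch`, `cycle`, `image` (natural-image
#' index within a set, `NA` elsewhere), carrying the frame rate as an
#' attribute. Frame counts follow the ceiling convention: an epoch of
#' duration `d` seconds occupies `ceiling(d * frame_rate)` frames, with
#' half-open epoch boundaries, so a 3-s stimulus at 4.22 Hz spans 13
#' frames.
#'
#' @name stimulus_schedule
NULL

GRATING_ANGLES <- c(0, 45, 90, 135)

new_schedule <- function(labels, epoch, cycle, image, frame_rate) {
  out <- data.frame(frame = seq_along(labels), label = labels,
                    epoch = epoch, cycle = cycle, image = image,
                    stringsAsFactors = FALSE)
  attr(out, "frame_rate") <- frame_rate
  class(out) <- c("stimulus_schedule", "data.frame")
  out
}

#' Frames spanned by an epoch of given duration
#'
#' @param duration seconds.
#' @param frame_rate Hz.
#' @return integer frame count, `ceiling(duration * frame_rate)`.
#' @export
epoch_frames <- function(duration, frame_rate) {
  if (duration <= 0 || frame_rate <= 0) stop("duration and frame_rate must be positive")
  as.integer(ceiling(duration * frame_rate))
}

#' Generate a stimulus schedule
#'
#' `multistim`: 30 s gray, then 8 cycles each presenting the four
#' grating orientations (0, 45, 90, 135 degrees; 3 s each) and two
#' 3-s natural-image sets (ten 0.3-s images per set) in per-cycle
#' shuffled order, each stimulus followed by 6 s of gray.
#' `plasticity`: 60 s gray followed by a single 100-s grating block.
#'
#' @param config a [synth_config()] list (uses `frame_rate`,
#'   `schedule_kind`, `seed`, and for plasticity `plasticity_angle`).
#' @return a `stimulus_schedule` data frame.
#' @export
generate_schedule <- function(config) {
  kind <- config$schedule_kind
  fr <- config$frame_rate
  if (!kind %in% c("multistim", "plasticity"))
    stop(sprintf("unknown schedule_kind '%s'", kind))

  lab <- character(0); epo <- integer(0); cyc <- integer(0); img <- integer(0)
  e <- 0L
  add_epoch <- function(label, duration, cycle, images = FALSE) {
    n <- epoch_frames(duration, fr)
    e <<- e + 1L
    lab <<- c(lab, rep(label, n))
    epo <<- c(epo, rep(e, n))
    cyc <<- c(cyc, rep(cycle, n))
    if (images) {
      t0 <- (seq_len(n) - 1L) / fr        # frame start time within epoch
      img <<- c(img, pmin(10L, as.integer(floor(t0 / 0.3)) + 1L))
    } else img <<- c(img, rep(NA_integer_, n))
  }

  if (kind == "multistim") {
    stims <- c(paste0("grating_", GRATING_ANGLES), "ni_1", "ni_2")
    orders <- with_seed(config$seed + .seed_offset[["schedule"]],
                        lapply(1:8, function(i) sample(stims)))
    add_epoch("gray", 30, 0L)
    for (cycle in 1:8) {
      for (s in orders[[cycle]]) {
        add_epoch(s, 3, cycle, images = startsWith(s, "ni_"))
        add_epoch("gray", 6, cycle)
      }
    }
  } else {
    ang <- if (is.null(config$plasticity_angle)) 45 else config$plasticity_angle
    add_epoch("gray", 60, 0L)
    add_epoch(paste0("grating_", ang), 100, 1L)
  }
  new_schedule(lab, epo, cyc, img, fr)
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  fr <- attr(x, "frame_rate")
  cat(sprintf("<stimulus_schedule> %d frames at %.2f Hz (%.1f s)\n",
              nrow(x), fr, nrow(x) / fr))
  tab <- table(x$label)
  cat("  frames per label:\n")
  for (l in names(tab)) cat(sprintf("    %-12s %d\n", l, tab[[l]]))
  invisible(x)
}

schedule_frame_rate <- function(schedule) attr(schedule, "frame_rate")

#' Epochs of a schedule as a table
#'
#' @param schedule a `stimulus_schedule`.
#' @return data frame with one row per epoch: `epoch`, `label`, `cycle`,
#'   `start`, `end` (frame indices, inclusive).
#' @export
schedule_epochs <- function(schedule) {
  sp <- split(seq_len(nrow(schedule)),
              factor(schedule$epoch, levels = unique(schedule$epoch)))
  data.frame(
    epoch = as.integer(names(sp)),
    label = vapply(sp, function(i) schedule$label[i[1L]], character(1)),
    cycle = vapply(sp, function(i) schedule$cycle[i[1L]], integer(1)),
    start = vapply(sp, min, integer(1)),
    end = vapply(sp, max, integer(1)),
    row.names = NULL
  )
}
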