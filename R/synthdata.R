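#' Configuration for synthetic recordings
#'
#' Bundles every parameter of the synthetic-data generator: Poisson
#' spiking with von Mises orientation tuning for gratings, per-image
#' multiplicative gains for natural images, planted co-firing
#' ensembles, an exponential calcium kernel with shared neuropil
#' background and Gaussian noise, and multiplicative "training"
#' effects applied to post-training sessions.
#'
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param n_neurons number of neurons.
#' @param frame_rate imaging rate, Hz.
#' @param schedule_kind "multistim" or "plasticity".
#' @param baseline_rate spontaneous event rate, events/s.
#' @param tuning_params data frame with per-neuron columns `theta`
#'   (preferred orientation, radians in [0, pi)), `K` (concentration,
#'   >= 0), `A` (evoked rate gain, events/s), `b` (baseline gain,
#'   events/s). `NULL` draws defaults.
#' @param ni_gains n_neurons x 20 matrix of multiplicative gains on the
#'   baseline rate, one column per natural image (two sets of ten).
#'   `NULL` draws lognormal defaults.
#' @param ensemble_spec list of lists with fields `members` (neuron
#'   indices), `rate` (ensemble event rate, events/s), `participation`
#'   (probability in [0, 1] that a member fires in an event frame).
#' @param calcium_tau calcium decay time constant, seconds.
#' @param spike_amp fractional fluorescence change per spike (dF/F0 units).
#' @param noise_sd Gaussian noise SD on fluorescence, a.u.
#' @param neuropil_scale scale of the shared neuropil background.
#' @param deconv_jitter_sd SD of the Gaussian jitter added to the
#'   simulated deconvolved-activity matrix.
#' @param training_effect named list of multiplicative factors applied
#'   in post-training sessions: `evoked` (scales evoked rates),
#'   `high_fraction` (scales the tuned gain of the top quartile of
#'   neurons), `persistence` (mean run length of evoked event frames).
#' @param plasticity_angle grating orientation (degrees) for the
#'   plasticity schedule.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed = 1L, n_neurons = 80L, frame_rate = 4.22,
                         schedule_kind = c("multistim", "plasticity"),
                         baseline_rate = 0.05,
                         tuning_params = NULL, ni_gains = NULL,
                         ensemble_spec = list(),
                         calcium_tau = 2.0, spike_amp = 0.2,
                         noise_sd = 1.0, neuropil_scale = 1.0,
                         deconv_jitter_sd = 0.02,
                         training_effect = list(evoked = 1, high_fraction = 1,
                                                persistence = 1),
                         plasticity_angle = 45) {
  schedule_kind <- match.arg(schedule_kind)
  if (baseline_rate < 0) stop("baseline_rate must be >= 0")
  if (calcium_tau <= 0) stop("calcium_tau must be > 0")
  if (!all(is.finite(c(baseline_rate, calcium_tau, spike_amp, noise_sd,
                       neuropil_scale, deconv_jitter_sd))))
    stop("non-finite generator parameters")
  for (es in ensemble_spec) {
    if (es$rate < 0) stop("ensemble event rate must be >= 0")
    if (es$participation < 0 || es$participation > 1)
      stop("participation probability must be in [0, 1]")
    if (any(es$members < 1 | es$members > n_neurons))
      stop("ensemble members out of range")
  }
  cfg <- list(seed = as.integer(seed), n_neurons = as.integer(n_neurons),
              frame_rate = frame_rate, schedule_kind = schedule_kind,
              baseline_rate = baseline_rate, tuning_params = tuning_params,
              ni_gains = ni_gains, ensemble_spec = ensemble_spec,
              calcium_tau = calcium_tau, spike_amp = spike_amp,
              noise_sd = noise_sd, neuropil_scale = neuropil_scale,
              deconv_jitter_sd = deconv_jitter_sd,
              training_effect = training_effect,
              plasticity_angle = plasticity_angle)
  class(cfg) <- "synth_config"
  cfg
}

default_tuning <- function(n) {
  data.frame(theta = stats::runif(n, 0, pi),
             K = stats::rgamma(n, shape = 4, rate = 2),
             A = stats::rlnorm(n, log(0.8), 0.4),
             b = stats::rlnorm(n, log(0.05), 0.3))
}

#' Von Mises orientation rate curve
#'
#' `A * exp(K * (cos(2 * (phi - theta)) - 1)) + b`, the evoked-rate
#' model for drifting/phase-reversing gratings; `phi`, `theta` radians.
#'
#' @param phi stimulus orientation(s), radians.
#' @param theta preferred orientation, radians.
#' @param K concentration (tuning width), >= 0.
#' @param A amplitude at the preferred orientation.
#' @param b offset.
#' @return evoked rate(s), same units as `A`/`b`.
#' @export
von_mises_rate <- function(phi, theta, K, A, b) {
  A * exp(K * (cos(2 * (phi - theta)) - 1)) + b
}

#' Generate a synthetic recording with known ground truth
#'
#' Draws Poisson spikes frame by frame from the configured rates
#' (baseline during gray; baseline + von Mises evoked rate during
#' gratings; baseline scaled by per-image gains during natural images),
#' adds planted ensemble co-events, convolves with an exponential
#' calcium kernel, and assembles fluorescence, neuropil and simulated
#' deconvolved-activity matrices.
#'
#' @param config a [synth_config()].
#' @param session "pre" or "post"; "post" applies `training_effect`.
#' @return list with elements `recording` (class `recording`: matrices
#'   `F`, `Fneu`, `deconv`, the `schedule`, `frame_rate`) and `truth`
#'   (class `ground_truth`: `spikes`, `tuning`, `ensembles`,
#'   `event_frames`, per-neuron `f0_true`).
#' @export
generate_population <- function(config, session = c("pre", "post")) {
  session <- match.arg(session)
  schedule <- generate_schedule(config)
  n <- config$n_neurons
  T <- nrow(schedule)
  fr <- config$frame_rate

  with_seed(config$seed + .seed_offset[["population"]], {
    tuning <- config$tuning_params
    if (is.null(tuning)) tuning <- default_tuning(n)
    ni_gains <- config$ni_gains
    if (is.null(ni_gains))
      ni_gains <- matrix(stats::rlnorm(n * 20, 0, 1), n, 20)

    evoked_f <- 1
    if (session == "post") {
      te <- config$training_effect
      evoked_f <- te$evoked
      if (!is.null(te$high_fraction) && te$high_fraction != 1) {
        top <- order(tuning$A, decreasing = TRUE)[seq_len(ceiling(n / 4))]
        tuning$A[top] <- tuning$A[top] * te$high_fraction
      }
    }

    ## per-frame Poisson rates (events/s)
    rates <- matrix(config$baseline_rate, n, T)
    for (ang in GRATING_ANGLES) {
      idx <- which(schedule$label == paste0("grating_", ang))
      if (length(idx)) {
        ev <- von_mises_rate(ang * pi / 180, tuning$theta, tuning$K,
                             tuning$A, tuning$b)
        rates[, idx] <- rates[, idx] + evoked_f * ev
      }
    }
    for (set in 1:2) {
      idx <- which(schedule$label == paste0("ni_", set))
      if (length(idx)) {
        cols <- (set - 1L) * 10L + schedule$image[idx]
        rates[, idx] <- evoked_f * config$baseline_rate *
          pmax(ni_gains[, cols, drop = FALSE], 0)
      }
    }

    spikes <- matrix(stats::rpois(n * T, rates / fr), n, T)

    ## planted ensemble co-events
    event_frames <- vector("list", length(config$ensemble_spec))
    for (j in seq_along(config$ensemble_spec)) {
      es <- config$ensemble_spec[[j]]
      ev <- which(stats::runif(T) < es$rate / fr)
      event_frames[[j]] <- ev
      for (t in ev) {
        fire <- es$members[stats::runif(length(es$members)) < es$participation]
        spikes[fire, t] <- spikes[fire, t] + 1L
      }
    }

    ## training-induced persistence: evoked frames smear into runs with
    ## geometric mean length = persistence factor
    if (session == "post" &&
        !is.null(config$training_effect$persistence) &&
        config$training_effect$persistence > 1) {
      q <- 1 - 1 / config$training_effect$persistence
      for (t in 2:T) {
        carry <- spikes[, t - 1L] > 0 & stats::runif(n) < q
        spikes[carry, t] <- spikes[carry, t] + 1L
      }
    }

    ## calcium convolution: recursive exponential kernel, unit height
    decay <- exp(-1 / (config$calcium_tau * fr))
    conv <- t(apply(spikes, 1L, function(s)
      as.numeric(stats::filter(s, decay, method = "recursive"))))

    f0_true <- stats::runif(n, 90, 110)
    np_scale <- config$neuropil_scale * stats::runif(n, 0.8, 1.2)
    background <- 20 * (1 + 0.2 * sin(2 * pi * seq_len(T) / (600 * fr)))
    np_clean <- outer(np_scale, background)

    F <- f0_true * (1 + config$spike_amp * conv) + 0.5 * np_clean +
      matrix(stats::rnorm(n * T, 0, config$noise_sd), n, T)
    Fneu <- np_clean + matrix(stats::rnorm(n * T, 0, config$noise_sd), n, T)
    deconv <- pmax(spikes + matrix(stats::rnorm(n * T, 0, config$deconv_jitter_sd),
                                   n, T), 0)

    recording <- new_recording(F, Fneu, deconv, schedule, fr)
    truth <- structure(
      list(spikes = spikes, tuning = tuning, ni_gains = ni_gains,
           ensembles = lapply(config$ensemble_spec, `[[`, "members"),
           event_frames = event_frames, f0_true = f0_true),
      class = "ground_truth")
    list(recording = recording, truth = truth)
  })
}

#' Generate a synthetic per-dendrite synapse table
#'
#' Dendrite lengths and excitatory/inhibitory synapse densities are
#' drawn from a bivariate log-normal whose log-scale correlation is
#' chosen so that the density-scale Pearson correlation matches
#' `target_r`. Counts are densities times length, rounded; dually
#' innervated spines are a binomial share of the inhibitory count.
#'
#' @param n number of dendrites (>= 3).
#' @param target_r target Pearson correlation between excitatory and
#'   inhibitory density, in (-1, 1).
#' @param mean_e,mean_i mean densities, synapses per micrometre.
#' @param sdlog log-scale SD of the density distributions.
#' @param mean_length mean dendrite length, micrometres.
#' @param compartment "apical" or "basal" label for the table.
#' @param seed integer seed.
#' @return data frame (class `dendrite_table`) with columns `id`,
#'   `cell`, `compartment`, `length_um`, `psd95_spines`,
#'   `psd95_negative_spines`, `dual_innervated_spines`,
#'   `shaft_gephyrin`, `session`.
#' @export
generate_dendrites <- function(n = 200L, target_r = 0.43,
                               mean_e = 0.45, mean_i = 0.30, sdlog = 0.3,
                               mean_length = 50, compartment = "apical",
                               seed = 1L) {
  if (n < 3L) stop("need n >= 3 dendrites")
  if (target_r <= -1 || target_r >= 1) stop("target_r must be in (-1, 1)")
  ## invert the lognormal correlation identity so the density-scale
  ## Pearson r hits the target
  v <- exp(sdlog^2) - 1
  arg <- 1 + target_r * v
  if (arg <= 0) stop("target_r unattainable at this sdlog")
  rho <- log(arg) / sdlog^2
  if (abs(rho) > 1) stop("target_r unattainable at this sdlog")
  with_seed(seed + .seed_offset[["dendrites"]], {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    e_d <- exp(log(mean_e) - sdlog^2 / 2 + sdlog * z1)
    i_d <- exp(log(mean_i) - sdlog^2 / 2 + sdlog * z2)
    len <- stats::rlnorm(n, log(mean_length) - 0.02, 0.2)
    inh <- round(i_d * len)
    dis <- stats::rbinom(n, inh, 0.38)
    exc <- pmax(round(e_d * len), dis)
    tab <- data.frame(
      id = seq_len(n),
      cell = rep(seq_len(max(1L, n %/% 8L)), length.out = n),
      compartment = compartment,
      length_um = len,
      psd95_spines = as.integer(exc - dis),
      psd95_negative_spines = stats::rpois(n, 0.2 * pmax(exc - dis, 0)),
      dual_innervated_spines = as.integer(dis),
      shaft_gephyrin = as.integer(inh - dis),
      session = 1L)
    class(tab) <- c("dendrite_table", "data.frame")
    tab
  })
}

PLATE_SIDE <- 42
plate_sensors <- function() {
  matrix(c(0, 0, PLATE_SIDE, 0, PLATE_SIDE, PLATE_SIDE, 0, PLATE_SIDE),
         4, 2, byrow = TRUE,
         dimnames = list(paste0("s", 1:4), c("x", "y")))
}

#' Generate force-plate traces from a scripted trajectory
#'
#' Interpolates the waypoint script to the sampling rate and distributes
#' a constant total force over the four corner sensors with bilinear
#' weights, so that the force-weighted centroid of the sensor
#' coordinates recovers the scripted path exactly (up to floating
#' point).
#'
#' @param waypoints data frame with columns `t` (seconds, increasing
#'   from 0), `x`, `y` (cm, inside the 42-cm plate).
#' @param rate sampling rate, Hz.
#' @param total_force total force per sample, a.u.
#' @return list of class `forceplate_trace`: `forces` (samples x 4),
#'   `rate`, `sensors` (4 x 2 corner coordinates), `path_true`
#'   (interpolated scripted positions).
#' @export
generate_forceplate <- function(waypoints, rate = 100, total_force = 1) {
  if (!all(c("t", "x", "y") %in% names(waypoints)))
    stop("waypoints needs columns t, x, y")
  if (any(waypoints$x < 0 | waypoints$x > PLATE_SIDE |
          waypoints$y < 0 | waypoints$y > PLATE_SIDE))
    stop("waypoints outside the 42-cm plate")
  tt <- seq(min(waypoints$t), max(waypoints$t), by = 1 / rate)
  x <- stats::approx(waypoints$t, waypoints$x, tt)$y
  y <- stats::approx(waypoints$t, waypoints$y, tt)$y
  u <- x / PLATE_SIDE
  v <- y / PLATE_SIDE
  forces <- total_force * cbind((1 - u) * (1 - v), u * (1 - v), u * v,
                                (1 - u) * v)
  colnames(forces) <- paste0("f", 1:4)
  structure(list(forces = forces, rate = rate, sensors = plate_sensors(),
                 path_true = cbind(x = x, y = y)),
            class = "forceplate_trace")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d neurons x %d frames, %d planted ensemble(s)\n",
              nrow(x$spikes), ncol(x$spikes), length(x$ensembles)))
  invisible(x)
}
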