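#' Population sparseness
#'
#' Treves-Rolls-type statistic
#' S = \[1 - (sum(R)/n)^2 / (sum(R^2)/n)\] / (1 - 1/n)
#' over the per-neuron responses R (AUC of the trial-averaged dF/F0
#' during the stimulus window) of all n identified neurons. 0 means
#' equal activity across the population, 1 means a single active
#' neuron. Negative responses are clipped to 0 before evaluation.
#'
#' @param R per-neuron nonnegative responses (negatives clipped).
#' @param n population size, >= 2; defaults to `length(R)` and may be
#'   larger (missing neurons count as silent).
#' @return S in [0, 1]; `NA` with a warning when all responses are 0.
#' @export
population_sparseness <- function(R, n = length(R)) {
  if (n < 2L) stop("need population size n >= 2")
  if (n < length(R)) stop("n smaller than the number of responses")
  R <- pmax(R, 0)
  s2 <- sum(R^2)
  if (s2 == 0) {
    warning("all responses zero: sparseness undefined")
    return(NA_real_)
  }
  (1 - (sum(R) / n)^2 / (s2 / n)) / (1 - 1 / n)
}

#' Natural-image selectivity index
#'
#' SI = 1 - (sum(R)/n)^2 / (sum(R^2)/n), without the finite-size
#' normalisation, over the trial-averaged deconvolved spike-event
#' amplitudes of the n imaging frames spanning a natural-image set
#' (13 frames for a 3-s set at 4.22 Hz). 0 means equal amplitudes in
#' every frame (low selectivity); a single responsive frame of 13
#' gives 12/13.
#'
#' @param frame_amplitudes per-frame nonnegative amplitudes (negatives
#'   clipped).
#' @param n frame count, defaults to `length(frame_amplitudes)`.
#' @return SI in [0, 1 - 1/n]; `NA` with a warning when all zero.
#' @export
selectivity_index <- function(frame_amplitudes, n = length(frame_amplitudes)) {
  if (n < 2L) stop("need at least 2 frames")
  R <- pmax(frame_amplitudes, 0)
  s2 <- sum(R^2)
  if (s2 == 0) {
    warning("all frame amplitudes zero: selectivity undefined")
    return(NA_real_)
  }
  1 - (sum(R) / n)^2 / (s2 / n)
}

## Fisher/Best approximation to the inverse of A1(K) = I1(K)/I0(K),
## used only to initialise the concentration estimate
a1inv <- function(R) {
  if (R >= 1) return(500)
  if (R < 0) R <- 0
  if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
  else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
  else 1 / (R^3 - 4 * R^2 + 3 * R)
}

von_mises_design <- function(phi, theta, K) exp(K * (cos(2 * (phi - theta)) - 1))

## given (theta, K), profile out (A, b) by linear least squares
vm_profile <- function(par, phi, y) {
  x <- von_mises_design(phi, par[1L], par[2L])
  fit <- stats::lm.fit(cbind(x, 1), y)
  list(ss = sum(fit$residuals^2), A = fit$coefficients[[1L]],
       b = fit$coefficients[[2L]])
}

#' Fit a von Mises orientation tuning curve
#'
#' Fits f(phi) = A * exp(K * (cos(2 * (phi - theta)) - 1)) + b to the
#' trial-averaged response AUCs at the four grating orientations.
#' Preferred orientation theta and concentration K are initialised by
#' circular maximum likelihood on the doubled angles (responses minus
#' their minimum as weights) and refined by least squares with A and b
#' profiled out linearly at each step. The fit is `valid` when it
#' retains at least 70% of the response variance (R^2 >= 0.7).
#'
#' @param responses response AUCs (dF/F0 s) at the stimulus angles.
#' @param angles_deg stimulus orientations in degrees, default
#'   c(0, 45, 90, 135).
#' @param r2_threshold validity cut on explained variance, default 0.7.
#' @return object of class `tuning_fit` with elements `theta` (radians
#'   in [0, pi)), `K`, `A`, `b`, `R2`, `fwhm` (radians, `NA` unless
#'   valid), `valid`, `fitted`, `responses`, `angles_deg`.
#' @export
fit_von_mises <- function(responses, angles_deg = c(0, 45, 90, 135),
                          r2_threshold = 0.7) {
  if (length(responses) != length(angles_deg) || length(responses) < 4L)
    stop("need one response per angle, at least 4 angles")
  if (any(!is.finite(responses))) stop("non-finite responses")
  out <- structure(list(theta = NA_real_, K = NA_real_, A = NA_real_,
                        b = NA_real_, R2 = NA_real_, fwhm = NA_real_,
                        valid = FALSE, fitted = rep(NA_real_, length(responses)),
                        responses = responses, angles_deg = angles_deg),
                   class = "tuning_fit")
  if (stats::var(responses) == 0) return(out)
  phi <- angles_deg * pi / 180
  w <- responses - min(responses)
  C <- sum(w * cos(2 * phi)); S <- sum(w * sin(2 * phi))
  theta0 <- (atan2(S, C) / 2) %% pi
  K0 <- max(a1inv(sqrt(C^2 + S^2) / sum(w)), 1e-3)
  obj <- function(p) vm_profile(p, phi, responses)$ss
  ## the profiled surface is multimodal in (theta, K); polish a small
  ## grid of starts around the circular-ML initialisation
  starts <- expand.grid(theta = unique(c(theta0, phi %% pi)),
                        K = unique(c(K0, 0.5, 2, 8)))
  opt <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                      lower = c(-pi, 1e-8), upper = c(2 * pi, 500),
                      control = list(factr = 10))
    if (is.null(opt) || o$value < opt$value) opt <- o
    if (opt$value < 1e-22) break
  }
  ## Nelder-Mead polish: the surface is nearly flat in K at high
  ## concentration and gradient steps stall before machine precision
  opt <- stats::optim(opt$par,
                      function(p) if (p[2L] <= 0) Inf else obj(p),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  prof <- vm_profile(opt$par, phi, responses)
  theta <- opt$par[1L] %% pi
  K <- opt$par[2L]
  A <- prof$A; b <- prof$b
  if (A < 0) { # curve peak must sit at theta; reflect a negative amplitude
    theta <- (theta + pi / 2) %% pi
    prof2 <- vm_profile(c(theta, K), phi, responses)
    A <- prof2$A; b <- prof2$b
  }
  fitted <- A * von_mises_design(phi, theta, K) + b
  R2 <- 1 - sum((responses - fitted)^2) / sum((responses - mean(responses))^2)
  valid <- is.finite(R2) && R2 >= r2_threshold
  out$theta <- theta; out$K <- K; out$A <- A; out$b <- b
  out$R2 <- R2; out$valid <- valid; out$fitted <- fitted
  if (valid && K > 0) out$fwhm <- fwhm(K)
  out
}

#' @export
print.tuning_fit <- function(x, ...) {
  if (!is.finite(x$theta)) {
    cat("<tuning_fit> invalid (flat or degenerate responses)\n")
    return(invisible(x))
  }
  cat(sprintf("<tuning_fit> theta = %.1f deg, K = %.3f, A = %.4f, b = %.4f\n",
              x$theta * 180 / pi, x$K, x$A, x$b))
  cat(sprintf("  R2 = %.3f (%s), FWHM = %s\n", x$R2,
              if (x$valid) "valid" else "below 0.7, rejected",
              if (is.finite(x$fwhm)) sprintf("%.1f deg", x$fwhm * 180 / pi) else "NA"))
  invisible(x)
}

#' @export
coef.tuning_fit <- function(object, ...) {
  c(theta = object$theta, K = object$K, A = object$A, b = object$b)
}

#' @export
predict.tuning_fit <- function(object, angles_deg = object$angles_deg, ...) {
  if (!is.finite(object$theta)) return(rep(NA_real_, length(angles_deg)))
  phi <- angles_deg * pi / 180
  object$A * von_mises_design(phi, object$theta, object$K) + object$b
}

#' Full width at half maximum of a von Mises tuning curve
#'
#' FWHM = arccos( ln(0.5 * e^K + 0.5 * e^-K) / K ), evaluated with a
#' log-domain cosh for numerical stability at large K. Strictly
#' decreasing in K; approaches pi/2 as K tends to 0.
#'
#' @param K concentration, > 0.
#' @return width in radians.
#' @export
fwhm <- function(K) {
  if (any(K <= 0)) stop("K must be > 0")
  log_cosh <- K + log1p(exp(-2 * K)) - log(2)
  acos(log_cosh / K)
}

#' Population-vector overlap across time lags
#'
#' Each analysis frame's population activity is unit-normalised and
#' dotted with the frames 1..max_lag ahead; overlaps are averaged per
#' lag. 1 means the same combination of neurons is active; 0 means an
#' orthogonal combination. Frames with zero norm are excluded from the
#' average.
#'
#' @param dff activity matrix, neurons x frames.
#' @param window_frames indices of analysis frames (e.g. stimulus
#'   onset to 10 s after onset).
#' @param max_lag largest lag in frames, default 50.
#' @return object of class `overlap_curve`: `lag` (1..max_lag),
#'   `overlap`, `n_pairs` per lag.
#' @export
neural_overlap <- function(dff, window_frames, max_lag = 50L) {
  T <- ncol(dff)
  if (max(window_frames) + max_lag > T)
    stop("window too short: frames beyond the recording at max_lag")
  norms <- sqrt(colSums(dff^2))
  unit <- sweep(dff, 2L, pmax(norms, .Machine$double.eps), "/")
  overlap <- numeric(max_lag); n_pairs <- integer(max_lag)
  for (lag in seq_len(max_lag)) {
    t1 <- window_frames; t2 <- window_frames + lag
    ok <- norms[t1] > 0 & norms[t2] > 0
    n_pairs[lag] <- sum(ok)
    overlap[lag] <- if (any(ok))
      mean(colSums(unit[, t1[ok], drop = FALSE] * unit[, t2[ok], drop = FALSE]))
    else NA_real_
  }
  structure(list(lag = seq_len(max_lag), overlap = overlap, n_pairs = n_pairs),
            class = "overlap_curve")
}

#' @export
print.overlap_curve <- function(x, ...) {
  cat(sprintf("<overlap_curve> lags 1..%d, overlap %.3f at lag 1, %.3f at lag %d\n",
              max(x$lag), x$overlap[1L], x$overlap[length(x$overlap)], max(x$lag)))
  invisible(x)
}

#' Exponential decay fit of the overlap curve
#'
#' Fits Overlap(t) = (1 - b) * exp(tau * t) + b to the per-lag mean
#' overlaps, with tau <= 0 and 0 <= b <= 1, so the fitted curve is 1
#' at zero delay by construction. tau is the per-frame decay rate
#' (more negative = faster decay, less persistent representation); b
#' is the asymptotic overlap.
#'
#' @param curve an `overlap_curve`, or a numeric vector of overlaps at
#'   lags 1..length(curve); at least 5 lags.
#' @return object of class `overlap_decay`: `tau`, `b`, `fitted`,
#'   `residual` (sum of squares), `flagged` (TRUE on non-convergence
#'   or boundary degeneracy).
#' @export
fit_overlap_decay <- function(curve) {
  if (inherits(curve, "overlap_curve")) {
    lag <- curve$lag; y <- curve$overlap
  } else {
    y <- as.numeric(curve); lag <- seq_along(y)
  }
  ok <- is.finite(y)
  lag <- lag[ok]; y <- y[ok]
  if (length(y) < 5L) stop("need at least 5 lags")
  b0 <- min(max(min(y), 0), 0.999)
  pos <- pmax(y - b0, 1e-6)
  tau0 <- stats::coef(stats::lm(log(pos) ~ lag))[[2L]]
  ## clip into a generic decay range: a near-zero or runaway slope
  ## (flat or degenerate curves) makes a poor starting point
  tau0 <- min(max(tau0, -5), -1e-3)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ (1 - b) * exp(tau * lag) + b,
                      start = list(tau = tau0, b = b0),
                      lower = c(tau = -50, b = 0), upper = c(tau = 0, b = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    ## degenerate curves (e.g. constant below 1) have a singular
    ## gradient: the decay collapses to the large-negative boundary
    ## with b absorbing the asymptote; flagged
    tau_b <- -50
    b_b <- min(max(mean(y), 0), 1)
    return(structure(list(tau = tau_b, b = b_b,
                          fitted = (1 - b_b) * exp(tau_b * lag) + b_b,
                          residual = sum((y - ((1 - b_b) * exp(tau_b * lag) + b_b))^2),
                          lag = lag, flagged = TRUE),
                     class = "overlap_decay"))
  }
  cf <- stats::coef(fit)
  flagged <- cf[["tau"]] <= -50 + 1e-6
  structure(list(tau = cf[["tau"]], b = cf[["b"]],
                 fitted = stats::fitted(fit), residual = sum(stats::resid(fit)^2),
                 lag = lag, flagged = flagged),
            class = "overlap_decay")
}

#' @export
print.overlap_decay <- function(x, ...) {
  cat(sprintf("<overlap_decay> tau = %.4f per frame, asymptote b = %.3f%s\n",
              x$tau, x$b, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' @export
coef.overlap_decay <- function(object, ...) c(tau = object$tau, b = object$b)

#' @export
predict.overlap_decay <- function(object, t = object$lag, ...) {
  (1 - object$b) * exp(object$tau * t) + object$b
}

#' Post/pre plasticity ratios
#'
#' Ratio of post-training to pre-training session summaries: population
#' AUC over the first 10 s of stimulus, active-neuron fraction, mean
#' node degree of active neurons, fraction of high responders
#' (dF/F0 > 15%), and the overlap decay rate tau. A zero pre-training
#' denominator leaves the ratio `NA` and flags the row.
#'
#' @param pre,post named lists (or vectors) of session summaries with
#'   matching names, e.g. from [plasticity_session_summary()].
#' @return data frame: `metric`, `pre`, `post`, `ratio`, `flagged`.
#' @export
plasticity_ratios <- function(pre, post) {
  pre <- unlist(pre); post <- unlist(post)
  metrics <- intersect(names(pre), names(post))
  if (!length(metrics)) stop("no shared metrics between sessions")
  prev <- pre[metrics]; postv <- post[metrics]
  ratio <- ifelse(prev == 0, NA_real_, postv / prev)
  data.frame(metric = metrics, pre = as.numeric(prev),
             post = as.numeric(postv), ratio = as.numeric(ratio),
             flagged = prev == 0, row.names = NULL)
}

#' Summarise a plasticity session
#'
#' Computes the quantities entering the plasticity ratios from a
#' preprocessed plasticity session: population AUC of the mean kept-
#' neuron dF/F0 over the first 10 s of stimulus, the active-neuron
#' fraction (mean dF/F0 > 5% and paired frame-wise t test against the
#' 10-s preceding gray, p < 0.05), the high-responder fraction
#' (dF/F0 > 15%), the mean degree of active neurons in the supplied
#' graph, and the overlap decay tau over the same window.
#'
#' @param traces an `activity_traces` from a plasticity recording.
#' @param graph optional `functional_graph` built on the first-10-s
#'   frames of the kept neurons.
#' @param window analysis window, seconds (default 10).
#' @param max_lag overlap lags, default 50.
#' @return named list: `auc`, `active_fraction`,
#'   `high_responder_fraction`, `mean_degree_active`, `tau`.
#' @export
plasticity_session_summary <- function(traces, graph = NULL, window = 10,
                                       max_lag = 50L) {
  fr <- traces$frame_rate
  sched <- traces$schedule
  onset <- which(sched$label != "gray")[1L]
  nw <- epoch_frames(window, fr)
  stim_idx <- onset:(onset + nw - 1L)
  gray_idx <- (onset - nw):(onset - 1L)
  kept <- which(traces$kept)
  dff_k <- traces$dff[kept, , drop = FALSE]

  pop_trace <- colMeans(dff_k[, stim_idx, drop = FALSE])
  auc <- compute_auc(pop_trace, 1 / fr)

  mean_stim <- rowMeans(dff_k[, stim_idx, drop = FALSE])
  pvals <- vapply(seq_along(kept), function(i) {
    d <- dff_k[i, stim_idx] - dff_k[i, gray_idx]
    if (stats::sd(d) == 0) return(1)
    stats::t.test(d)$p.value
  }, numeric(1))
  active <- mean_stim > 0.05 & pvals < 0.05

  mean_deg <- if (!is.null(graph) && any(active))
    mean(graph$degree[active]) else NA_real_

  oc <- neural_overlap(dff_k, stim_idx, max_lag = max_lag)
  dec <- fit_overlap_decay(oc)

  list(auc = auc,
       active_fraction = mean(active),
       high_responder_fraction = unname(response_fractions(mean_stim, 0.15)),
       mean_degree_active = mean_deg,
       tau = dec$tau)
}
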