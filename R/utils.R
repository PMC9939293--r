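#' Evaluate an expression with a locally seeded RNG
#'
#' All stochastic stages draw from one seeded generator with fixed
#' per-stage offsets so that a pipeline run is reproducible end to end
#' without clobbering the caller's RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# fixed per-stage seed offsets (kept < 2^31 after addition for small seeds)
.seed_offset <- c(schedule = 0L, population = 101L, dendrites = 202L,
                  forceplate = 303L, connectivity = 404L, ensembles = 505L)

#' Centered moving-average filter
#'
#' @param x numeric vector.
#' @param window odd window length in samples; 1 returns `x` unchanged.
#' @return filtered vector, edges padded by replicating the first/last value.
#' @keywords internal
moving_average <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window == 1L) return(x)
  n <- length(x)
  half <- window %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, rep(1 / window, window), sides = 2L))[(half + 1L):(half + n)]
}

#' Circular cross-correlation of two equal-length vectors
#'
#' Returns `ccf[d + 1] = sum_t a[t] * b[1 + (t - 1 + d) %% T]` for
#' d = 0..T-1, i.e. the coactivity count of `a` with `b` circularly
#' shifted backward by d frames. Computed by FFT; exact up to rounding
#' (results for binary trains are rounded to integers by the callers
#' that need counts).
#'
#' @keywords internal
circ_crosscorr <- function(a, b) {
  n <- length(a)
  stopifnot(length(b) == n)
  Re(stats::fft(Conj(stats::fft(as.numeric(a))) * stats::fft(as.numeric(b)),
                inverse = TRUE)) / n
}

stop_if_not_matrix_like <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix (neurons x frames)", name))
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name))
  invisible(x)
}

#' Fisher-Pearson moment coefficient of skewness
#'
#' g1 = m3 / m2^(3/2) with central moments over n (no bias correction),
#' the convention used for degree-distribution skew.
#'
#' @param x numeric vector, length >= 3.
#' @return scalar skewness; `NA` (with a warning) when the variance is zero.
#' @export
moment_skewness <- function(x) {
  if (length(x) < 3L) stop("need at least 3 values")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    warning("zero variance: skewness undefined")
    return(NA_real_)
  }
  mean((x - m)^3) / m2^1.5
}
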