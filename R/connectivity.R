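#' Pairwise coactivity counts
#'
#' `count[a, b]` is the number of imaging frames in which neurons `a`
#' and `b` are both active in the binary event matrix.
#'
#' @param binary 0/1 matrix, neurons x frames.
#' @return symmetric integer matrix, neurons x neurons.
#' @export
coactivity_counts <- function(binary) {
  b <- (binary > 0) * 1
  m <- b %*% t(b)
  storage.mode(m) <- "integer"
  m
}

## nearest-rank percentile of a sample
nearest_rank <- function(x, percentile) {
  s <- sort(x)
  s[max(1L, ceiling(percentile / 100 * length(s)))]
}

## surrogate coactivity counts for one pair from precomputed FFTs:
## independent uniform circular shifts in [1, T-1] of both trains are
## equivalent to a relative shift, read off the circular
## cross-correlation
surrogate_counts <- function(fa, fb, T, n_shifts) {
  ccf <- round(Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / T)
  s_a <- sample.int(T - 1L, n_shifts, replace = TRUE)
  s_b <- sample.int(T - 1L, n_shifts, replace = TRUE)
  list(observed = ccf[1L], counts = ccf[((s_a - s_b) %% T) + 1L])
}

#' Surrogate test for functional connection between two spike trains
#'
#' Two neurons are functionally connected when their observed
#' coactivity count exceeds the nearest-rank 95th percentile of counts
#' obtained from `n_shifts` surrogates, each applying independent
#' uniform circular shifts (1..T-1 frames) to both binary trains, and
#' the observed count is at least 1.
#'
#' @param train_a,train_b binary vectors of equal length T >= 10.
#' @param n_shifts number of surrogates, default 1000.
#' @param percentile cut on the surrogate distribution, default 95.
#' @param seed integer seed for the surrogate shifts.
#' @return logical, with attributes `observed` and `threshold`.
#' @export
connection_test <- function(train_a, train_b, n_shifts = 1000L,
                            percentile = 95, seed = 1L) {
  T <- length(train_a)
  if (length(train_b) != T) stop("trains must have equal length")
  if (T < 10L) stop("trains too short (need >= 10 frames)")
  a <- as.numeric(train_a > 0); b <- as.numeric(train_b > 0)
  obs <- sum(a * b)
  if (obs < 1) return(structure(FALSE, observed = obs, threshold = NA_real_))
  with_seed(seed, {
    sc <- surrogate_counts(stats::fft(a), stats::fft(b), T, n_shifts)
    thr <- nearest_rank(sc$counts, percentile)
    structure(obs > thr, observed = obs, threshold = thr)
  })
}

#' Build the functional-connectivity graph
#'
#' Applies the circular-shift surrogate test to every neuron pair of a
#' binary event matrix and collects the significant coactivations into
#' an undirected graph with per-neuron node degrees and the
#' Fisher-Pearson skewness of the degree distribution.
#'
#' @param binary 0/1 matrix (kept neurons x frames), >= 2 neurons.
#' @param n_shifts surrogates per pair, default 1000.
#' @param percentile surrogate cut, default 95.
#' @param seed integer seed.
#' @return object of class `functional_graph`: `n_nodes`, `edges`
#'   (two-column matrix of neuron indices), `degree`, `skewness`,
#'   `config`.
#' @export
build_graph <- function(binary, n_shifts = 1000L, percentile = 95, seed = 1L) {
  n <- nrow(binary)
  if (is.null(n) || n < 2L) stop("need at least 2 neurons")
  T <- ncol(binary)
  b <- (binary > 0) * 1
  active <- rowSums(b) > 0
  ffts <- vector("list", n)
  for (i in which(active)) ffts[[i]] <- stats::fft(b[i, ])

  edges <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("a", "b")))
  with_seed(seed + .seed_offset[["connectivity"]], {
    for (i in seq_len(n - 1L)) {
      if (!active[i]) next
      for (j in (i + 1L):n) {
        if (!active[j]) next
        sc <- surrogate_counts(ffts[[i]], ffts[[j]], T, n_shifts)
        if (sc$observed >= 1 &&
            sc$observed > nearest_rank(sc$counts, percentile))
          edges <- rbind(edges, c(i, j))
      }
    }
  })
  degree <- tabulate(c(edges), nbins = n)
  structure(list(n_nodes = n, edges = edges, degree = degree,
                 skewness = if (n >= 3L && stats::var(degree) > 0)
                   moment_skewness(degree) else NA_real_,
                 config = list(n_shifts = n_shifts, percentile = percentile,
                               seed = seed)),
            class = "functional_graph")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf("<functional_graph> %d nodes, %d edges, mean degree %.2f, skewness %.3f\n",
              x$n_nodes, nrow(x$edges), mean(x$degree), x$skewness))
  invisible(x)
}

#' Skewness of a degree distribution
#'
#' Fisher-Pearson moment coefficient g1 (no bias correction) of the
#' node degrees; heavier-than-symmetric right tails (a few hub
#' neurons) give positive skew.
#'
#' @param degrees integer vector, >= 3 nodes.
#' @return scalar skewness; `NA` with a warning at zero variance.
#' @export
degree_skewness <- function(degrees) moment_skewness(degrees)

#' Tuning similarity of connected vs non-connected pairs
#'
#' Absolute circular difference of preferred orientations (doubled-
#' angle metric, range [0, pi/2]) for every neuron pair with valid
#' tuning, split by whether the pair is an edge of the graph.
#'
#' @param graph a `functional_graph`.
#' @param theta per-neuron preferred orientation, radians in [0, pi);
#'   `NA` for neurons without a valid fit.
#' @return list with `connected` and `nonconnected` numeric vectors of
#'   |delta theta| and a `flagged` logical (TRUE when either side is
#'   empty).
#' @export
connected_pair_tuning_similarity <- function(graph, theta) {
  if (all(is.na(theta))) stop("no valid tuning fits")
  n <- graph$n_nodes
  adj <- matrix(FALSE, n, n)
  if (nrow(graph$edges))
    adj[graph$edges] <- adj[graph$edges[, 2:1, drop = FALSE]] <- TRUE
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  ok <- !is.na(theta[pairs[, 1L]]) & !is.na(theta[pairs[, 2L]])
  pairs <- pairs[ok, , drop = FALSE]
  d2 <- theta[pairs[, 1L]] - theta[pairs[, 2L]]
  dth <- abs(atan2(sin(2 * d2), cos(2 * d2))) / 2
  conn <- adj[pairs]
  list(connected = dth[conn], nonconnected = dth[!conn],
       flagged = !any(conn) || all(conn))
}
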