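#' High-coactivity frame filter
#'
#' @param binary 0/1 matrix, neurons x frames.
#' @param min_coactive minimum simultaneously active neurons, default 3.
#' @return integer indices of retained frames.
#' @export
filter_frames <- function(binary, min_coactive = 3L) {
  which(colSums(binary > 0) >= min_coactive)
}

## pairwise Jaccard similarity between binary frame vectors (columns)
jaccard_similarity <- function(cols) {
  b <- (cols > 0) * 1
  inter <- t(b) %*% b
  act <- colSums(b)
  uni <- outer(act, act, "+") - inter
  s <- inter / uni
  s[uni == 0] <- 0
  s
}

#' Drop frames without a similar partner
#'
#' Single-linkage clustering on Jaccard distance merges a frame at the
#' distance to its nearest neighbour, so frames whose merge height is
#' >= 0.5 (no other frame with Jaccard similarity strictly above 50%)
#' are excluded.
#'
#' @param frame_cols binary matrix, neurons x retained frames (>= 2).
#' @return indices (into the columns) of frames kept.
#' @export
jaccard_filter <- function(frame_cols) {
  nf <- ncol(frame_cols)
  if (nf < 2L) return(integer(0))
  s <- jaccard_similarity(frame_cols)
  diag(s) <- 0
  which(apply(s, 1L, max) > 0.5)
}

## contrast index: (mean within-cluster similarity - mean between) /
## (mean within + mean between), on Jaccard similarity
contrast_index <- function(sim, labels) {
  ut <- upper.tri(sim)
  same <- outer(labels, labels, "==")[ut]
  w <- sim[ut][same]; b <- sim[ut][!same]
  if (!length(w) || !length(b)) return(NA_real_)
  (mean(w) - mean(b)) / (mean(w) + mean(b))
}

#' Cluster similar frames into ensembles
#'
#' Ward-linkage hierarchical clustering on Jaccard distance between
#' frame vectors; the tree is cut at the number of clusters maximising
#' the contrast index (within- vs between-cluster Jaccard similarity)
#' over k = 2..min(kmax, n_frames - 1). All-identical frames collapse
#' to a single ensemble.
#'
#' @param frame_cols binary matrix, neurons x similar frames (>= 2).
#' @param kmax largest candidate cluster count, default 10.
#' @return list: `labels` (ensemble id per frame), `k`,
#'   `contrast_by_k` (named vector).
#' @export
cluster_ensembles <- function(frame_cols, kmax = 10L) {
  nf <- ncol(frame_cols)
  if (nf < 2L) stop("need at least 2 frames")
  sim <- jaccard_similarity(frame_cols)
  d <- stats::as.dist(1 - sim)
  if (all(d < 1e-12))
    return(list(labels = rep(1L, nf), k = 1L,
                contrast_by_k = stats::setNames(numeric(0), character(0))))
  hc <- stats::hclust(d, method = "ward.D2")
  ks <- 2:min(kmax, nf - 1L)
  contrast <- vapply(ks, function(k)
    contrast_index(sim, stats::cutree(hc, k)), numeric(1))
  names(contrast) <- ks
  if (all(is.na(contrast)))
    return(list(labels = rep(1L, nf), k = 1L, contrast_by_k = contrast))
  k <- ks[which.max(contrast)]
  labels <- merge_similar_clusters(sim, stats::cutree(hc, k))
  list(labels = labels, k = max(labels), contrast_by_k = contrast)
}

## collapse clusters that are still mutually similar: when the mean
## Jaccard similarity across two clusters exceeds the 50% frame-
## similarity cut the cut has fragmented one ensemble, not separated
## two
merge_similar_clusters <- function(sim, labels, cut = 0.5) {
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) < 2L) break
    best <- NULL; best_s <- cut
    for (i in seq_along(ids)[-length(ids)]) for (j in (i + 1L):length(ids)) {
      cross <- sim[labels == ids[i], labels == ids[j], drop = FALSE]
      if (mean(cross) > best_s) { best <- c(ids[i], ids[j]); best_s <- mean(cross) }
    }
    if (is.null(best)) break
    labels[labels == best[2L]] <- best[1L]
  }
  as.integer(factor(labels))
}

#' Surrogate-tested ensemble membership
#'
#' Candidate neurons are those whose Pearson (phi) correlation P with
#' the ensemble frame vector V_j is positive and exceeds the
#' nearest-rank 95th percentile of its own circular-shift surrogate
#' distribution. For every candidate pair (a, b), the ensemble weight
#' W = P_a * P_b * Co combines each train's correlation with V_j and
#' the pair's mutual correlation Co. Surrogate weights come from
#' independent uniform circular shifts of both trains (V_j held
#' fixed); a within-ensemble connection is placed when W exceeds the
#' 95th percentile of the surrogate weights and the pair is itself
#' functionally connected (observed coactivity above the same
#' surrogates' count percentile, at least 1 frame). A neuron is an
#' ensemble member when it holds at least one such connection.
#'
#' @param binary 0/1 matrix, neurons x frames.
#' @param V binary frame vector of the ensemble over all frames
#'   (nonempty support).
#' @param n_surrogates surrogates per pair, default 1000.
#' @param percentile surrogate cut, default 95.
#' @param seed integer seed.
#' @return list: `members` (neuron indices), `W` (pairwise weight
#'   matrix, `NA` where untestable), `excluded` (neurons with
#'   zero-variance trains, flagged out of testing).
#' @export
membership_test <- function(binary, V, n_surrogates = 1000L,
                            percentile = 95, seed = 1L) {
  if (!any(V > 0)) stop("ensemble frame vector V is empty")
  b <- (binary > 0) * 1
  n <- nrow(b); T <- ncol(b)
  v <- as.numeric(V > 0)
  mV <- mean(v); sV <- stats::sd(v)
  m <- rowMeans(b); s <- apply(b, 1L, stats::sd)
  testable <- s > 0
  ffts <- vector("list", n)
  fV <- stats::fft(v)
  ccfV <- vector("list", n)
  for (i in which(testable)) {
    ffts[[i]] <- stats::fft(b[i, ])
    ## S(a_shift_s, V) for s = 0..T-1
    ccfV[[i]] <- Re(stats::fft(Conj(ffts[[i]]) * fV, inverse = TRUE)) / T
  }
  corr_from_S <- function(S, mx, sx, my, sy) {
    (S - T * mx * my) / ((T - 1) * sx * sy)
  }
  ## candidate members must be significantly positively correlated with
  ## the ensemble frame vector (their own circular-shift surrogate
  ## distribution as the null): without this per-neuron gate, a
  ## strongly coupled pair that is only weakly or anti-correlated with
  ## V_j could still produce a large surrogate-beating weight through
  ## its mutual correlation alone
  P <- rep(NA_real_, n)
  for (i in which(testable))
    P[i] <- corr_from_S(ccfV[[i]][1L], m[i], s[i], mV, sV)
  W <- matrix(NA_real_, n, n)
  conn <- matrix(FALSE, n, n)
  with_seed(seed + .seed_offset[["ensembles"]], {
    P_sig <- rep(FALSE, n)
    for (i in which(testable & P > 0)) {
      si <- sample.int(T - 1L, n_surrogates, replace = TRUE)
      SP <- corr_from_S(ccfV[[i]][si + 1L], m[i], s[i], mV, sV)
      P_sig[i] <- P[i] > nearest_rank(SP, percentile)
    }
    idx <- which(P_sig)
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        a <- idx[ii]; bb <- idx[jj]
        ccf_ab <- Re(stats::fft(Conj(ffts[[a]]) * ffts[[bb]],
                                inverse = TRUE)) / T
        Pa <- P[a]; Pb <- P[bb]
        Co <- corr_from_S(ccf_ab[1L], m[a], s[a], m[bb], s[bb])
        W[a, bb] <- W[bb, a] <- Pa * Pb * Co
        sa <- sample.int(T - 1L, n_surrogates, replace = TRUE)
        sb <- sample.int(T - 1L, n_surrogates, replace = TRUE)
        SPa <- corr_from_S(ccfV[[a]][sa + 1L], m[a], s[a], mV, sV)
        SPb <- corr_from_S(ccfV[[bb]][sb + 1L], m[bb], s[bb], mV, sV)
        counts_s <- ccf_ab[((sa - sb) %% T) + 1L]
        SCo <- corr_from_S(counts_s, m[a], s[a], m[bb], s[bb])
        sw <- SPa * SPb * SCo
        ## a within-ensemble connection needs both a significant
        ## ensemble weight and a significant pairwise coactivation
        ## (the pair must itself be functionally connected)
        if (W[a, bb] > nearest_rank(sw, percentile) &&
            ccf_ab[1L] >= 1 &&
            ccf_ab[1L] > nearest_rank(counts_s, percentile))
          conn[a, bb] <- conn[bb, a] <- TRUE
      }
    }
  })
  list(members = which(rowSums(conn) > 0), W = W, P = P,
       excluded = which(!testable))
}

#' Detect neuronal ensembles from binary activity
#'
#' Full ensemble pipeline: retain frames with at least `min_coactive`
#' coactive neurons, drop frames without a >50% Jaccard partner,
#' Ward-cluster the rest into ensembles (contrast-index cut), build
#' each ensemble's frame vector V_j over all frames, and assign neuron
#' membership by the surrogate-tested ensemble-weight rule.
#'
#' @param binary 0/1 matrix, neurons x frames.
#' @param min_coactive minimum coactive neurons per frame, default 3.
#' @param n_surrogates surrogates per pair in the membership test.
#' @param percentile surrogate cut, default 95.
#' @param kmax largest candidate ensemble count, default 10.
#' @param seed integer seed.
#' @return object of class `ensemble_set`: `retained_frames`,
#'   `similar_frames`, `ensemble_of_frame` (labels aligned with
#'   `similar_frames`), `V` (ensembles x frames binary matrix),
#'   `membership` (neurons x ensembles logical), `n_ensembles`,
#'   `contrast_by_k`, `counts` (ensembles per neuron).
#' @export
detect_ensembles <- function(binary, min_coactive = 3L, n_surrogates = 1000L,
                             percentile = 95, kmax = 10L, seed = 1L) {
  n <- nrow(binary); T <- ncol(binary)
  empty <- function() structure(
    list(retained_frames = integer(0), similar_frames = integer(0),
         ensemble_of_frame = integer(0),
         V = matrix(0, 0L, T), membership = matrix(FALSE, n, 0L),
         n_ensembles = 0L, contrast_by_k = numeric(0),
         counts = rep(0L, n)),
    class = "ensemble_set")

  retained <- filter_frames(binary, min_coactive)
  if (length(retained) < 2L) return(empty())
  sim_keep <- jaccard_filter(binary[, retained, drop = FALSE])
  if (length(sim_keep) < 2L) return(empty())
  similar <- retained[sim_keep]
  cl <- cluster_ensembles(binary[, similar, drop = FALSE], kmax = kmax)
  k <- max(cl$labels)
  V <- matrix(0, k, T)
  for (j in seq_len(k)) V[j, similar[cl$labels == j]] <- 1
  membership <- matrix(FALSE, n, k)
  for (j in seq_len(k)) {
    mt <- membership_test(binary, V[j, ], n_surrogates = n_surrogates,
                          percentile = percentile, seed = seed + j)
    membership[mt$members, j] <- TRUE
  }
  structure(list(retained_frames = retained, similar_frames = similar,
                 ensemble_of_frame = cl$labels, V = V,
                 membership = membership, n_ensembles = k,
                 contrast_by_k = cl$contrast_by_k,
                 counts = rowSums(membership)),
            class = "ensemble_set")
}

#' @export
print.ensemble_set <- function(x, ...) {
  cat(sprintf("<ensemble_set> %d ensemble(s) over %d similar frames; %d member neuron(s)\n",
              x$n_ensembles, length(x$similar_frames), sum(x$counts > 0)))
  invisible(x)
}

#' Ensembles-per-neuron summary
#'
#' @param membership neurons x ensembles logical matrix (or an
#'   `ensemble_set`).
#' @return list: `counts` per neuron, `fractions` of neurons in 0, 1,
#'   2, >2 ensembles, `mean_neurons_per_ensemble`.
#' @export
ensembles_per_neuron <- function(membership) {
  if (inherits(membership, "ensemble_set")) membership <- membership$membership
  counts <- rowSums(membership)
  n <- length(counts)
  fractions <- c(`0` = mean(counts == 0), `1` = mean(counts == 1),
                 `2` = mean(counts == 2), `>2` = mean(counts > 2))
  list(counts = counts, fractions = fractions,
       mean_neurons_per_ensemble = if (ncol(membership)) mean(colSums(membership)) else NA_real_)
}
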