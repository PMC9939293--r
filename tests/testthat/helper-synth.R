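# shared fixture builders and scoring helpers

# F1 score of a predicted member set against a true member set
member_f1 <- function(pred, truth) {
  tp <- length(intersect(pred, truth))
  fp <- length(setdiff(pred, truth))
  fn <- length(setdiff(truth, pred))
  if (tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# generator config with flat (untuned) neurons, for planted-ensemble work
flat_config <- function(seed, n, ...) {
  synth_config(seed = seed, n_neurons = n,
               tuning_params = data.frame(theta = rep(0, n), K = rep(1, n),
                                          A = rep(0, n), b = rep(0, n)),
               ni_gains = matrix(1, n, 20), ...)
}

# a small deterministic recording for I/O and preprocessing tests
small_recording <- function(seed = 1, n = 12) {
  generate_population(synth_config(seed = seed, n_neurons = n))$recording
}

# scripted 2-Hz path with an exact 70/30 stimulus/non-stimulus split of
# masked samples (one fast crossing step, all other steps 3 cm at 2 Hz)
split_7030_path <- function() {
  xs <- 31.5; xn <- 10.5
  y <- 1; dir <- 1
  path <- matrix(NA_real_, 101, 2)
  path[1, ] <- c(xs, y)
  for (i in 2:71) {            # 70 masked samples in the stimulus half
    if (y + dir * 3 > 40 || y + dir * 3 < 1) dir <- -dir
    y <- y + dir * 3
    path[i, ] <- c(xs, y)
  }
  path[72, ] <- c(xn, y)       # fast crossing, lands in non-stimulus half
  for (i in 73:101) {          # 29 more masked samples, non-stimulus half
    if (y + dir * 3 > 40 || y + dir * 3 < 1) dir <- -dir
    y <- y + dir * 3
    path[i, ] <- c(xn, y)
  }
  colnames(path) <- c("x", "y")
  attr(path, "rate") <- 2
  path
}
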