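test_that("neuropil correction is the printed subtraction", {
  expect_equal(neuropil_correct(100, 40, 0.5), 80)
  expect_equal(neuropil_correct(100, 40, 0), 100)
  F <- matrix(rnorm(20, 100), 4)
  expect_equal(neuropil_correct(F, F, 0.5), F / 2)
  expect_error(neuropil_correct(F, F[1:2, ]), "shape")
  expect_error(neuropil_correct(100, 40, 1.5), "coeff")
})

test_that("density-mode F0 finds the dominant level", {
  set.seed(1)
  tr <- c(rep(50, 190), rep(200, 10)) + rnorm(200, 0, 0.5)
  expect_lt(abs(estimate_f0_mode(tr) - 50), 2)

  # bimodal 70/30: the mode sits at the heavy component; frozen KDE oracle
  set.seed(2)
  bi <- c(rnorm(700, 10, 1), rnorm(300, 20, 1))
  d <- stats::density(bi, bw = "nrd0", n = 512, from = min(bi), to = max(bi))
  oracle <- d$x[which.max(d$y)]
  expect_equal(estimate_f0_mode(bi), oracle)
  expect_lt(abs(oracle - 10), 1)

  set.seed(3)
  g <- rnorm(500, 100, 4)
  expect_lt(abs(estimate_f0_mode(g) - 100), 4)

  expect_equal(estimate_f0_mode(rep(7, 200)), 7)
  expect_error(estimate_f0_mode(c(rep(1, 150), NA)), "finite")
  expect_error(estimate_f0_mode(rnorm(50)), "100 samples")
})

test_that("window F0 is the pre-stimulus mean", {
  sch <- generate_schedule(synth_config(seed = 1, schedule_kind = "plasticity"))
  onset <- which(sch$label != "gray")[1]
  nw <- epoch_frames(10, 4.22)
  tr <- rep(80, nrow(sch))
  expect_equal(estimate_f0_window(tr, sch), 80)
  ramp <- rep(0, nrow(sch))
  ramp[(onset - nw):(onset - 1)] <- seq(0, 10, length.out = nw)
  expect_equal(estimate_f0_window(ramp, sch), 5)
  expect_error(estimate_f0_window(tr, sch, window = 500), "window")
})

test_that("dF/F0 is the fractional change", {
  expect_equal(compute_dff(100, 100), 0)
  expect_equal(compute_dff(105, 100), 0.05)
  expect_equal(compute_dff(90, 100), -0.1)
  expect_error(compute_dff(100, 0), "F0")
})

test_that("dF/F0 of corrected traces is scale invariant", {
  set.seed(4)
  F <- matrix(runif(60, 90, 110), 3)
  Fneu <- matrix(runif(60, 10, 30), 3)
  f0 <- c(80, 90, 100)
  a <- compute_dff(neuropil_correct(F, Fneu), f0)
  b <- compute_dff(neuropil_correct(3.7 * F, 3.7 * Fneu), 3.7 * f0)
  expect_equal(a, b)
})

test_that("event thresholding cuts at mean + 2 SD, strictly", {
  z <- matrix(0, 1, 50)
  out <- threshold_events(z)
  expect_true(all(out$events == 0) && all(out$binary == 0))

  tr <- matrix(c(rep(0, 49), 10), 1)
  out <- threshold_events(tr)
  expect_equal(which(out$binary[1, ] == 1), 50L)

  set.seed(5)
  hn <- matrix(abs(rnorm(500)), 1)
  out <- threshold_events(hn)
  thr <- mean(hn) + 2 * sd(hn)
  expect_equal(out$binary[1, ], as.numeric(hn[1, ] > thr))
  expect_true(all(out$events <= hn))      # never increases amplitudes
  expect_true(all(hn[out$binary == 1] > 0))
})

test_that("noiseless events recover ground-truth spike frames", {
  cfg <- flat_config(seed = 31, n = 20, baseline_rate = 0.1, noise_sd = 0,
                     deconv_jitter_sd = 0.02)
  sim <- generate_population(cfg)
  ev <- threshold_events(sim$recording$deconv)
  truth <- sim$truth$spikes >= 1
  recovered <- sum(ev$binary[truth] == 1) / sum(truth)
  expect_gte(recovered, 0.95)
})

test_that("QC keeps peaks strictly above 10% and trims F0 outliers", {
  dff <- rbind(rep(0.09, 100), rep(0.11, 100))
  f0 <- c(100, 100)
  kept <- qc_filter(dff, f0, "multistim")
  expect_equal(as.logical(kept), c(FALSE, TRUE))

  # plasticity: F0 exactly at the mean stays in, far outliers go
  dff <- matrix(0.2, 21, 100)
  f0 <- c(rep(100, 20), 300)
  kept <- qc_filter(dff, f0, "plasticity")
  expect_true(kept[1])
  expect_false(kept[21])
  expect_false(attr(qc_filter(dff, f0, "plasticity", novel_dff = 0.02), "low_quality"))
  expect_true(attr(qc_filter(dff, f0, "plasticity", novel_dff = 0.005), "low_quality"))
})

test_that("preprocess_recording wires the stages together", {
  rec <- small_recording(seed = 6)
  tr <- preprocess_recording(rec, "multistim")
  expect_s3_class(tr, "activity_traces")
  expect_equal(dim(tr$dff), dim(rec$F))
  expect_true(all(tr$binary %in% c(0, 1)))
  expect_true(all(tr$f0[tr$kept] > 0))
})
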