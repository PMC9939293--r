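test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(seed = 11, n_neurons = 10)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a$recording$F, b$recording$F)
  expect_identical(a$recording$deconv, b$recording$deconv)
  expect_identical(a$truth$spikes, b$truth$spikes)
  d1 <- generate_dendrites(n = 50, seed = 4)
  d2 <- generate_dendrites(n = 50, seed = 4)
  expect_identical(d1, d2)
})

test_that("evoked spike counts are ordered by the von Mises rates", {
  # one strongly tuned neuron; theta off the stimulus grid so all four
  # rates are distinct, amplitude large enough that Poisson noise
  # cannot reorder them
  n <- 1L
  th <- 30 * pi / 180
  cfg <- synth_config(seed = 9, n_neurons = n, baseline_rate = 0, noise_sd = 0,
                      tuning_params = data.frame(theta = th, K = 1.5,
                                                 A = 60, b = 0),
                      ni_gains = matrix(0, n, 20))
  sim <- generate_population(cfg)
  sch <- sim$recording$schedule
  counts <- vapply(GRATING_ANGLES, function(a)
    sum(sim$truth$spikes[1, sch$label == paste0("grating_", a)]), numeric(1))
  rates <- von_mises_rate(GRATING_ANGLES * pi / 180, th, 1.5, 60, 0)
  expect_equal(order(counts), order(rates))
  expect_equal(which.max(counts), which.max(rates))
})

test_that("mean spike rate matches the configured rate within 3 SE", {
  cfg <- flat_config(seed = 21, n = 30, baseline_rate = 0.3)
  sim <- generate_population(cfg)
  sch <- sim$recording$schedule
  gray <- sch$label == "gray"
  lam <- 0.3 / 4.22
  m <- mean(sim$truth$spikes[, gray])
  se <- sqrt(lam / (30 * sum(gray)))
  expect_lt(abs(m - lam), 3 * se)
})

test_that("planted ensembles coactivate members at the expected rate", {
  cfg <- flat_config(seed = 13, n = 20, baseline_rate = 0,
                     ensemble_spec = list(list(members = 1:10, rate = 0.2,
                                               participation = 1)))
  sim <- generate_population(cfg)
  ev <- sim$truth$event_frames[[1]]
  expect_true(length(ev) > 0)
  # participation 1: all members spike in every event frame
  expect_true(all(sim$truth$spikes[1:10, ev] >= 1))
  # empirical event rate within 3 binomial SDs of expectation
  T <- ncol(sim$truth$spikes)
  p <- 0.2 / 4.22
  expect_lt(abs(length(ev) - T * p), 3 * sqrt(T * p * (1 - p)))
})

test_that("an isolated spike decays with the configured calcium tau", {
  # silent population except for rare single-neuron events, no noise
  cfg <- flat_config(seed = 1, n = 2, baseline_rate = 0, noise_sd = 0,
                     calcium_tau = 2.0, deconv_jitter_sd = 0,
                     ensemble_spec = list(list(members = 1L, rate = 0.01,
                                               participation = 1)))
  sim <- generate_population(cfg)
  spikes <- sim$truth$spikes[1, ]
  fr <- sim$recording$frame_rate
  ev <- which(spikes == 1)
  # pick an event with 10 clean frames after it
  iso <- ev[vapply(ev, function(t)
    t + 10 <= length(spikes) && sum(spikes[(t + 1):(t + 10)]) == 0,
    logical(1))][1]
  expect_false(is.na(iso))
  fcorr <- neuropil_correct(sim$recording$F, sim$recording$Fneu)
  tail_tr <- fcorr[1, iso:(iso + 10)] - min(fcorr[1, ])
  tfit <- -1 / (fr * coef(stats::lm(log(tail_tr) ~ seq_along(tail_tr)))[[2]])
  expect_lt(abs(tfit - 2.0) / 2.0, 0.10)
})

test_that("dendrite generator hits the target E/I correlation", {
  dd <- generate_dendrites(n = 2000, target_r = 0.43, seed = 7)
  r <- ei_correlation(dd)$r
  expect_lt(abs(r - 0.43), 0.05)
  d0 <- generate_dendrites(n = 2000, target_r = 0, seed = 8)
  expect_lt(abs(ei_correlation(d0)$r), 3 / sqrt(2000))
  expect_error(generate_dendrites(n = 100, target_r = 1.2), "target_r")
  expect_error(generate_dendrites(n = 2), "n >= 3")
})

test_that("force generation recovers scripted geometry", {
  # parked at sensor 1: all force on f1
  fp <- generate_forceplate(data.frame(t = c(0, 1), x = 0, y = 0))
  expect_true(all(fp$forces[, 1] == 1 & fp$forces[, 2:4] == 0))
  # plate centre: four equal forces
  fc <- generate_forceplate(data.frame(t = c(0, 1), x = 21, y = 21))
  expect_true(all(abs(fc$forces - 0.25) < 1e-12))
  expect_error(generate_forceplate(data.frame(t = 0:1, x = 50, y = 1)),
               "outside")
})
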