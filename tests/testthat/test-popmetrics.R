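# brute-force evaluation of the sparseness formula, kept independent of
# the implementation
sparseness_oracle <- function(R, n = length(R)) {
  R <- pmax(R, 0)
  (1 - (sum(R) / n)^2 / (sum(R^2) / n)) / (1 - 1 / n)
}

test_that("population sparseness hits its analytic extremes", {
  expect_equal(population_sparseness(c(5, rep(0, 9))), 1)
  expect_equal(population_sparseness(rep(2, 10)), 0)
  expect_equal(population_sparseness(c(1, 1, 0, 0)), 2 / 3)
  expect_warning(s <- population_sparseness(rep(0, 5)), "undefined")
  expect_true(is.na(s))
  expect_error(population_sparseness(c(1), n = 1), "n >= 2")
})

test_that("sparseness agrees with the brute-force formula on random vectors", {
  set.seed(10)
  for (i in 1:1000) {
    n <- sample(2:12, 1)
    R <- round(runif(n, 0, 3), 2)
    if (all(R == 0)) R[1] <- 1
    expect_equal(population_sparseness(R), sparseness_oracle(R))
  }
})

test_that("sparseness is scale invariant and decreases as activity spreads", {
  set.seed(11)
  R <- runif(8)
  expect_equal(population_sparseness(R), population_sparseness(5.5 * R))
  # spreading constant total over k of 10 neurons: sparser when fewer
  vals <- vapply(1:9, function(k)
    population_sparseness(c(rep(1 / k, k), rep(0, 10 - k))), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("selectivity index matches its frame-count arithmetic", {
  expect_equal(selectivity_index(rep(0.4, 13)), 0)
  expect_equal(selectivity_index(c(1, rep(0, 12))), 12 / 13)
  expect_equal(selectivity_index(c(1, 1, rep(0, 11))), 11 / 13)
  expect_equal(selectivity_index(2 * c(1, 1, rep(0, 11))),
               selectivity_index(c(1, 1, rep(0, 11))))
  expect_warning(s <- selectivity_index(rep(0, 13)), "undefined")
  expect_true(is.na(s))
})

test_that("von Mises fits recover exact generative parameters", {
  th <- 45 * pi / 180
  resp <- von_mises_rate(c(0, 45, 90, 135) * pi / 180, th, 2, 1, 0.1)
  fit <- fit_von_mises(resp)
  expect_true(fit$valid)
  truth <- c(theta = th, K = 2, A = 1, b = 0.1)
  expect_lt(max(abs(coef(fit) - truth) / truth), 1e-3)
  # the fitted curve reproduces its inputs at R2 = 1
  expect_equal(predict(fit), resp, tolerance = 1e-6)

  # flat responses are invalid
  expect_false(fit_von_mises(rep(0.3, 4))$valid)

  # rotating the angle labels by 90 degrees rotates theta by 90 mod 180
  fit2 <- fit_von_mises(resp, angles_deg = c(0, 45, 90, 135) + 90)
  d <- abs(atan2(sin(2 * (fit2$theta - (th + pi / 2))),
                 cos(2 * (fit2$theta - (th + pi / 2))))) / 2
  expect_lt(d, 1e-3)
  expect_lt(abs(fit2$K - 2) / 2, 1e-3)
})

test_that("FWHM follows the printed closed form", {
  expect_equal(fwhm(1), acos(log(cosh(1))), tolerance = 1e-12)
  expect_lt(abs(fwhm(1) - 1.122), 1e-3)
  # K -> 0 limit is pi/2
  expect_lt(abs(fwhm(1e-6) - pi / 2), 1e-3)
  # strictly decreasing in K, stable at large K
  ks <- c(0.1, 0.5, 1, 2, 5, 10, 50, 200)
  expect_true(all(diff(fwhm(ks)) < 0))
  expect_error(fwhm(0), "K must be")
})

test_that("neural overlap matches hand-computed dot products", {
  # identical frames: overlap 1 at every lag
  v <- c(0.2, 0.1, 0, 0.3)
  m <- matrix(v, 4, 60)
  oc <- neural_overlap(m, 1:5, max_lag = 10)
  expect_true(all(abs(oc$overlap - 1) < 1e-12))

  # alternating orthogonal frames: overlap 0 at odd lags, 1 at even
  m2 <- matrix(c(1, 0, 0, 1), 2, 40)[, rep(1:2, 20)]
  m2 <- rbind(c(1, 0), c(0, 1))[, rep(1:2, 20)]
  oc2 <- neural_overlap(m2, 1:6, max_lag = 8)
  expect_true(all(abs(oc2$overlap[c(1, 3, 5, 7)]) < 1e-12))
  expect_true(all(abs(oc2$overlap[c(2, 4, 6, 8)] - 1) < 1e-12))

  # hand value 1/sqrt(2)
  m3 <- cbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 0))
  oc3 <- neural_overlap(m3, 1, max_lag = 2)
  expect_equal(oc3$overlap[1], 1 / sqrt(2))
  expect_error(neural_overlap(m3, 1:2, max_lag = 2), "window too short")

  # bounded and scale invariant
  set.seed(12)
  m4 <- matrix(rnorm(300), 5)
  oc4 <- neural_overlap(m4, 1:8, max_lag = 5)
  oc5 <- neural_overlap(4.2 * m4, 1:8, max_lag = 5)
  expect_true(all(abs(oc4$overlap) <= 1 + 1e-12))
  expect_equal(oc4$overlap, oc5$overlap)
})

test_that("overlap decay fits recover tau and b and pin 1 at t = 0", {
  set.seed(13)
  t <- 1:50
  y <- (1 - 0.3) * exp(-0.1 * t) + 0.3 + rnorm(50, 0, 0.01)
  fit <- fit_overlap_decay(y)
  expect_lt(abs(fit$tau + 0.1) / 0.1, 0.10)
  expect_lt(abs(fit$b - 0.3) / 0.3, 0.10)
  expect_equal(predict(fit, 0), 1)

  # constant curve: b absorbs the level and the fit is flagged degenerate
  const <- fit_overlap_decay(rep(0.4, 20))
  expect_true(const$flagged || abs(const$b - 0.4) < 0.05)
  expect_equal(predict(const, 0), 1)
  expect_error(fit_overlap_decay(c(1, 0.5, 0.4)), "at least 5")
})

test_that("plasticity ratios are identity on identical sessions", {
  s <- list(auc = 1.2, active_fraction = 0.5, high_responder_fraction = 0.2,
            tau = -0.15)
  pr <- plasticity_ratios(s, s)
  expect_true(all(pr$ratio == 1))
  # doubled decay rate shows up as a tau ratio of 2
  s2 <- s; s2$tau <- -0.30
  pr2 <- plasticity_ratios(s, s2)
  expect_equal(pr2$ratio[pr2$metric == "tau"], 2)
  # zero denominators are flagged, not divided
  s0 <- s; s0$auc <- 0
  pr3 <- plasticity_ratios(s0, s)
  expect_true(pr3$flagged[pr3$metric == "auc"])
  expect_true(is.na(pr3$ratio[pr3$metric == "auc"]))
})
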