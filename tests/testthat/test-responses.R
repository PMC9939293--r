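make_traces <- function(dff, schedule, fr = 4.22) {
  list(dff = dff, schedule = schedule, frame_rate = fr)
}

test_that("trial averaging is the arithmetic mean over cycles", {
  sch <- generate_schedule(synth_config(seed = 2))
  n <- 3
  dff <- matrix(0, n, nrow(sch))
  # constant response in every grating_0 epoch: average equals any trial
  dff[, sch$label == "grating_0"] <- 0.2
  ta <- trial_average(make_traces(dff, sch), "grating_0")
  expect_equal(ta$n_trials, 8L)
  expect_equal(dim(ta$avg), c(n, 13L))
  expect_true(all(abs(ta$avg - 0.2) < 1e-12))

  # alternating +x / -x trials cancel
  idx <- which(sch$label == "grating_45")
  ep <- schedule_epochs(generate_schedule(synth_config(seed = 2)))
  stim_eps <- ep[ep$label == "grating_45", ]
  for (k in seq_len(nrow(stim_eps)))
    dff2 <- NULL
  dff2 <- matrix(0, 1, nrow(sch))
  for (k in seq_len(nrow(stim_eps)))
    dff2[1, stim_eps$start[k]:stim_eps$end[k]] <- ifelse(k %% 2 == 0, 0.3, -0.3)
  ta2 <- trial_average(make_traces(dff2, sch), "grating_45")
  expect_true(all(abs(ta2$avg) < 1e-12))

  # random trials: average equals the hand-computed mean
  set.seed(7)
  dff3 <- matrix(rnorm(nrow(sch)), 1)
  ta3 <- trial_average(make_traces(dff3, sch), "ni_1")
  ni_eps <- ep[ep$label == "ni_1", ]
  mat <- t(vapply(seq_len(nrow(ni_eps)), function(k)
    dff3[1, ni_eps$start[k]:(ni_eps$start[k] + 12)], numeric(13)))
  expect_equal(ta3$avg[1, ], colMeans(mat))
  expect_error(trial_average(make_traces(dff3, sch), "nope"), "not in schedule")
})

test_that("activity classification applies strict thresholds and the paired test", {
  sch <- generate_schedule(synth_config(seed = 2))
  n_tr <- 8
  build_ta <- function(stim, gray) {
    # synthetic trial_average: trial means given directly
    structure(list(stim_trial_means = matrix(stim, 1, n_tr),
                   gray_trial_means = matrix(gray, 1, n_tr),
                   gray_avg = matrix(gray[1], 1, 13),
                   avg = matrix(stim[1], 1, 13),
                   n_trials = n_tr, dt = 1 / 4.22, stimulus = "x"),
              class = "trial_average")
  }
  # mean exactly 5%: not active_high (strict >)
  set.seed(1)
  ta <- build_ta(rep(0.05, n_tr) + c(-.001, .001), rnorm(n_tr, 0, 1e-4))
  cl <- classify_active(ta)
  expect_false(cl$active_high)

  # clearly evoked, consistent trials: active_high
  ta <- build_ta(rnorm(n_tr, 0.2, 0.01), rnorm(n_tr, 0, 0.01))
  cl <- classify_active(ta)
  expect_true(cl$active_high)
  expect_equal(cl$class, "active_high")
  # matches a direct paired t oracle
  d <- ta$stim_trial_means[1, ] - ta$gray_trial_means[1, ]
  expect_equal(cl$p_value, t.test(d)$p.value)

  # stimulus identical to gray: nonresponsive
  same <- rnorm(n_tr, 0.1, 0.02)
  cl <- classify_active(build_ta(same, same))
  expect_equal(cl$class, "nonresponsive")
  expect_true(cl$flagged)  # zero-variance differences, t test undefined
})

test_that("active_high implies active_low", {
  sim <- generate_population(synth_config(seed = 17, n_neurons = 30))
  tr <- preprocess_recording(sim$recording, "multistim")
  ta <- trial_average(tr, "grating_90")
  cl <- classify_active(ta)
  expect_true(all(!cl$active_high | cl$active_low))
})

test_that("AUC is the trapezoidal integral", {
  # constant 0.1 spanning 3 s
  tr <- rep(0.1, 13); dt <- 3 / 12
  expect_equal(compute_auc(tr, dt), 0.3)
  # single-frame triangle of height h
  expect_equal(compute_auc(c(0, 2, 0), 0.5), 2 * 0.5)
  # arbitrary trace equals the brute-force trapezoid sum
  set.seed(8)
  y <- rnorm(13); dt <- 1 / 4.22
  brute <- sum((y[-1] + y[-13]) / 2 * dt)
  expect_equal(compute_auc(y, dt), brute)
  # linear in the trace and in dt
  expect_equal(compute_auc(3 * y, dt), 3 * compute_auc(y, dt))
  expect_equal(compute_auc(y, 2 * dt), 2 * compute_auc(y, dt))
  expect_error(compute_auc(numeric(0), dt), "empty")
})

test_that("response fractions count strict threshold crossings", {
  expect_equal(unname(response_fractions(rep(0, 10))), 0)
  expect_equal(unname(response_fractions(c(rep(0.2, 5), rep(0.1, 5)))), 0.5)
  set.seed(9)
  m <- runif(40, 0, 0.3)
  expect_equal(unname(response_fractions(m, 0.15)), mean(m > 0.15))
  expect_equal(active_fraction(c(TRUE, TRUE, FALSE, FALSE), 8), 0.25)
  expect_error(response_fractions(numeric(0)), "empty")
})

test_that("classified active fraction is monotone in the threshold", {
  sim <- generate_population(synth_config(seed = 23, n_neurons = 30))
  tr <- preprocess_recording(sim$recording, "multistim")
  ta <- trial_average(tr, "grating_0")
  fr <- vapply(c(0.02, 0.05, 0.10, 0.20), function(th)
    mean(classify_active(ta, high_threshold = th)$active_high), numeric(1))
  expect_true(all(diff(fr) <= 0))
})
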