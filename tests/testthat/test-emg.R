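make_emg <- function(make_channel, rate = 3000, dur = 2,
                     mvc = c(ta = 1, gm = 1)) {
  t <- seq(0, dur, by = 1 / rate)
  out <- tibble::tibble(
    time_s = t,
    ta_left = make_channel(t), ta_right = make_channel(t),
    gm_left = make_channel(t), gm_right = make_channel(t)
  )
  attr(out, "rate") <- rate
  attr(out, "mvc_mv") <- mvc
  out
}

test_that("a 100 Hz sinusoid yields an envelope plateau at A/sqrt(2)", {
  a <- 0.8
  rec <- make_emg(function(t) a * sin(2 * pi * 100 * t))
  env <- preprocess_emg(rec)
  core <- env$ta[env$time_s > 0.5 & env$time_s < 1.5]
  expect_lt(max(abs(core - a / sqrt(2))), 0.03 * a)
})

test_that("a 600 Hz component is attenuated at least 20 dB relative to
          100 Hz", {
  rec100 <- make_emg(function(t) sin(2 * pi * 100 * t))
  rec600 <- make_emg(function(t) sin(2 * pi * 600 * t))
  p100 <- max(preprocess_emg(rec100)$ta)
  p600 <- max(preprocess_emg(rec600)$ta[
    rec600$time_s > 0.5 & rec600$time_s < 1.5
  ])
  expect_lt(20 * log10(p600 / p100), -20)
})

test_that("normalizing by the trial's own envelope maximum gives peak 1", {
  rec <- make_emg(function(t) sin(2 * pi * 100 * t))
  env_raw <- preprocess_emg(rec, mvc_values = c(ta = 1, gm = 1))
  m <- max(env_raw$ta)
  env <- preprocess_emg(rec, mvc_values = c(ta = m, gm = m))
  expect_equal(max(env$ta), 1, tolerance = 1e-9)
})

test_that("invalid MVC values and missing channels are rejected", {
  rec <- make_emg(function(t) sin(2 * pi * 100 * t), dur = 0.5)
  expect_error(preprocess_emg(rec, mvc_values = c(ta = 0, gm = 1)), "MVC")
  expect_error(preprocess_emg(rec[, 1:3]), "missing EMG channels")
})

test_that("onset detection finds a 150 ms burst within 15 ms", {
  withr::with_seed(7, {
    t <- seq(-0.5, 1, by = 1 / 3000)
    env <- tibble::tibble(
      time_s = t,
      ta = 0.05 + abs(rnorm(length(t), 0, 0.002)) +
        0.5 * (t >= 0.15) * pmin((t - 0.15) / 0.05, 1)
    )
    onset <- detect_muscle_onset(env, 0, baseline_window = c(-0.4, -0.1))
    expect_lt(abs(onset - 0.15), 0.015)
  })
})

test_that("onset detection returns NA on a flat envelope and never gets
          earlier when k grows", {
  withr::with_seed(8, {
    t <- seq(-0.5, 1, by = 1 / 3000)
    flat <- tibble::tibble(time_s = t, ta = rep(0.05, length(t)))
    expect_true(is.na(detect_muscle_onset(flat, 0)))
    env <- tibble::tibble(
      time_s = t,
      ta = 0.05 + abs(rnorm(length(t), 0, 0.01)) +
        0.4 * (t >= 0.2) * pmin((t - 0.2) / 0.2, 1)
    )
    o3 <- detect_muscle_onset(env, 0, k = 3)
    o5 <- detect_muscle_onset(env, 0, k = 5)
    expect_gte(o5, o3)
  })
  expect_error(
    detect_muscle_onset(
      tibble::tibble(time_s = 0:10 / 10, ta = 0), 0,
      baseline_window = c(-0.4, -0.1)
    ),
    "no samples"
  )
})

test_that("the co-contraction index follows its ratio-times-sum form", {
  e <- 0.4
  expect_equal(compute_cci(rep(e, 10), rep(e, 10)), 2 * e) # ratio 1
  expect_equal(compute_cci(rep(0, 10), rep(1, 10)), 0) # silent antagonist
  expect_equal(compute_cci(rep(1, 5), rep(3, 5)), 4 / 3)
  expect_error(compute_cci(c(-1, 1), c(1, 1)), "non-negative")
})

test_that("CCI is symmetric, scale-equivariant and bounded", {
  withr::with_seed(9, {
    a <- abs(rnorm(100))
    b <- abs(rnorm(100))
    expect_equal(compute_cci(a, b), compute_cci(b, a))
    expect_equal(compute_cci(3 * a, 3 * b), 3 * compute_cci(a, b))
    expect_lte(max(cci_samples(a, b)), 2 * max(pmax(a, b)))
  })
})

test_that("trial features use the feedforward window and the
          onset-to-halt feedback period", {
  t <- seq(-0.5, 1.5, by = 1 / 3000)
  # equal constant envelopes: CCI = 2 * 0.3 everywhere, both features match
  env_const <- tibble::tibble(
    time_s = t, ta = rep(0.3, length(t)), gm = rep(0.3, length(t))
  )
  f <- emg_trial_features(env_const, 0, halt_time = 1)
  expect_equal(f$cci_feedforward, 0.6)
  expect_true(is.na(f$cci_feedback) || abs(f$cci_feedback - 0.6) < 1e-9)

  # CCI 1 before a detectable onset at ~0.2 s, 2 after
  ta <- ifelse(t >= 0.2, 2, 0.5)
  gm <- ifelse(t >= 0.2, 2, 0.5)
  env_step <- tibble::tibble(time_s = t, ta = ta, gm = gm)
  f2 <- emg_trial_features(env_step, 0, halt_time = 1)
  expect_equal(f2$cci_feedforward, 1)
  expect_equal(f2$cci_feedback, 4, tolerance = 0.01)
  expect_lt(abs(f2$ta_onset_time - 0.2), 0.01)

  # no detectable onset: feedback flagged missing, feedforward kept
  flat <- tibble::tibble(time_s = t, ta = rep(0.5, length(t)), gm = rep(0.5, length(t)))
  f3 <- emg_trial_features(flat, 0, halt_time = 1)
  expect_equal(f3$cci_feedforward, 1)
  expect_true(is.na(f3$cci_feedback))
  expect_true(is.na(f3$ta_onset_time))
})

test_that("simulated trials yield the group/trial co-contraction ordering", {
  cfg <- light_config()
  pf <- platform_profile(rate = cfg$kinematics$rate)
  withr::with_seed(71, {
    cci_f <- replicate(10, {
      e <- simulate_trial_emg(default_profile("Faller"), 3, pf, cfg)
      extract_emg_features(e)$cci_feedforward
    })
    cci_nf <- replicate(10, {
      e <- simulate_trial_emg(default_profile("Non-faller"), 3, pf, cfg)
      extract_emg_features(e)$cci_feedforward
    })
  })
  expect_gt(median(cci_f), median(cci_nf))
})
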