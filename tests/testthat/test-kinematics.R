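test_that("quiet-stance normalization subtracts the reference with the
          flexion-positive sign convention", {
  a <- tibble::tibble(time_s = c(0, 0.005), back = c(5, 7), ankle_left = c(2, 3))
  out <- normalize_to_quiet_stance(a, c(back = 5, ankle = 2))
  expect_equal(out$back, c(0, 2)) # raw at reference -> 0; above -> positive
  expect_equal(out$ankle_left, c(0, 1)) # joint-level reference reaches sides
  # zero reference is the identity
  expect_equal(normalize_to_quiet_stance(a, c(back = 0, ankle = 0)), a)
  expect_error(
    normalize_to_quiet_stance(a, c(back = 5)),
    "missing quiet-stance reference"
  )
})

test_that("bilateral averaging is the pointwise mean and rejects mismatch", {
  expect_equal(bilateral_average(rep(10, 5), rep(20, 5)), rep(15, 5))
  x <- rnorm(8)
  expect_equal(bilateral_average(x, x), x)
  expect_error(bilateral_average(1:4, 1:5), "length")
  expect_error(bilateral_average(NULL, 1:5), "both sides")
})

test_that("feedforward window is half-open with exactly 20 samples at 200 Hz", {
  t <- seq(-0.5, 0.5, by = 1 / 200)
  a <- tibble::tibble(time_s = t, back = rep(7, length(t)))
  expect_equal(feedforward_posture(a)$back, 7)
  # count the samples the window actually uses
  a2 <- tibble::tibble(time_s = t, back = as.numeric(t >= -0.1 & t < 0))
  expect_equal(feedforward_posture(a2)$back * sum(a2$back), sum(a2$back))
  expect_equal(sum(t >= -0.1 & t < 0), 20)
  # window before recording start errors
  short <- tibble::tibble(time_s = seq(-0.05, 0.5, by = 1 / 200), back = 0)
  expect_error(feedforward_posture(short), "before the start")
})

test_that("feedforward mean of a linear ramp equals the sampled closed form", {
  t <- seq(-0.5, 0.5, by = 1 / 200)
  slope <- 3
  a <- tibble::tibble(time_s = t, back = slope * t)
  sel <- t >= -0.1 & t < 0
  expect_equal(feedforward_posture(a)$back, slope * mean(t[sel]))
  # the sampled grid puts the mean at -52.5 ms for this alignment
  expect_equal(feedforward_posture(a)$back, -slope * 0.0525, tolerance = 1e-9)
})

test_that("feedback range splits signed excursions and floors at zero", {
  t <- seq(-0.1, 1, by = 1 / 200)
  halt <- 1
  zero <- tibble::tibble(time_s = t, back = 0)
  fr <- feedback_range(zero, 0, halt)
  expect_equal(fr$max_flexion, 0)
  expect_equal(fr$max_extension, 0)
  # full sine cycle inside the period reaches +1 and -1
  sine <- tibble::tibble(time_s = t, back = sin(2 * pi * t))
  fr2 <- feedback_range(sine, 0, halt)
  expect_equal(fr2$max_flexion, 1, tolerance = 1e-3)
  expect_equal(fr2$max_extension, 1, tolerance = 1e-3)
  # pure flexion has extension 0
  flex <- tibble::tibble(time_s = t, back = 3)
  fr3 <- feedback_range(flex, 0, halt)
  expect_equal(fr3$max_flexion, 3)
  expect_equal(fr3$max_extension, 0)
  expect_error(feedback_range(zero, 1, 1), "precede")
})

test_that("feedback range ignores sample order", {
  withr::with_seed(5, {
    t <- seq(0, 1, by = 0.01)
    x <- rnorm(length(t))
    a <- tibble::tibble(time_s = t, back = x)
    shuffle <- sample(length(t))
    b <- a[shuffle, ]
    expect_equal(feedback_range(a, 0, 1), feedback_range(b, 0, 1))
  })
})

test_that("normalization then feedforward commutes with a shared constant", {
  t <- seq(-0.2, 0.2, by = 1 / 200)
  raw <- tibble::tibble(time_s = t, back = sin(t) + 10)
  f1 <- feedforward_posture(normalize_to_quiet_stance(raw, c(back = 10)))
  raw2 <- raw
  raw2$back <- raw2$back + 5
  f2 <- feedforward_posture(normalize_to_quiet_stance(raw2, c(back = 15)))
  expect_equal(f1, f2)
})

test_that("synthetic non-fallers flex more before trial 3 than trial 1", {
  cfg <- light_config()
  pf <- platform_profile(rate = cfg$kinematics$rate)
  prof <- default_profile("Non-faller")
  withr::with_seed(61, {
    d <- replicate(40, {
      k1 <- simulate_trial_kinematics(prof, 1, pf, cfg)
      k3 <- simulate_trial_kinematics(prof, 3, pf, cfg)
      feedforward_posture(average_sides(k3))$knee -
        feedforward_posture(average_sides(k1))$knee
    })
  })
  expect_gt(mean(d > 0), 0.95)
})

test_that("trial feature extraction produces the full named set", {
  cfg <- light_config()
  pf <- platform_profile(rate = cfg$kinematics$rate)
  k <- simulate_trial_kinematics(default_profile(), 1, pf, cfg, seed = 3)
  feats <- extract_kinematic_features(k)
  expect_named(feats, c(
    paste0("ff_", c("ankle", "knee", "hip", "back")),
    paste0("fb_", c("ankle", "knee", "hip", "back"), "_flex"),
    paste0("fb_", c("ankle", "knee", "hip", "back"), "_ext")
  ))
  expect_true(all(feats[grep("fb_", names(feats))] >= 0))
})
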