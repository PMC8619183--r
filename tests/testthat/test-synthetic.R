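test_that("the same seed reproduces trial signals bit-identically", {
  cfg <- light_config()
  pf <- platform_profile(rate = cfg$kinematics$rate)
  prof <- default_profile("Faller")
  k1 <- simulate_trial_kinematics(prof, 2, pf, cfg, seed = 5)
  k2 <- simulate_trial_kinematics(prof, 2, pf, cfg, seed = 5)
  expect_identical(k1, k2)
  e1 <- simulate_trial_emg(prof, 2, pf, cfg, seed = 5)
  e2 <- simulate_trial_emg(prof, 2, pf, cfg, seed = 5)
  expect_identical(e1, e2)
  s1 <- simulate_sway_trace(prof, "stable_eo", cfg, seed = 5)
  s2 <- simulate_sway_trace(prof, "stable_eo", cfg, seed = 5)
  expect_identical(s1, s2)
})

test_that("an identical config yields a bit-identical cohort", {
  c1 <- simulate_cohort_features(light_config(seed = 9))
  c2 <- simulate_cohort_features(light_config(seed = 9))
  expect_identical(c1, c2)
})

test_that("noise-free, response-free kinematics sit at the configured
          feedforward offsets", {
  cfg <- light_config()
  cfg$noise_sd$angle_deg <- 0
  cfg$noise_sd$side_asym_deg <- 0
  cfg$feedback_response$flex_amp <- 0
  cfg$feedback_response$ext_amp <- 0
  pf <- platform_profile(rate = cfg$kinematics$rate)
  k <- simulate_trial_kinematics(default_profile("Faller"), 3, pf, cfg)
  # faller trial-3 ankle offset is +4 deg plantar flexion by default
  expect_true(all(abs(k$ankle_left - 4) < 1e-9))
  expect_true(all(abs(k$back - 0) < 1e-9))
})

test_that("configured feedforward offsets are recovered in Monte Carlo mean", {
  cfg <- light_config()
  ta <- cfg$trial_adaptation
  ta$ff_offsets$offset_deg[
    ta$ff_offsets$group == "Faller" & ta$ff_offsets$joint == "ankle"
  ] <- 2
  cfg$trial_adaptation <- ta
  pf <- platform_profile(rate = cfg$kinematics$rate)
  prof <- default_profile("Faller")
  withr::with_seed(21, {
    means <- replicate(300, {
      k <- simulate_trial_kinematics(prof, 1, pf, cfg)
      ff <- feedforward_posture(average_sides(k))
      ff$ankle
    })
  })
  expect_equal(mean(means), 2, tolerance = 0.05)
})

test_that("unknown joints in the adaptation table are rejected", {
  cfg <- light_config()
  expect_error(
    cohort_config(trial_adaptation = list(
      ff_offsets = tibble::tibble(
        group = "Faller", trial = 1, joint = "elbow", offset_deg = 1
      ),
      cci = cfg$trial_adaptation$cci
    )),
    "unknown joint"
  )
})

test_that("a silent activation envelope leaves only the noise floor", {
  cfg <- light_config()
  cfg$emg$tonic_ta <- 0
  cfg$emg$tonic_gm <- 0
  cfg$emg$burst_amp <- 0
  pf <- platform_profile(rate = cfg$kinematics$rate)
  e <- simulate_trial_emg(default_profile(), 1, pf, cfg, seed = 2)
  rms <- sqrt(mean(e$ta_left^2))
  expect_equal(rms, cfg$noise_sd$emg_floor_mv, tolerance = 0.15)
})

test_that("the programmed tibialis burst peaks where configured", {
  cfg <- light_config()
  pf <- platform_profile(rate = cfg$kinematics$rate)
  # peak is at latency + rise width; configure so the peak lands at 200 ms
  cfg$emg$burst_latency_s <- 0.15
  cfg$emg$burst_width_s <- 0.05
  env <- emg_activation_envelope("Non-faller", 1, pf, cfg)
  t_peak <- env$time_s[which.max(env$ta)]
  expect_lt(abs(t_peak - 0.2), 0.025)
})

test_that("negative burst latency is rejected", {
  expect_error(cohort_config(emg = list(
    rate = 1500, burst_latency_s = -0.1, burst_width_s = 0.05,
    burst_amp = 0.6, tonic_ta = 0.08, tonic_gm = 0.1,
    mvc_mv = c(ta = 1, gm = 1)
  )), "latency")
})

test_that("sway traces have the configured stationary sd and degenerate
          cleanly at sd zero", {
  # full 30 s records: shorter windows under-estimate the stationary sd
  # because of the process autocorrelation
  cfg <- light_config(sway = list(rate = 200, duration_s = 30, theta = 1))
  cfg$sway_sd$ap_sd_cm[] <- 1
  cfg$sway_sd$ml_sd_cm[] <- 1
  prof <- default_profile()
  withr::with_seed(31, {
    sds <- replicate(100, {
      s <- simulate_sway_trace(prof, "stable_eo", cfg)
      sd(s$ap_cm)
    })
  })
  expect_lt(abs(mean(sds) - 1), 0.1)

  cfg0 <- light_config()
  cfg0$sway_sd$ap_sd_cm[] <- 0
  cfg0$sway_sd$ml_sd_cm[] <- 0
  s0 <- simulate_sway_trace(prof, "stable_ec", cfg0, seed = 1)
  expect_true(all(s0$ap_cm == 0) && all(s0$ml_cm == 0))
  expect_equal(ellipse_area(s0[, c("ap_cm", "ml_cm")]), 0, ignore_attr = TRUE)
  expect_error(simulate_sway_trace(prof, "one-leg", cfg0), "unknown condition")
})

test_that("unstable eyes-open sway exceeds stable eyes-open for both groups", {
  cfg <- light_config()
  withr::with_seed(41, {
    for (grp in c("Non-faller", "Faller")) {
      prof <- default_profile(grp)
      areas <- sapply(c("stable_eo", "unstable_eo"), function(cond) {
        median(replicate(20, {
          s <- filter_cop(simulate_sway_trace(prof, cond, cfg))
          ellipse_area(s[, c("ap_cm", "ml_cm")])
        }))
      })
      expect_gt(areas[["unstable_eo"]], areas[["stable_eo"]])
    }
  })
})

test_that("cohorts honour the configured faller share and outcome rules", {
  parts <- simulate_cohort_features(light_config(n_subjects = 12, seed = 4))
  subj <- parts$subjects
  expect_equal(sum(subj$group == "Faller"), round(12 * 1 / 6))
  fallers <- subj[subj$group == "Faller", ]
  expect_true(all(fallers$outcome_1 == "fall" & fallers$outcome_2 == "fall" &
    fallers$outcome_3 == "fall"))
  nonfallers <- subj[subj$group == "Non-faller", ]
  expect_true(all(nonfallers$outcome_3 == "success"))
  expect_false(any(is.na(parts$trial_features$cci_feedforward)))
})

test_that("an empty cohort and a schema-violating effect table are handled", {
  empty <- simulate_cohort_features(light_config(n_subjects = 0))
  expect_equal(nrow(empty$subjects), 0)
  bad <- light_config()
  bad$effect_table <- bad$effect_table[bad$effect_table$variable != "sppb", ]
  expect_error(simulate_cohort_features(bad), "schema")
})

test_that("configured group effect directions are recoverable from the
          scalar generator", {
  withr::with_seed(51, {
    et <- default_effect_table()
    ns <- cohort_config()$noise_sd
    worse <- replicate(200, {
      nf <- replicate(30, posturadapt:::.draw_scalars(
        "Non-faller", et, ns,
        rho = 0.6
      )$torque_knee_ext)
      fa <- replicate(5, posturadapt:::.draw_scalars(
        "Faller", et, ns,
        rho = 0.6
      )$torque_knee_ext)
      median(fa) < median(nf)
    })
  })
  expect_gt(mean(worse), 0.95)
})

test_that("missingness is applied at the configured rate", {
  cfg <- light_config(n_subjects = 30, missing_rate = 0.2)
  parts <- simulate_cohort_features(cfg)
  vars <- cfg$effect_table$variable
  vars <- setdiff(vars, "reaction_time") # stored as five raw trials
  rate <- mean(is.na(as.matrix(parts$subjects[vars])))
  expect_gt(rate, 0.1)
  expect_lt(rate, 0.3)
})
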