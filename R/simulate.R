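#' Default group effect table for the synthetic cohort
#'
#' Generative means and standard deviations for every subject-level scalar
#' variable, by group. The group means follow the published descriptive
#' medians of a faller / non-faller perturbation cohort (fallers: older,
#' shorter, more medications, weaker knee extension and ankle plantar
#' flexion, slower reaction time, lower SPPB, larger sway); the standard
#' deviations are set from the corresponding interquartile ranges
#' (IQR / 1.35). Every entry can be overridden before passing the table to
#' [cohort_config()].
#'
#' @return A tibble with columns `variable`, `nonfaller_mean`,
#'   `faller_mean`, `sd`.
#' @export
default_effect_table <- function() {
  tibble::tribble(
    ~variable,          ~nonfaller_mean, ~faller_mean, ~sd,
    "age",                     74,          77,       3.5,
    "height_cm",              167,         155,       8,
    "weight_kg",               71.5,        75,      10,
    "n_medications",            2,           6,       2,
    "afraid_falling",           1,           1,       0.6,
    "concern_injury",           1,           2,       1.0,
    "concern_helpless",         1,           1,       0.5,
    "concern_help",             1,           1,       0.8,
    "concern_burden",           1,           2,       0.7,
    "fes_i",                   19,          23,       4,
    "mmt",                     29,          28,       1.5,
    "visual_acuity",            0.8,         0.7,     0.12,
    "jps_knee_left",            4.65,        3.2,     1.8,
    "jps_knee_right",           4.65,        3.2,     1.8,
    "jps_ankle_left",           3.85,        6.0,     1.8,
    "jps_ankle_right",          3.85,        6.0,     1.8,
    "torque_hip_ext",          49.8,        37.3,    16,
    "torque_hip_abd",          51.8,        40.8,    18,
    "torque_knee_ext",         84.5,        61.0,    22,
    "torque_knee_flex",        61.9,        50.1,    16,
    "torque_ankle_df",         21.7,        19.6,     4.5,
    "torque_ankle_pf",         88.0,        57.7,    22,
    "reaction_time",          365,         442,      45,
    "sppb",                    11.5,        10,       1.0
  )
}

#' Default trial-dependent adaptation parameters
#'
#' Feedforward joint-angle offsets (degrees, positive = flexion / ankle
#' plantar flexion) and tonic EMG co-contraction multipliers per group and
#' perturbation trial. Non-fallers progressively adopt a flexed anticipatory
#' posture (hips, knees, ankles) by trial 3 while relaxing their tonic
#' co-contraction; fallers mainly increase ankle plantar flexion (a more
#' erect, stiffened stance) and ramp up co-contraction across trials.
#'
#' @return A list with elements `ff_offsets` (tibble: `group`, `trial`,
#'   `joint`, `offset_deg`) and `cci` (tibble: `group`, `trial`,
#'   `multiplier`).
#' @export
default_trial_adaptation <- function() {
  nf3 <- c(ankle = 2, knee = 3, hip = 3, back = 1)
  f3 <- c(ankle = 4, knee = 0.5, hip = 0.5, back = 0)
  grid <- tidyr::expand_grid(
    group = .groups, trial = 1:3, joint = .joints
  )
  grid$offset_deg <- purrr::pmap_dbl(grid, function(group, trial, joint) {
    full <- if (group == "Faller") f3[[joint]] else nf3[[joint]]
    full * (trial - 1) / 2 # 0 at trial 1, half at trial 2, full at trial 3
  })
  cci <- tibble(
    group = rep(.groups, each = 3),
    trial = rep(1:3, 2),
    multiplier = c(1.0, 0.95, 0.9, 1.2, 1.5, 1.8)
  )
  list(ff_offsets = grid, cci = cci)
}

#' Default perturbation-evoked kinematic response amplitudes
#'
#' Flexion and extension deflection amplitudes (degrees) of the reactive
#' joint excursion during the platform movement, per group, trial and joint.
#' The pattern follows the published feedback range-of-motion medians:
#' non-fallers reduce knee/hip/back flexion excursions from trial 1 to
#' trial 3 (effective feedforward adaptation), while fallers show a large
#' back-extension response in trial 1. Trial 2 amplitudes are interpolated.
#'
#' @return A tibble with columns `group`, `trial`, `joint`, `flex_amp`,
#'   `ext_amp`.
#' @export
default_feedback_response <- function() {
  t1 <- tibble::tribble(
    ~group, ~joint, ~flex_amp, ~ext_amp,
    "Non-faller", "ankle", 0.80, 6.55,
    "Non-faller", "knee", 12.50, 0.23,
    "Non-faller", "hip", 7.67, 0.04,
    "Non-faller", "back", 2.61, 0.13,
    "Faller", "ankle", 0.79, 7.47,
    "Faller", "knee", 14.01, 0.15,
    "Faller", "hip", 12.26, 0.35,
    "Faller", "back", 1.90, 2.04
  )
  t3 <- tibble::tribble(
    ~group, ~joint, ~flex_amp, ~ext_amp,
    "Non-faller", "ankle", 2.63, 6.48,
    "Non-faller", "knee", 8.77, 0.15,
    "Non-faller", "hip", 3.23, 0.19,
    "Non-faller", "back", 1.51, 0.11,
    "Faller", "ankle", 1.85, 6.70,
    "Faller", "knee", 8.15, 0.17,
    "Faller", "hip", 5.03, 2.14,
    "Faller", "back", 1.64, 0.70
  )
  t2 <- t1
  t2$flex_amp <- (t1$flex_amp + t3$flex_amp) / 2
  t2$ext_amp <- (t1$ext_amp + t3$ext_amp) / 2
  dplyr::bind_rows(
    dplyr::mutate(t1, trial = 1L), dplyr::mutate(t2, trial = 2L),
    dplyr::mutate(t3, trial = 3L)
  )[, c("group", "trial", "joint", "flex_amp", "ext_amp")]
}

#' Default quiet-stance sway magnitudes
#'
#' Stationary standard deviations (cm) of the anteroposterior and
#' mediolateral centre-of-pressure excursion per group and stance condition.
#' They are back-calculated from published median 95% prediction-ellipse
#' areas per condition via `area = pi * qchisq(0.95, 2) * sd_ap * sd_ml`
#' under isotropy, so the generator reproduces those ellipse areas in
#' expectation; sway grows from stable/eyes-open to unstable/eyes-closed and
#' fallers sway more in every condition.
#'
#' @return A tibble with columns `group`, `condition`, `ap_sd_cm`,
#'   `ml_sd_cm`.
#' @export
default_sway_sd <- function() {
  # median ellipse areas (cm^2) per condition: non-fallers then fallers
  areas <- tibble::tribble(
    ~group, ~condition, ~area_cm2,
    "Non-faller", "stable_eo", 0.93,
    "Non-faller", "stable_ec", 1.25,
    "Non-faller", "unstable_eo", 4.95,
    "Non-faller", "unstable_ec", 12.20,
    "Faller", "stable_eo", 2.95,
    "Faller", "stable_ec", 2.81,
    "Faller", "unstable_eo", 11.08,
    "Faller", "unstable_ec", 19.11
  )
  s <- sqrt(areas$area_cm2 / (pi * stats::qchisq(0.95, 2)))
  tibble(
    group = areas$group, condition = areas$condition,
    ap_sd_cm = s, ml_sd_cm = s
  )
}

#' Configuration of a synthetic perturbation-study cohort
#'
#' Collects every generative parameter of the synthetic study: cohort
#' composition, group effect sizes for the subject-level scalars,
#' trial-dependent feedforward/co-contraction adaptation, perturbation-evoked
#' kinematic responses, EMG activation parameters, quiet-stance sway
#' magnitudes and noise scales. Defaults reproduce the structure of a
#' 35-subject study with 5 fallers and three identical perturbations.
#'
#' @param n_subjects Number of subjects (default 35).
#' @param faller_fraction Proportion of fallers (default 5/35); the realised
#'   faller count is exactly `round(n_subjects * faller_fraction)`.
#' @param seed Integer RNG seed; identical configs generate bit-identical
#'   cohorts.
#' @param effect_table Group means/sds per scalar variable, see
#'   [default_effect_table()].
#' @param trial_adaptation See [default_trial_adaptation()].
#' @param feedback_response See [default_feedback_response()].
#' @param sway_sd See [default_sway_sd()].
#' @param noise_sd List of noise scales: `angle_deg` white noise on joint
#'   angles, `side_asym_deg` independent left/right asymmetry,
#'   `emg_floor_mv` EMG noise floor (mV), `rt_trial_ms` within-subject
#'   reaction-time trial scatter.
#' @param platform Platform motion parameters passed to
#'   [platform_profile()].
#' @param kinematics List: `rate` (Hz, default 200), `baseline_sd_deg`
#'   between-subject quiet-stance posture scatter, `response_scale_sd`
#'   log-sd of the subject-specific response amplitude factor.
#' @param emg List: `rate` (Hz, default 3000), `burst_latency_s` tibialis
#'   burst onset after platform onset (default 0.12 s), `burst_width_s` rise
#'   time to burst peak, `burst_amp` burst amplitude (fraction of MVC),
#'   `tonic_ta`, `tonic_gm` tonic pre-perturbation levels (fraction of MVC),
#'   `mvc_mv` named MVC reference amplitudes (mV).
#' @param sway List: `rate` (Hz, default 3000), `duration_s` (default 30),
#'   `theta` mean-reversion rate (1/s) of the sway process.
#' @param construct_correlation Within-subject correlation among variables
#'   of the same construct (fall-related concerns, strength, joint position
#'   sense), induced by a shared latent factor per construct (default 0.6).
#'   This is what makes the one-component PCA base models meaningful:
#'   similar-construct items co-vary within a person.
#' @param sway_scale_sd Log-sd of a subject-level sway magnitude factor
#'   multiplying all four condition sds (default 0.25, i.e. roughly +/-50%
#'   between subjects); induces the positive correlation among a subject's
#'   four sway areas.
#' @param missing_rate Missing-at-random probability applied per scalar
#'   variable (default 0).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 35, faller_fraction = 5 / 35,
                          seed = 1L,
                          effect_table = default_effect_table(),
                          trial_adaptation = default_trial_adaptation(),
                          feedback_response = default_feedback_response(),
                          sway_sd = default_sway_sd(),
                          noise_sd = list(
                            angle_deg = 0.3, side_asym_deg = 0.15,
                            emg_floor_mv = 0.02, rt_trial_ms = 30
                          ),
                          platform = list(
                            translation_cm = 8, translation_velocity = 10,
                            tilt_deg = 6, tilt_velocity = 11
                          ),
                          kinematics = list(
                            rate = 200, baseline_sd_deg = 0.8,
                            response_scale_sd = 0.2
                          ),
                          emg = list(
                            rate = 3000, burst_latency_s = 0.12,
                            burst_width_s = 0.05, burst_amp = 0.6,
                            tonic_ta = 0.08, tonic_gm = 0.10,
                            mvc_mv = c(ta = 1, gm = 1)
                          ),
                          sway = list(rate = 3000, duration_s = 30, theta = 1),
                          construct_correlation = 0.6,
                          sway_scale_sd = 0.25,
                          missing_rate = 0) {
  if (n_subjects < 0) abort("n_subjects must be >= 0")
  if (faller_fraction < 0 || faller_fraction > 1) {
    abort("faller_fraction must lie in [0, 1]")
  }
  if (any(effect_table$sd < 0)) abort("effect_table sds must be >= 0")
  if (missing_rate < 0 || missing_rate > 1) {
    abort("missing_rate must lie in [0, 1]")
  }
  if (emg$burst_latency_s < 0) abort("burst latency must be >= 0")
  bad <- setdiff(unique(trial_adaptation$ff_offsets$joint), .joints)
  if (length(bad) > 0) {
    abort(paste0("unknown joint in trial_adaptation: ", toString(bad)))
  }
  if (any(sway_sd$ap_sd_cm < 0) || any(sway_sd$ml_sd_cm < 0)) {
    abort("sway sds must be >= 0")
  }
  if (construct_correlation < 0 || construct_correlation >= 1) {
    abort("construct_correlation must lie in [0, 1)")
  }
  structure(
    list(
      n_subjects = n_subjects, faller_fraction = faller_fraction,
      seed = as.integer(seed), effect_table = effect_table,
      trial_adaptation = trial_adaptation,
      feedback_response = feedback_response,
      sway_sd = sway_sd, noise_sd = noise_sd, platform = platform,
      kinematics = kinematics, emg = emg, sway = sway,
      construct_correlation = construct_correlation,
      sway_scale_sd = sway_scale_sd,
      missing_rate = missing_rate
    ),
    class = "cohort_config"
  )
}

# smooth bump supported on [t0, t0 + len]: sin^2 rising to 1 at the middle
.bump <- function(t, t0, len) {
  s <- (t - t0) / len
  out <- numeric(length(t))
  in_sup <- s >= 0 & s <= 1
  out[in_sup] <- sin(pi * s[in_sup])^2
  out
}

# one-sided activation bump: 0 before t0, sin^2 rise over `rise` to a peak
# at t0 + rise, then sin^2 decay over `fall`
.burst_shape <- function(t, t0, rise, fall = 2 * rise) {
  out <- numeric(length(t))
  up <- t >= t0 & t < t0 + rise
  out[up] <- sin(pi / 2 * (t[up] - t0) / rise)^2
  dn <- t >= t0 + rise & t <= t0 + rise + fall
  out[dn] <- cos(pi / 2 * (t[dn] - t0 - rise) / fall)^2
  out
}

.lookup <- function(df, keys, value) {
  out <- df
  for (nm in names(keys)) out <- out[out[[nm]] == keys[[nm]], , drop = FALSE]
  if (nrow(out) != 1) {
    abort(paste0(
      "no unique ", value, " entry for ",
      paste(names(keys), unlist(keys), sep = "=", collapse = ", ")
    ))
  }
  out[[value]]
}

#' Simulate joint-angle series for one perturbation trial
#'
#' Generates sagittal joint-angle time series (degrees, positive = flexion /
#' ankle plantar flexion, zero = the subject's quiet-stance reference) as a
#' group- and trial-dependent feedforward posture offset, plus a
#' perturbation-evoked flexion/extension excursion during the platform
#' movement, plus Gaussian noise. Ankle, knee and hip are generated
#' bilaterally with a small independent left/right asymmetry; the back is a
#' single series.
#'
#' @param subject_profile List with `group` (`"Faller"`/`"Non-faller"`) and
#'   optionally `baseline_deg` (named per-joint posture offsets, default 0)
#'   and `response_scale` (multiplier on response amplitudes, default 1).
#' @param trial_index Trial number, 1 to 3.
#' @param platform A [platform_profile()] trajectory.
#' @param config A [cohort_config()].
#' @param seed Optional integer seed for reproducible draws.
#' @return A tibble of class `joint_angle_set` with `time_s` and columns
#'   `ankle_left`, ..., `back`; attributes `rate`, `onset_time`, `halt_time`.
#' @export
simulate_trial_kinematics <- function(subject_profile, trial_index, platform,
                                      config, seed = NULL) {
  if (!trial_index %in% 1:3) abort("trial_index must be 1, 2 or 3")
  if (!is.null(seed)) set.seed(seed)
  grp <- subject_profile$group
  base <- subject_profile$baseline_deg %||% setNames(numeric(4), .joints)
  rscale <- subject_profile$response_scale %||% 1
  off <- config$trial_adaptation$ff_offsets
  bad <- setdiff(unique(off$joint), .joints)
  if (length(bad) > 0) abort(paste0("unknown joint in config: ", toString(bad)))

  t <- platform$time_s
  halt <- attr(platform, "halt_time")
  noise_sd <- config$noise_sd$angle_deg
  asym_sd <- config$noise_sd$side_asym_deg

  series <- lapply(.joints, function(j) {
    ff <- .lookup(off, list(group = grp, trial = trial_index, joint = j),
      "offset_deg"
    ) + (base[[j]] %||% 0)
    fa <- .lookup(config$feedback_response,
      list(group = grp, trial = trial_index, joint = j), "flex_amp"
    )
    ea <- .lookup(config$feedback_response,
      list(group = grp, trial = trial_index, joint = j), "ext_amp"
    )
    resp <- numeric(length(t))
    if (halt > 0) {
      resp <- rscale * (fa * .bump(t, 0, 0.55 * halt) -
        ea * .bump(t, 0.55 * halt, 0.45 * halt))
    }
    ff + resp + rnorm(length(t), 0, noise_sd)
  })
  names(series) <- .joints

  out <- tibble(time_s = t)
  for (j in .sided_joints) {
    out[[paste0(j, "_left")]] <- series[[j]] + rnorm(length(t), 0, asym_sd)
    out[[paste0(j, "_right")]] <- series[[j]] + rnorm(length(t), 0, asym_sd)
  }
  out$back <- series$back
  structure(out,
    class = c("joint_angle_set", class(out)),
    rate = attr(platform, "rate"),
    onset_time = attr(platform, "onset_time"),
    halt_time = halt
  )
}

#' Programmed EMG activation envelopes for a simulated trial
#'
#' The noise-free activation envelopes (fraction of MVC) that
#' [simulate_trial_emg()] modulates onto its band-limited carrier: a tonic
#' pre-perturbation level scaled by the group/trial co-contraction
#' multiplier, plus a reactive tibialis anterior burst starting at the
#' configured latency after platform onset.
#'
#' @inheritParams simulate_trial_kinematics
#' @param group Group label.
#' @return A tibble with `time_s`, `ta`, `gm` at the EMG rate.
#' @export
emg_activation_envelope <- function(group, trial_index, platform, config) {
  if (config$emg$burst_latency_s < 0) abort("negative burst latency")
  t <- seq(min(platform$time_s), max(platform$time_s),
    by = 1 / config$emg$rate
  )
  mult <- .lookup(config$trial_adaptation$cci,
    list(group = group, trial = trial_index), "multiplier"
  )
  e <- config$emg
  ta <- e$tonic_ta * mult +
    e$burst_amp * .burst_shape(t, e$burst_latency_s, e$burst_width_s)
  gm <- e$tonic_gm * mult +
    0.25 * e$burst_amp *
      .burst_shape(t, e$burst_latency_s + 0.05, 1.5 * e$burst_width_s)
  tibble(time_s = t, ta = ta, gm = gm)
}

#' Simulate bilateral surface EMG for one perturbation trial
#'
#' Each channel is a 20-450 Hz band-limited Gaussian noise carrier (so the
#' analysis band-pass transmits it) amplitude-modulated by the programmed
#' activation envelope ([emg_activation_envelope()]), in mV relative to the
#' muscle's MVC reference amplitude, plus an unmodulated noise floor.
#'
#' @inheritParams simulate_trial_kinematics
#' @return A tibble of class `emg_recording` with `time_s` and channels
#'   `ta_left`, `ta_right`, `gm_left`, `gm_right` (mV); attributes `rate`,
#'   `mvc_mv`, `onset_time`, `halt_time`.
#' @export
simulate_trial_emg <- function(subject_profile, trial_index, platform,
                               config, seed = NULL) {
  if (!trial_index %in% 1:3) abort("trial_index must be 1, 2 or 3")
  if (!is.null(seed)) set.seed(seed)
  env <- emg_activation_envelope(
    subject_profile$group, trial_index, platform, config
  )
  rate <- config$emg$rate
  mvc <- config$emg$mvc_mv
  floor_mv <- config$noise_sd$emg_floor_mv
  n <- nrow(env)
  out <- tibble(time_s = env$time_s)
  for (ch in .emg_channels) {
    muscle <- substr(ch, 1, 2)
    carrier <- band_limited_noise(n, rate)
    noise <- band_limited_noise(n, rate)
    out[[ch]] <- mvc[[muscle]] * env[[muscle]] * carrier + floor_mv * noise
  }
  structure(out,
    class = c("emg_recording", class(out)),
    rate = rate, mvc_mv = mvc,
    onset_time = attr(platform, "onset_time"),
    halt_time = attr(platform, "halt_time")
  )
}

#' Simulate a 30-second quiet-stance centre-of-pressure trace
#'
#' AP and ML excursions follow independent Ornstein-Uhlenbeck (mean
#' reverting) processes with stationary standard deviations per group and
#' stance condition, so a 30 s trace has a finite, condition-dependent
#' sway ellipse. Exact discretisation is used, with the initial point drawn
#' from the stationary distribution.
#'
#' @inheritParams simulate_trial_kinematics
#' @param condition One of `"stable_eo"`, `"stable_ec"`, `"unstable_eo"`,
#'   `"unstable_ec"`.
#' @return A tibble of class `cop_trace` with `time_s`, `ap_cm`, `ml_cm`;
#'   attributes `condition`, `rate`.
#' @export
simulate_sway_trace <- function(subject_profile, condition, config,
                                seed = NULL) {
  if (!condition %in% .sway_conditions) {
    abort(paste0("unknown condition: ", condition))
  }
  if (!is.null(seed)) set.seed(seed)
  grp <- subject_profile$group
  scale <- subject_profile$sway_scale %||% 1
  ap_sd <- scale * .lookup(config$sway_sd,
    list(group = grp, condition = condition), "ap_sd_cm"
  )
  ml_sd <- scale * .lookup(config$sway_sd,
    list(group = grp, condition = condition), "ml_sd_cm"
  )
  rate <- config$sway$rate
  n <- round(config$sway$duration_s * rate) + 1
  dt <- 1 / rate
  a <- exp(-config$sway$theta * dt)
  ou <- function(s) {
    if (s == 0) return(numeric(n))
    e <- c(rnorm(1, 0, s), rnorm(n - 1, 0, s * sqrt(1 - a^2)))
    as.numeric(stats::filter(e, a, method = "recursive"))
  }
  out <- tibble(
    time_s = seq(0, by = dt, length.out = n),
    ap_cm = ou(ap_sd), ml_cm = ou(ml_sd)
  )
  structure(out,
    class = c("cop_trace", class(out)),
    condition = condition, rate = rate
  )
}

# variables build_feature_table() needs from the effect table
.required_schema <- function() default_effect_table()$variable

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# scalar variables sharing a latent factor within subject
.scalar_constructs <- list(
  fall_concerns = c(
    "afraid_falling", "concern_injury", "concern_helpless",
    "concern_help", "concern_burden", "fes_i"
  ),
  strength = c(
    "torque_hip_ext", "torque_hip_abd", "torque_knee_ext",
    "torque_knee_flex", "torque_ankle_df", "torque_ankle_pf"
  ),
  jps = c(
    "jps_knee_left", "jps_knee_right", "jps_ankle_left", "jps_ankle_right"
  )
)

# draw one subject's scalar features from the effect table; variables in
# the same construct share a latent factor with correlation rho
.draw_scalars <- function(group, effect_table, noise_sd, rho = 0) {
  mu_col <- if (group == "Faller") "faller_mean" else "nonfaller_mean"
  z <- rnorm(nrow(effect_table))
  if (rho > 0) {
    for (vars in .scalar_constructs) {
      sel <- which(effect_table$variable %in% vars)
      if (length(sel) > 1) {
        u <- rnorm(1)
        z[sel] <- sqrt(rho) * u + sqrt(1 - rho) * z[sel]
      }
    }
  }
  draws <- effect_table[[mu_col]] + effect_table$sd * z
  names(draws) <- effect_table$variable
  g <- function(v) draws[[v]]
  rt_mean <- g("reaction_time")
  rt <- rt_mean + rnorm(5, 0, noise_sd$rt_trial_ms)
  out <- as.list(draws)
  # respect the scale constraints of the instruments
  likert <- c(
    "afraid_falling", "concern_injury", "concern_helpless",
    "concern_help", "concern_burden"
  )
  for (v in intersect(likert, names(out))) {
    out[[v]] <- .clamp(round(out[[v]]), 1, 4)
  }
  if ("fes_i" %in% names(out)) out$fes_i <- .clamp(round(out$fes_i), 16, 64)
  if ("mmt" %in% names(out)) out$mmt <- .clamp(round(out$mmt), 0, 30)
  if ("sppb" %in% names(out)) out$sppb <- .clamp(round(out$sppb), 0, 12)
  if ("n_medications" %in% names(out)) {
    out$n_medications <- max(round(out$n_medications), 0)
  }
  if ("visual_acuity" %in% names(out)) {
    out$visual_acuity <- max(round(out$visual_acuity, 1), 0.1)
  }
  if ("age" %in% names(out)) out$age <- round(out$age)
  for (v in grep("^torque_", names(out), value = TRUE)) {
    out[[v]] <- max(out[[v]], 1)
  }
  for (v in grep("^jps_", names(out), value = TRUE)) {
    out[[v]] <- max(out[[v]], 0.2)
  }
  out$reaction_time <- NULL # stored as the five raw trials
  for (k in 1:5) out[[paste0("rt_ms_", k)]] <- rt[k]
  p_male <- if (group == "Faller") 1 / 5 else 13 / 30
  out$sex <- if (runif(1) < p_male) "male" else "female"
  out
}

# shared cohort generator; extract_features switches between keeping raw
# signals (simulate_cohort) and reducing each subject to features on the
# fly (simulate_cohort_features) without changing the RNG stream
.generate_cohort <- function(config, extract_features) {
  stopifnot(inherits(config, "cohort_config"))
  missing_vars <- setdiff(.required_schema(), config$effect_table$variable)
  if (length(missing_vars) > 0) {
    abort(paste0(
      "effect_table is missing variables required by the pipeline schema: ",
      toString(missing_vars)
    ))
  }
  n <- config$n_subjects
  set.seed(config$seed)
  empty <- list(
    subjects = tibble(), trials = list(), sway = list(),
    trial_features = tibble(), sway_features = tibble()
  )
  if (n == 0) return(empty)

  n_fall <- round(n * config$faller_fraction)
  groups <- rep("Non-faller", n)
  if (n_fall > 0) groups[sample.int(n, n_fall)] <- "Faller"
  ids <- sprintf("S%02d", seq_len(n))
  platform <- platform_profile(
    translation_cm = config$platform$translation_cm,
    translation_velocity = config$platform$translation_velocity,
    tilt_deg = config$platform$tilt_deg,
    tilt_velocity = config$platform$tilt_velocity,
    rate = config$kinematics$rate
  )

  subj_rows <- vector("list", n)
  trials_all <- vector("list", n)
  sway_all <- vector("list", n)
  tf_all <- vector("list", n)
  sf_all <- vector("list", n)

  for (i in seq_len(n)) {
    grp <- groups[i]
    scalars <- .draw_scalars(
      grp, config$effect_table, config$noise_sd,
      rho = config$construct_correlation %||% 0
    )
    profile <- list(
      group = grp,
      baseline_deg = setNames(
        rnorm(4, 0, config$kinematics$baseline_sd_deg), .joints
      ),
      response_scale = exp(rnorm(1, 0, config$kinematics$response_scale_sd)),
      sway_scale = exp(rnorm(1, 0, config$sway_scale_sd %||% 0))
    )
    if (grp == "Faller") {
      outcomes <- rep("fall", 3)
    } else {
      outcomes <- c(
        if (runif(1) < 0.3) "fall" else "success",
        if (runif(1) < 0.1) "fall" else "success",
        "success"
      )
    }
    trials <- lapply(1:3, function(k) {
      structure(
        list(
          joint_angles = simulate_trial_kinematics(profile, k, platform, config),
          emg = simulate_trial_emg(profile, k, platform, config),
          platform = platform, trial_index = k, outcome = outcomes[k]
        ),
        class = "trial_recording"
      )
    })
    sway <- lapply(.sway_conditions, function(cond) {
      simulate_sway_trace(profile, cond, config)
    })
    names(sway) <- .sway_conditions

    # missing-at-random holes in the scalar features
    if (config$missing_rate > 0) {
      for (v in config$effect_table$variable) {
        if (v %in% names(scalars) && runif(1) < config$missing_rate) {
          scalars[[v]] <- NA_real_
        }
      }
    }

    subj_rows[[i]] <- tibble(
      id = ids[i], group = grp, !!!scalars,
      outcome_1 = outcomes[1], outcome_2 = outcomes[2],
      outcome_3 = outcomes[3], vestibular_positive = FALSE
    )
    if (extract_features) {
      tf <- purrr::map_dfr(trials, function(tr) {
        dplyr::bind_cols(
          tibble(id = ids[i], trial = tr$trial_index),
          extract_kinematic_features(tr$joint_angles),
          extract_emg_features(tr$emg)
        )
      })
      sf <- purrr::map_dfr(.sway_conditions, function(cond) {
        filtered <- filter_cop(sway[[cond]])
        tibble(
          id = ids[i], condition = cond,
          area_cm2 = ellipse_area(filtered[, c("ap_cm", "ml_cm")])
        )
      })
      tf_all[[i]] <- tf
      sf_all[[i]] <- sf
    } else {
      trials_all[[i]] <- trials
      sway_all[[i]] <- sway
    }
  }

  subjects <- dplyr::bind_rows(subj_rows)
  if (extract_features) {
    list(
      subjects = subjects,
      trial_features = dplyr::bind_rows(tf_all),
      sway_features = dplyr::bind_rows(sf_all)
    )
  } else {
    subjects$trials <- trials_all
    subjects$sway <- sway_all
    structure(subjects, class = c("cohort", class(subjects)))
  }
}

#' Simulate a full synthetic cohort with raw signals
#'
#' Generates every subject's scalar features, three perturbation-trial
#' recordings (joint angles + EMG + platform trajectory + fall outcome) and
#' four quiet-stance sway traces. Fallers (exactly
#' `round(n * faller_fraction)` of the cohort) fall in all three trials;
#' non-fallers always succeed on trial 3 but may fall earlier. The same
#' config (including seed) yields a bit-identical cohort.
#'
#' Holding the raw signals for a full default cohort takes a few hundred MB;
#' use [simulate_cohort_features()] when only the derived features are
#' needed.
#'
#' @param config A [cohort_config()].
#' @return A tibble of class `cohort`, one row per subject, with scalar
#'   feature columns, `outcome_1..3`, and list-columns `trials` (3
#'   `trial_recording`s) and `sway` (4 named `cop_trace`s).
#' @export
simulate_cohort <- function(config) {
  .generate_cohort(config, extract_features = FALSE)
}

#' Simulate a cohort and reduce it to analysis features on the fly
#'
#' Streams subject by subject: raw trial signals and sway traces are
#' generated exactly as in [simulate_cohort()] (same seed, same draws) but
#' immediately reduced to kinematic, EMG and sway features, so memory stays
#' flat.
#'
#' @param config A [cohort_config()].
#' @return A list with `subjects` (scalar features + outcomes),
#'   `trial_features` (one row per subject x trial) and `sway_features`
#'   (one row per subject x condition).
#' @export
simulate_cohort_features <- function(config) {
  .generate_cohort(config, extract_features = TRUE)
}
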