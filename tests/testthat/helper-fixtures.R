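# A down-sized cohort config for unit tests that exercise structure and
# determinism: lower signal rates and shorter sway records keep individual
# tests fast. Tests about the default study conditions use cohort_config()
# unchanged.
light_config <- function(n_subjects = 6, seed = 1,
                         kinematics = list(
                           rate = 100, baseline_sd_deg = 0.8,
                           response_scale_sd = 0.2
                         ),
                         emg = list(
                           rate = 1500, burst_latency_s = 0.12,
                           burst_width_s = 0.05, burst_amp = 0.6,
                           tonic_ta = 0.08, tonic_gm = 0.10,
                           mvc_mv = c(ta = 1, gm = 1)
                         ),
                         sway = list(rate = 200, duration_s = 10, theta = 1),
                         ...) {
  cohort_config(
    n_subjects = n_subjects,
    faller_fraction = 1 / 6,
    seed = seed,
    kinematics = kinematics, emg = emg, sway = sway,
    ...
  )
}

default_profile <- function(group = "Non-faller") {
  list(
    group = group,
    baseline_deg = stats::setNames(numeric(4), c("ankle", "knee", "hip", "back")),
    response_scale = 1
  )
}

# gain (output/input amplitude ratio) of a filter function at a given
# frequency, measured on the central part of a long sine to avoid edges
measure_gain <- function(filter_fun, freq, rate, dur = 4) {
  t <- seq(0, dur, by = 1 / rate)
  x <- sin(2 * pi * freq * t)
  y <- filter_fun(x)
  core <- t > dur * 0.25 & t < dur * 0.75
  sqrt(mean(y[core]^2) / mean(x[core]^2))
}
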