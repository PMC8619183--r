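#' Support-surface perturbation motion profile
#'
#' Builds the piecewise-linear motion profile of the perturbation platform:
#' an anterior translation at constant velocity, followed by a toes-down tilt
#' at constant angular velocity, followed by a mirrored tilt back to level.
#' The default arguments are the protocol used throughout the package: 8 cm
#' anterior translation at 10 cm/s, then a 6 degree tilt at 11 deg/s.
#'
#' Time is expressed relative to perturbation onset, so `onset_time` is 0 and
#' `halt_time` marks the end of the tilt phase, when the platform rests in
#' its most anterior and tilted pose. A pre-onset and post-return pad of
#' quiet support surface is included so that feedforward windows and late
#' responses are covered.
#'
#' @param translation_cm Anterior translation amplitude (cm).
#' @param translation_velocity Translation velocity (cm/s).
#' @param tilt_deg Tilt amplitude (degrees).
#' @param tilt_velocity Tilt velocity (deg/s).
#' @param rate Sampling rate (Hz); the kinematic rate, default 200.
#' @param pre_s,post_s Quiet padding before onset and after the return phase
#'   (seconds).
#' @return A tibble of class `platform_trajectory` with columns `time_s`,
#'   `translation_cm`, `tilt_deg` and `phase`
#'   (`pre`/`translate`/`tilt`/`return`/`post`), and attributes `onset_time`,
#'   `halt_time`, `rate` and `degenerate`.
#' @examples
#' pf <- platform_profile()
#' attr(pf, "halt_time") # 0.8 s translation + ~0.545 s tilt
#' @export
platform_profile <- function(translation_cm = 8, translation_velocity = 10,
                             tilt_deg = 6, tilt_velocity = 11,
                             rate = 200, pre_s = 0.5, post_s = 0.5) {
  if (translation_cm < 0 || tilt_deg < 0 || pre_s < 0 || post_s < 0) {
    abort("amplitudes and paddings must be non-negative")
  }
  if (rate <= 0) abort("sampling rate must be positive")
  if (translation_cm > 0 && translation_velocity <= 0) {
    abort("invalid config: zero translation velocity with nonzero amplitude")
  }
  if (tilt_deg > 0 && tilt_velocity <= 0) {
    abort("invalid config: zero tilt velocity with nonzero amplitude")
  }

  d_translate <- if (translation_cm > 0) translation_cm / translation_velocity else 0
  d_tilt <- if (tilt_deg > 0) tilt_deg / tilt_velocity else 0
  onset <- 0
  halt <- d_translate + d_tilt
  end <- halt + d_tilt + post_s # return phase mirrors the tilt phase

  time_s <- seq(-pre_s, end, by = 1 / rate)
  translation <- pmin(pmax(time_s, 0) * translation_velocity, translation_cm)
  tilt <- numeric(length(time_s))
  if (d_tilt > 0) {
    up <- (time_s - d_translate) * tilt_velocity
    down <- tilt_deg - (time_s - halt) * tilt_velocity
    tilt <- pmax(pmin(up, down, tilt_deg), 0)
  }
  phase <- dplyr::case_when(
    time_s < onset ~ "pre",
    time_s < d_translate & d_translate > 0 ~ "translate",
    time_s < halt & d_tilt > 0 ~ "tilt",
    time_s < halt + d_tilt & d_tilt > 0 ~ "return",
    .default = "post"
  )

  out <- tibble(
    time_s = time_s,
    translation_cm = translation,
    tilt_deg = tilt,
    phase = phase
  )
  structure(out,
    class = c("platform_trajectory", class(out)),
    onset_time = onset, halt_time = halt, rate = rate,
    degenerate = halt <= onset
  )
}

#' Detect platform movement onset from a translation trace
#'
#' Fallback for recordings without an event channel: onset is the first time
#' the platform translation velocity exceeds a threshold and stays above it
#' for a sustain period.
#'
#' @param platform A `platform_trajectory` or tibble with `time_s` and
#'   `translation_cm`.
#' @param threshold_cm_s Velocity threshold (default 0.5 cm/s).
#' @param sustain_s Minimum time above threshold (default 0.05 s).
#' @return Onset time in seconds, or `NA` if never detected.
#' @export
detect_platform_onset <- function(platform, threshold_cm_s = 0.5,
                                  sustain_s = 0.05) {
  t <- platform$time_s
  v <- c(0, diff(platform$translation_cm)) / c(1, diff(t))
  dt <- stats::median(diff(t))
  need <- max(1L, ceiling(sustain_s / dt))
  above <- v > threshold_cm_s
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (length(hit) == 0) return(NA_real_)
  t[starts[hit[1]]]
}
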