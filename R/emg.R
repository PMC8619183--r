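#' Preprocess raw EMG into normalized muscle envelopes
#'
#' Standard surface-EMG reduction: each channel is band-pass filtered
#' 20-500 Hz (zero-phase Butterworth), rectified into a 50 ms centred
#' sliding-window RMS envelope, normalized by the muscle's maximal isometric
#' contraction (MVC) reference amplitude, and finally the left and right
#' channels of each muscle are averaged pointwise into one tibialis anterior
#' and one gastrocnemius envelope.
#'
#' @param raw_channels Tibble with `time_s` and channels `ta_left`,
#'   `ta_right`, `gm_left`, `gm_right` (mV), e.g. an `emg_recording`.
#' @param mvc_values Named numeric, MVC envelope maxima in mV per muscle
#'   (`ta`, `gm`); defaults to the recording's `mvc_mv` attribute.
#' @param rate Sampling rate (Hz); defaults to the recording's `rate`
#'   attribute, else inferred from `time_s`.
#' @param band Band-pass corners in Hz (default `c(20, 500)`).
#' @param order Butterworth order of each filter pass (default 8; steep
#'   enough that a 600 Hz component is rejected by more than 20 dB while
#'   the corners stay at -3 dB).
#' @param rms_window_s RMS window length (default 0.05 s).
#' @return Tibble with `time_s`, `ta`, `gm` (fraction of MVC), carrying the
#'   `rate` attribute.
#' @export
preprocess_emg <- function(raw_channels, mvc_values = attr(raw_channels, "mvc_mv"),
                           rate = attr(raw_channels, "rate"),
                           band = c(20, 500), order = 8,
                           rms_window_s = 0.05) {
  missing_ch <- setdiff(.emg_channels, names(raw_channels))
  if (length(missing_ch) > 0) {
    abort(paste0("missing EMG channels: ", toString(missing_ch)))
  }
  if (is.null(mvc_values) || !all(c("ta", "gm") %in% names(mvc_values))) {
    abort("MVC values for muscles 'ta' and 'gm' are required")
  }
  if (any(mvc_values[c("ta", "gm")] <= 0)) abort("MVC values must be > 0")
  if (is.null(rate)) {
    rate <- 1 / stats::median(diff(raw_channels$time_s))
  }
  env <- lapply(.emg_channels, function(ch) {
    muscle <- substr(ch, 1, 2)
    filt <- butter_zero_phase(raw_channels[[ch]], rate, "pass", band,
      order = order
    )
    moving_rms(filt, rate, rms_window_s) / mvc_values[[muscle]]
  })
  names(env) <- .emg_channels
  out <- tibble(
    time_s = raw_channels$time_s,
    ta = (env$ta_left + env$ta_right) / 2,
    gm = (env$gm_left + env$gm_right) / 2
  )
  attr(out, "rate") <- rate
  out
}

#' Detect muscle activation onset in an EMG envelope
#'
#' Automated threshold rule: the onset is the earliest time after platform
#' movement onset at which the envelope exceeds the baseline mean plus `k`
#' baseline standard deviations continuously for at least `sustain_s`.
#'
#' @param envelope Tibble with `time_s` and the envelope column (see
#'   `muscle`), e.g. from [preprocess_emg()].
#' @param platform_onset Platform movement onset (s), default 0.
#' @param baseline_window Two-element numeric, start/end (s) of the baseline
#'   window; must precede `platform_onset`.
#' @param k Threshold in baseline standard deviations (default 3).
#' @param sustain_s Minimum supra-threshold duration (default 0.025 s).
#' @param muscle Envelope column to use (default `"ta"`).
#' @return Onset time in seconds (same clock as `time_s`), or `NA_real_` if
#'   no onset is detected.
#' @export
detect_muscle_onset <- function(envelope, platform_onset = 0,
                                baseline_window = c(-0.4, -0.15),
                                k = 3, sustain_s = 0.025, muscle = "ta") {
  if (baseline_window[2] > platform_onset) {
    abort("baseline window must precede the platform onset")
  }
  t <- envelope$time_s
  x <- envelope[[muscle]]
  base <- x[t >= baseline_window[1] & t <= baseline_window[2]]
  if (length(base) == 0) abort("baseline window contains no samples")
  thr <- mean(base) + k * stats::sd(base)
  after <- which(t > platform_onset)
  if (length(after) == 0) return(NA_real_)
  dt <- stats::median(diff(t))
  need <- max(1L, ceiling(sustain_s / dt))
  above <- x[after] > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (length(hit) == 0) return(NA_real_)
  t[after[starts[hit[1]]]]
}

#' Co-contraction index of an agonist-antagonist muscle pair
#'
#' Per-sample index
#' `CCI(t) = (lower(t) / higher(t)) * (lower(t) + higher(t))`,
#' where `lower`/`higher` are the smaller and larger of the two normalized
#' envelopes at each instant (0 where both are silent), averaged over the
#' requested period. The index is symmetric in its arguments, equals twice
#' the common level under perfectly matched activation, and is zero when
#' either muscle is silent.
#'
#' @param envelope_a,envelope_b Non-negative numeric envelopes, aligned
#'   sample by sample.
#' @param time_s Optional time vector (needed when `period` is given).
#' @param period Optional two-element numeric `c(start, end)`; the mean is
#'   taken over samples with `start <= time_s <= end`.
#' @return Mean CCI over the period (scalar).
#' @examples
#' compute_cci(rep(1, 10), rep(3, 10)) # (1/3) * 4 = 4/3
#' @export
compute_cci <- function(envelope_a, envelope_b, time_s = NULL, period = NULL) {
  if (any(envelope_a < 0, na.rm = TRUE) || any(envelope_b < 0, na.rm = TRUE)) {
    abort("envelopes are magnitudes and must be non-negative")
  }
  if (length(envelope_a) != length(envelope_b)) {
    abort("envelopes differ in length")
  }
  cci <- cci_samples(envelope_a, envelope_b)
  if (!is.null(period)) {
    if (is.null(time_s)) abort("time_s is required when period is given")
    sel <- time_s >= period[1] - 1e-9 & time_s <= period[2] + 1e-9
    if (!any(sel)) abort("period contains no samples")
    cci <- cci[sel]
  }
  mean(cci)
}

#' Per-sample co-contraction index
#'
#' @inheritParams compute_cci
#' @return Numeric vector of per-sample CCI values.
#' @export
cci_samples <- function(envelope_a, envelope_b) {
  lo <- pmin(envelope_a, envelope_b)
  hi <- pmax(envelope_a, envelope_b)
  ifelse(hi == 0, 0, lo / hi * (lo + hi))
}

#' EMG features of one perturbation trial
#'
#' Computes the feedforward co-contraction index (mean CCI over the 100 ms
#' window ending at platform onset, half-open like the kinematic window),
#' the tibialis anterior onset, and the feedback co-contraction index (mean
#' CCI from the tibialis onset until the platform halt). If no onset is
#' detected, or the onset falls at/after the halt, the feedback feature is
#' returned as `NA` while the feedforward feature is still computed.
#'
#' @param envelopes Tibble with `time_s`, `ta`, `gm` from
#'   [preprocess_emg()].
#' @param platform_onset Platform onset (s), default 0.
#' @param halt_time Platform halt (s).
#' @param ff_window_s Feedforward window length (default 0.1 s).
#' @param ... Passed to [detect_muscle_onset()].
#' @return One-row tibble: `cci_feedforward`, `cci_feedback`,
#'   `ta_onset_time` (s after platform onset).
#' @export
emg_trial_features <- function(envelopes, platform_onset = 0, halt_time,
                               ff_window_s = 0.1, ...) {
  t <- envelopes$time_s
  cci <- cci_samples(envelopes$ta, envelopes$gm)
  ff_sel <- t >= platform_onset - ff_window_s - 1e-9 &
    t < platform_onset - 1e-9
  if (!any(ff_sel)) abort("no samples in the feedforward window")
  cci_ff <- mean(cci[ff_sel])

  onset <- detect_muscle_onset(envelopes, platform_onset, ...)
  if (is.na(onset) || onset >= halt_time) {
    cci_fb <- NA_real_
  } else {
    fb_sel <- t >= onset - 1e-9 & t <= halt_time + 1e-9
    cci_fb <- mean(cci[fb_sel])
  }
  tibble(
    cci_feedforward = cci_ff,
    cci_feedback = cci_fb,
    ta_onset_time = if (is.na(onset)) NA_real_ else onset - platform_onset
  )
}

#' Extract EMG features from a raw recording
#'
#' Convenience wrapper chaining [preprocess_emg()] and
#' [emg_trial_features()] using the onset/halt times carried by the
#' recording.
#'
#' @param emg An `emg_recording` (e.g. from [simulate_trial_emg()]).
#' @param ... Passed to [emg_trial_features()].
#' @return One-row tibble of EMG features.
#' @export
extract_emg_features <- function(emg, ...) {
  env <- preprocess_emg(emg)
  emg_trial_features(env,
    platform_onset = attr(emg, "onset_time"),
    halt_time = attr(emg, "halt_time"), ...
  )
}
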