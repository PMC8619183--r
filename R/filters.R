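#' Zero-phase Butterworth filtering with corner compensation
#'
#' Filters a signal forward and backward with a Butterworth design
#' ([signal::filtfilt()]), which doubles the effective order and removes phase
#' distortion. Because two passes square the magnitude response, a filter
#' designed directly at the nominal cutoff would sit at -6 dB there; the
#' design cutoffs are therefore shifted (in the prewarped analog domain) so
#' that the *two-pass* response is -3 dB at the requested corner
#' frequencies.
#'
#' @param x Numeric vector, uniformly sampled.
#' @param rate Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"pass"`.
#' @param cutoff Corner frequency in Hz (length 2 for `"pass"`).
#' @param order Butterworth order of each pass (default 4).
#' @return Filtered numeric vector, same length as `x`.
#' @examples
#' t <- seq(0, 2, by = 1 / 200)
#' x <- sin(2 * pi * 2 * t) + sin(2 * pi * 60 * t)
#' y <- butter_zero_phase(x, 200, "low", 10)
#' @export
butter_zero_phase <- function(x, rate, type = c("low", "high", "pass"),
                              cutoff, order = 4) {
  type <- match.arg(type)
  stopifnot(is.numeric(x), rate > 0, all(cutoff > 0))
  if (any(rate <= 2 * cutoff)) {
    abort("sampling rate must exceed twice the cutoff frequency")
  }
  # single-pass attenuation at the corner must be -1.5 dB so that the
  # two-pass response lands at -3 dB: |H|^2 = 2^(-1/2) at the corner
  r <- (sqrt(2) - 1)^(1 / (2 * order))
  design_freq <- function(f0, widen) {
    # solve for the design cutoff in the prewarped (tan) domain
    w <- tan(pi * f0 / rate)
    wc <- if (widen) w / r else w * r
    rate / pi * atan(wc)
  }
  apply_filt <- function(x, type1, fc) {
    bf <- signal::butter(order, 2 * fc / rate, type = type1)
    signal::filtfilt(bf, x)
  }
  switch(type,
    low  = apply_filt(x, "low", design_freq(cutoff[1], widen = TRUE)),
    high = apply_filt(x, "high", design_freq(cutoff[1], widen = FALSE)),
    pass = {
      if (length(cutoff) != 2) abort("band-pass needs two cutoff frequencies")
      # cascade of compensated high- and low-pass; for a wide band this
      # keeps each corner independently at -3 dB after both passes
      y <- apply_filt(x, "high", design_freq(min(cutoff), widen = FALSE))
      apply_filt(y, "low", design_freq(max(cutoff), widen = TRUE))
    }
  )
}

#' Centred sliding-window RMS envelope
#'
#' Root-mean-square of `x` over a centred window. The window length is
#' rounded to the nearest odd sample count; at the edges the window is
#' truncated to the available samples.
#'
#' @param x Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param window_s Window length in seconds (default 0.05, i.e. 50 ms).
#' @return Numeric vector of the same length.
#' @export
moving_rms <- function(x, rate, window_s = 0.05) {
  stopifnot(is.numeric(x), rate > 0, window_s > 0)
  n <- length(x)
  k <- round(window_s * rate)
  if (k %% 2 == 0) k <- k + 1
  half <- (k - 1) / 2
  cs <- cumsum(c(0, x^2))
  i <- seq_len(n)
  i1 <- pmax(i - half, 1)
  i2 <- pmin(i + half, n)
  sqrt((cs[i2 + 1] - cs[i1]) / (i2 - i1 + 1))
}

# unit-RMS band-limited Gaussian noise carrier (draws from the current RNG
# stream); used by the EMG simulator. Corner precision is irrelevant for a
# noise carrier, so a plain (uncompensated) band-pass is enough.
band_limited_noise <- function(n, rate, band = c(20, 450)) {
  e <- rnorm(n)
  bf <- signal::butter(4, 2 * band / rate, type = "pass")
  y <- signal::filtfilt(bf, e)
  y / sqrt(mean(y^2))
}
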