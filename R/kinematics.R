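#' Re-reference joint angles to the quiet-stance posture
#'
#' Subtracts each subject's quiet-stance reference angle from the raw joint
#' angle series, so that zero degrees is the erect standing posture and
#' positive values indicate flexion of back, hip and knee and plantar
#' flexion of the ankle.
#'
#' @param angles Wide tibble of joint-angle series: a `time_s` column plus
#'   any of `ankle_left`, `ankle_right`, `knee_left`, `knee_right`,
#'   `hip_left`, `hip_right`, `back` (degrees).
#' @param reference Named numeric vector of reference angles. Names may be
#'   series columns (`"ankle_left"`) or bare joints (`"ankle"`, applied to
#'   both sides). Every series present in `angles` must have a reference.
#' @return The re-referenced tibble, same shape as `angles`.
#' @examples
#' a <- tibble::tibble(time_s = 0:1, back = c(5, 6))
#' normalize_to_quiet_stance(a, c(back = 5))
#' @export
normalize_to_quiet_stance <- function(angles, reference) {
  cols <- setdiff(names(angles), "time_s")
  out <- angles
  for (col in cols) {
    joint <- sub("_(left|right)$", "", col)
    ref <- if (col %in% names(reference)) {
      reference[[col]]
    } else if (joint %in% names(reference)) {
      reference[[joint]]
    } else {
      NULL
    }
    if (is.null(ref) || is.na(ref)) {
      abort(paste0("missing quiet-stance reference for joint series: ", col))
    }
    out[[col]] <- angles[[col]] - ref
  }
  out
}

#' Pointwise average of left and right joint-angle series
#'
#' @param left_series,right_series Numeric vectors of equal length sampled
#'   at the same rate.
#' @return Numeric vector of pointwise means.
#' @export
bilateral_average <- function(left_series, right_series) {
  if (is.null(left_series) || is.null(right_series)) {
    abort("both sides are required for bilateral averaging")
  }
  if (length(left_series) != length(right_series)) {
    abort("left and right series differ in length")
  }
  (left_series + right_series) / 2
}

#' Collapse sided joint-angle columns to one series per joint
#'
#' Applies [bilateral_average()] to the left/right ankle, knee and hip
#' columns; the back column passes through.
#'
#' @inheritParams normalize_to_quiet_stance
#' @return Tibble with `time_s` and one column per joint present.
#' @export
average_sides <- function(angles) {
  out <- tibble(time_s = angles$time_s)
  for (j in .sided_joints) {
    l <- angles[[paste0(j, "_left")]]
    r <- angles[[paste0(j, "_right")]]
    if (!is.null(l) || !is.null(r)) {
      out[[j]] <- bilateral_average(l, r)
    }
  }
  if (!is.null(angles$back)) out$back <- angles$back
  for (a in c("rate", "onset_time", "halt_time")) {
    attr(out, a) <- attr(angles, a)
  }
  out
}

#' Feedforward posture: mean joint angles over the pre-onset window
#'
#' Averages each joint-angle series over the anticipatory window, by default
#' the 100 ms immediately preceding platform movement onset. The window is
#' half-open, `[onset - window_s, onset)`, so the onset sample itself is not
#' included; at 200 Hz the default window contains exactly 20 samples.
#'
#' @param angles Wide tibble with `time_s` plus joint series (typically
#'   after [average_sides()]).
#' @param onset_time Platform onset (s), default 0.
#' @param window_s Window length (s), default 0.1.
#' @return One-row tibble of per-series means.
#' @export
feedforward_posture <- function(angles, onset_time = 0, window_s = 0.1) {
  t0 <- onset_time - window_s
  if (min(angles$time_s) > t0 + 1e-9) {
    abort("feedforward window extends before the start of the recording")
  }
  sel <- angles$time_s >= t0 - 1e-9 & angles$time_s < onset_time - 1e-9
  if (!any(sel)) abort("no samples in the feedforward window")
  cols <- setdiff(names(angles), "time_s")
  tibble::as_tibble_row(
    vapply(angles[sel, cols, drop = FALSE], mean, numeric(1))
  )
}

#' Feedback range: maximum flexion and extension during the perturbation
#'
#' Extracts, per joint, the maximum flexion (positive) excursion and the
#' maximum extension (negative) excursion over the period from platform
#' movement onset until the platform halts in its most anterior, tilted
#' pose. Both magnitudes are floored at zero: a joint that never crosses
#' neutral in one direction scores 0 for that direction.
#'
#' @inheritParams feedforward_posture
#' @param halt_time End of the platform movement (s).
#' @return Tibble with one row per joint: `joint`, `max_flexion`,
#'   `max_extension` (degrees, both >= 0).
#' @export
feedback_range <- function(angles, onset_time = 0, halt_time) {
  if (onset_time >= halt_time) abort("onset_time must precede halt_time")
  sel <- angles$time_s >= onset_time - 1e-9 & angles$time_s <= halt_time + 1e-9
  if (!any(sel)) abort("no samples in the feedback period")
  cols <- setdiff(names(angles), "time_s")
  purrr::map_dfr(cols, function(col) {
    x <- angles[[col]][sel]
    tibble(
      joint = col,
      max_flexion = max(max(x), 0),
      max_extension = max(-min(x), 0)
    )
  })
}

#' Extract all kinematic features of one trial
#'
#' Convenience wrapper: averages sides, then computes the feedforward mean
#' angle per joint and the feedback maximum flexion/extension per joint,
#' using the onset and halt times carried by the recording.
#'
#' @param angles A `joint_angle_set` (e.g. from
#'   [simulate_trial_kinematics()]) whose `onset_time`/`halt_time`
#'   attributes are set, or pass them explicitly.
#' @param onset_time,halt_time Override the recording's attributes.
#' @return One-row tibble with columns `ff_<joint>`, `fb_<joint>_flex`,
#'   `fb_<joint>_ext`.
#' @export
extract_kinematic_features <- function(angles,
                                       onset_time = attr(angles, "onset_time"),
                                       halt_time = attr(angles, "halt_time")) {
  avg <- average_sides(angles)
  ff <- feedforward_posture(avg, onset_time)
  names(ff) <- paste0("ff_", names(ff))
  fb <- feedback_range(avg, onset_time, halt_time)
  fb_wide <- tibble::as_tibble_row(setNames(
    c(fb$max_flexion, fb$max_extension),
    c(paste0("fb_", fb$joint, "_flex"), paste0("fb_", fb$joint, "_ext"))
  ))
  dplyr::bind_cols(ff, fb_wide)
}
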