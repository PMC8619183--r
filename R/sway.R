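#' Low-pass filter a centre-of-pressure trace
#'
#' Zero-phase Butterworth low-pass, 10 Hz cutoff by default, applied to both
#' the anteroposterior and mediolateral components.
#'
#' @param trace Tibble with `time_s`, `ap_cm`, `ml_cm` (e.g. a `cop_trace`).
#' @param cutoff Cutoff frequency (Hz), default 10.
#' @param rate Sampling rate (Hz); defaults to the trace's `rate` attribute,
#'   else inferred from `time_s`.
#' @return The filtered trace, same shape and attributes.
#' @export
filter_cop <- function(trace, cutoff = 10, rate = attr(trace, "rate")) {
  if (is.null(rate)) rate <- 1 / stats::median(diff(trace$time_s))
  if (rate <= 2 * cutoff) {
    abort("sampling rate must exceed twice the cutoff frequency")
  }
  out <- trace
  out$ap_cm <- butter_zero_phase(trace$ap_cm, rate, "low", cutoff)
  out$ml_cm <- butter_zero_phase(trace$ml_cm, rate, "low", cutoff)
  out
}

#' Sway prediction ellipse from a COP point swarm
#'
#' Fits the PCA prediction ellipse expected to enclose a given fraction of
#' the centre-of-pressure points: the points are mean-centred, the 2x2
#' sample covariance is eigendecomposed (the PCA step), and the ellipse
#' semi-axes along the eigenvectors are `sqrt(chisq(coverage, 2) * lambda)`.
#' The area is `pi * chisq(coverage, 2) * sqrt(lambda1 * lambda2)`.
#'
#' @param points Two-column matrix or data frame of AP/ML coordinates (cm);
#'   columns named `ap_cm`/`ml_cm` are used when present, otherwise the
#'   first two numeric columns.
#' @param coverage Nominal enclosed fraction, default 0.95.
#' @return One-row tibble: `area_cm2`, `enclosed_frac` (realised fraction of
#'   points inside the ellipse), `lambda_1`, `lambda_2` (eigenvalues),
#'   `angle_deg` (orientation of the major axis), `degenerate` (TRUE when
#'   the swarm is collinear or a single point, in which case the area is 0).
#' @examples
#' set.seed(1)
#' pts <- matrix(rnorm(2000), ncol = 2)
#' sway_ellipse(pts)$area_cm2 # ~ pi * 5.991 = 18.8
#' @export
sway_ellipse <- function(points, coverage = 0.95) {
  if (coverage <= 0 || coverage >= 1) abort("coverage must lie in (0, 1)")
  m <- .as_ap_ml(points)
  if (nrow(m) < 3) abort("at least 3 points are required")
  ctr <- colMeans(m)
  cc <- sweep(m, 2, ctr)
  S <- crossprod(cc) / (nrow(m) - 1)
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  q <- stats::qchisq(coverage, df = 2)
  degenerate <- lam[1] <= 0 || lam[2] <= lam[1] * 1e-12
  if (degenerate) {
    return(tibble(
      area_cm2 = 0, enclosed_frac = NA_real_,
      lambda_1 = lam[1], lambda_2 = lam[2],
      angle_deg = NA_real_, degenerate = TRUE
    ))
  }
  d2 <- stats::mahalanobis(m, ctr, S)
  tibble(
    area_cm2 = pi * q * sqrt(lam[1] * lam[2]),
    enclosed_frac = mean(d2 <= q),
    lambda_1 = lam[1], lambda_2 = lam[2],
    angle_deg = atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi,
    degenerate = FALSE
  )
}

#' Sway ellipse area
#'
#' Scalar shortcut for [sway_ellipse()]: the area (cm^2) of the prediction
#' ellipse, 0 (with a `degenerate` attribute) for a collinear or constant
#' point swarm.
#'
#' @inheritParams sway_ellipse
#' @return Area in cm^2.
#' @export
ellipse_area <- function(points, coverage = 0.95) {
  e <- sway_ellipse(points, coverage)
  out <- e$area_cm2
  if (e$degenerate) attr(out, "degenerate") <- TRUE
  out
}

.as_ap_ml <- function(points) {
  if (is.matrix(points)) {
    storage.mode(points) <- "double"
    return(points[, 1:2, drop = FALSE])
  }
  df <- as.data.frame(points)
  if (all(c("ap_cm", "ml_cm") %in% names(df))) {
    return(cbind(df$ap_cm, df$ml_cm))
  }
  num <- df[vapply(df, is.numeric, logical(1))]
  num <- num[setdiff(names(num), "time_s")]
  if (ncol(num) < 2) abort("need two numeric coordinate columns")
  as.matrix(num[, 1:2])
}

#' Sway features: ellipse area per stance condition
#'
#' Filters each trace ([filter_cop()]) and computes the prediction-ellipse
#' area.
#'
#' @param traces Named list of COP traces (names = condition labels), or a
#'   single trace with a `condition` attribute.
#' @param coverage Ellipse coverage, default 0.95.
#' @param cutoff Low-pass cutoff (Hz), default 10.
#' @return Tibble with `condition` and `area_cm2`.
#' @export
extract_sway_features <- function(traces, coverage = 0.95, cutoff = 10) {
  if (is.data.frame(traces)) {
    traces <- setNames(list(traces), attr(traces, "condition") %||% "trace")
  }
  purrr::imap_dfr(traces, function(tr, cond) {
    f <- filter_cop(tr, cutoff)
    tibble(
      condition = cond,
      area_cm2 = ellipse_area(f[, c("ap_cm", "ml_cm")], coverage)
    )
  })
}
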