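#' Coefficient plot for an OPLS-DA coefficient report
#'
#' Horizontal bars of the model coefficients with jackknife confidence
#' intervals; variables whose interval excludes zero (significant for the
#' discrimination) are highlighted. Bars to the positive side indicate
#' higher values in the positive class.
#'
#' @param object A `coefficient_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coefficient_report <- function(object, ...) {
  df <- as_tibble(object)
  df$variable <- stats::reorder(df$variable, df$coefficient)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$coefficient, y = .data$variable, fill = .data$significant
  )) +
    ggplot2::geom_col(width = 0.75) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.3, linewidth = 0.3
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "grey70", `FALSE` = "grey30"),
      name = "CI excludes 0"
    ) +
    ggplot2::labs(
      x = paste0("coefficient (positive = higher in ",
        attr(object, "positive") %||% "positive class", ")"
      ),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Permutation plot
#'
#' R2Y and Q2 of label-permuted models against the absolute correlation of
#' the permuted class vector with the original, with the original model at
#' correlation 1 and the regression lines whose intercepts summarise the
#' validation.
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_result <- function(object, ...) {
  pts <- tidyr::pivot_longer(object$points,
    dplyr::all_of(c("R2Y", "Q2")),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(pts, ggplot2::aes(
    x = .data$correlation, y = .data$value,
    colour = .data$metric, shape = .data$permutation == 0
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(
      method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4,
      fullrange = TRUE
    ) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 17, `FALSE` = 16), guide = "none"
    ) +
    ggplot2::labs(
      x = "|correlation(permuted class, original class)|",
      y = NULL,
      subtitle = sprintf(
        "intercepts: R2Y %.3f, Q2 %.3f; verdict %s",
        object$r2y_intercept, object$q2_intercept, object$verdict
      )
    ) +
    ggplot2::theme_minimal()
}

#' Scree / loading plot for a NIPALS PCA fit
#'
#' With two or more components, plots the score swarm of the first two
#' components; with one component, a loading bar chart.
#'
#' @param object A `pca_nipals` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_nipals <- function(object, ...) {
  if (object$n_components >= 2) {
    df <- tibble(t1 = object$scores[, 1], t2 = object$scores[, 2])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$t1, y = .data$t2)) +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = sprintf("PC1 (%.1f%%)", 100 * object$R2[1]),
        y = sprintf("PC2 (%.1f%%)", 100 * object$R2[2])
      ) +
      ggplot2::theme_minimal()
  } else {
    df <- tidy.pca_nipals(object)
    df$variable <- stats::reorder(df$variable, df$loading)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$loading, y = .data$variable)) +
      ggplot2::geom_col() +
      ggplot2::labs(
        x = sprintf("PC1 loading (R2 = %.1f%%)", 100 * object$R2[1]), y = NULL
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot a COP point swarm with its prediction ellipse
#'
#' @param points Two-column AP/ML coordinates (cm).
#' @param coverage Ellipse coverage, default 0.95.
#' @return A ggplot object.
#' @export
plot_sway_ellipse <- function(points, coverage = 0.95) {
  m <- .as_ap_ml(points)
  e <- sway_ellipse(m, coverage)
  ctr <- colMeans(m)
  theta <- seq(0, 2 * pi, length.out = 181)
  q <- stats::qchisq(coverage, 2)
  ang <- e$angle_deg * pi / 180
  a <- sqrt(q * e$lambda_1)
  b <- sqrt(q * e$lambda_2)
  ell <- tibble(
    ap = ctr[1] + a * cos(theta) * cos(ang) - b * sin(theta) * sin(ang),
    ml = ctr[2] + a * cos(theta) * sin(ang) + b * sin(theta) * cos(ang)
  )
  df <- tibble(ap = m[, 1], ml = m[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ap, y = .data$ml)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_path(data = ell, colour = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "AP (cm)", y = "ML (cm)",
      subtitle = sprintf("%.0f%% ellipse, area %.2f cm^2",
        100 * coverage, e$area_cm2
      )
    ) +
    ggplot2::theme_minimal()
}
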