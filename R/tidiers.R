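#' Tidy a NIPALS PCA fit
#'
#' @param x A `pca_nipals` object.
#' @param ... Unused.
#' @return Tibble with `variable`, `component`, `loading`.
#' @export
tidy.pca_nipals <- function(x, ...) {
  p <- x$loadings
  tibble(
    variable = rep(rownames(p) %||% paste0("V", seq_len(nrow(p))),
      times = ncol(p)
    ),
    component = rep(seq_len(ncol(p)), each = nrow(p)),
    loading = as.numeric(p)
  )
}

#' @rdname tidy.pca_nipals
#' @export
glance.pca_nipals <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    r2 = sum(x$R2),
    q2 = x$Q2
  )
}

#' Tidy an OPLS-DA fit
#'
#' @param x An `oplsda` object.
#' @param ... Unused.
#' @return Tibble with `variable`, `weight` (predictive), `loading`,
#'   `coefficient`.
#' @export
tidy.oplsda <- function(x, ...) {
  tibble(
    variable = x$variables,
    weight = unname(x$w),
    loading = unname(x$p),
    coefficient = unname(x$coefficients)
  )
}

#' @rdname tidy.oplsda
#' @export
glance.oplsda <- function(x, ...) {
  tibble(
    n = x$n, n_orth = x$n_orth, r2y = x$R2Y, q2 = x$Q2,
    positive = x$positive
  )
}

#' Tidy a permutation validation result
#'
#' @param x A `permutation_result` object.
#' @param ... Unused.
#' @return The permutation points tibble (`permutation`, `correlation`,
#'   `R2Y`, `Q2`); permutation 0 is the original model.
#' @export
tidy.permutation_result <- function(x, ...) x$points

#' @rdname tidy.permutation_result
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(
    n_perms = x$n_perms,
    r2y_intercept = x$r2y_intercept,
    q2_intercept = x$q2_intercept,
    prop_q2_ge = x$prop_q2_ge,
    verdict = x$verdict
  )
}

#' Tidy an analysis report
#'
#' @param x An `analysis_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The coefficient report of the top model.
#' @export
tidy.analysis_report <- function(x, ...) as_tibble(x$coefficients)

#' @rdname tidy.analysis_report
#' @export
glance.analysis_report <- function(x, ...) {
  tibble(
    n = nrow(x$features),
    n_fallers = sum(x$features$class == "Faller"),
    r2y = x$top_model$R2Y,
    q2 = x$top_model$Q2,
    n_significant = sum(x$coefficients$significant),
    permutation_verdict = x$permutation$verdict
  )
}
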