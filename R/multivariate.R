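#' Unit-variance (UV) scaling of a feature table
#'
#' Mean-centres every numeric column and divides it by its standard
#' deviation, both computed ignoring missing entries. Columns with zero
#' variance cannot be scaled and are dropped with a warning. Non-numeric
#' columns (ids, class labels) pass through untouched.
#'
#' @param table Data frame of subjects x variables.
#' @param exclude Character vector of column names to pass through without
#'   scaling (in addition to non-numeric columns).
#' @return The scaled tibble with attributes `uv_center` and `uv_scale`
#'   (named numeric vectors over the scaled columns).
#' @export
scale_uv <- function(table, exclude = character()) {
  if (nrow(table) < 2) abort("UV scaling needs at least 2 rows")
  out <- as_tibble(table)
  num_cols <- names(out)[vapply(out, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, exclude)
  ctr <- scl <- setNames(numeric(0), character(0))
  dropped <- character(0)
  for (col in num_cols) {
    m <- mean(out[[col]], na.rm = TRUE)
    s <- stats::sd(out[[col]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      dropped <- c(dropped, col)
      next
    }
    out[[col]] <- (out[[col]] - m) / s
    ctr[col] <- m
    scl[col] <- s
  }
  if (length(dropped) > 0) {
    warn(paste0("dropping zero-variance columns: ", toString(dropped)))
    out <- out[setdiff(names(out), dropped)]
  }
  attr(out, "uv_center") <- ctr
  attr(out, "uv_scale") <- scl
  out
}

#' PCA by NIPALS with missing-value support
#'
#' Fits principal components with the iterative NIPALS algorithm, which
#' tolerates missing entries by restricting each projection sum to observed
#' cells. Input is expected to be centred (and usually UV-scaled, see
#' [scale_uv()]); no centring is applied internally. Components are
#' extracted sequentially with deflation; each loading is unit norm and the
#' sign is fixed so the largest-magnitude loading is positive.
#'
#' @param X Numeric matrix or data frame (subjects x variables), centred;
#'   `NA`s allowed.
#' @param n_components Number of components to extract.
#' @param tol Relative convergence tolerance on the score vector
#'   (default 1e-8).
#' @param max_iter Maximum NIPALS iterations per component (default 5000);
#'   exceeded iterations raise an error reporting the count. NIPALS
#'   converges linearly at the ratio of the first two eigenvalues, so
#'   nearly isotropic matrices need many cheap iterations.
#' @param compute_q2 Also estimate a cross-validated Q2 by element-wise
#'   deletion (see [pca_q2()]). Default `TRUE`.
#' @param q2_folds Folds for the Q2 deletion pattern (default 7).
#' @return An object of class `pca_nipals`: list with `scores` (n x k),
#'   `loadings` (p x k), `R2` (variance fraction per component), `Q2`,
#'   `n_components`, `iterations`.
#' @export
fit_pca_nipals <- function(X, n_components = 2, tol = 1e-8, max_iter = 5000,
                           compute_q2 = TRUE, q2_folds = 7) {
  Xm <- .as_numeric_matrix(X)
  n <- nrow(Xm)
  p <- ncol(Xm)
  if (n_components > min(n, p)) {
    abort("n_components exceeds the rank bound min(n, p)")
  }
  ss_total <- sum(Xm^2, na.rm = TRUE)
  scores <- matrix(NA_real_, n, n_components)
  loadings <- matrix(NA_real_, p, n_components,
    dimnames = list(colnames(Xm), NULL)
  )
  iters <- integer(n_components)
  R2 <- numeric(n_components)
  Xr <- Xm
  ss_prev <- ss_total
  for (k in seq_len(n_components)) {
    fit <- .nipals_component(Xr, tol, max_iter)
    t <- fit$t
    pvec <- fit$p
    # sign convention: dominant loading positive
    j <- which.max(abs(pvec))
    if (pvec[j] < 0) {
      pvec <- -pvec
      t <- -t
    }
    scores[, k] <- t
    loadings[, k] <- pvec
    iters[k] <- fit$iter
    Xr <- Xr - tcrossprod(t, pvec)
    ss_k <- sum(Xr^2, na.rm = TRUE)
    R2[k] <- (ss_prev - ss_k) / ss_total
    ss_prev <- ss_k
  }
  out <- structure(
    list(
      scores = scores, loadings = loadings, R2 = R2, Q2 = NA_real_,
      n_components = n_components, iterations = iters,
      ss_total = ss_total
    ),
    class = "pca_nipals"
  )
  if (compute_q2) {
    out$Q2 <- pca_q2(Xm, n_components,
      folds = q2_folds, tol = tol,
      max_iter = max_iter
    )
  }
  out
}

# one NIPALS component on (possibly incomplete) residual matrix
.nipals_component <- function(Xr, tol, max_iter) {
  M <- !is.na(Xr)
  X0 <- Xr
  X0[!M] <- 0
  Mn <- matrix(as.numeric(M), nrow(Xr), ncol(Xr))
  # start from the column with the largest observed sum of squares
  start <- which.max(colSums(X0^2))
  t <- X0[, start]
  if (all(t == 0)) t <- rnorm(nrow(Xr))
  for (iter in seq_len(max_iter)) {
    denom_p <- as.numeric(crossprod(Mn, t^2))
    p <- as.numeric(crossprod(X0, t)) / ifelse(denom_p == 0, 1, denom_p)
    p <- p / sqrt(sum(p^2))
    denom_t <- as.numeric(Mn %*% p^2)
    t_new <- as.numeric(X0 %*% p) / ifelse(denom_t == 0, 1, denom_t)
    delta <- sqrt(sum((t_new - t)^2)) / max(sqrt(sum(t_new^2)), 1e-300)
    t <- t_new
    if (delta < tol) {
      return(list(t = t, p = p, iter = iter))
    }
  }
  abort(paste0(
    "NIPALS did not converge within ", max_iter, " iterations"
  ))
}

#' Cross-validated Q2 of a PCA model by element-wise deletion
#'
#' Estimates how well a `n_components` PCA predicts left-out cells: matrix
#' elements are assigned to folds in a diagonal pattern, each fold's cells
#' are set to missing in turn, the model is refit by NIPALS (which skips
#' missing cells) and the deleted cells are predicted from the refitted
#' scores and loadings. `Q2 = 1 - PRESS / SS` over all deleted cells.
#'
#' @inheritParams fit_pca_nipals
#' @param folds Number of deletion folds (default 7).
#' @return Scalar Q2 (can be negative for models with no predictive power).
#' @export
pca_q2 <- function(X, n_components = 1, folds = 7, tol = 1e-8,
                   max_iter = 5000) {
  Xm <- .as_numeric_matrix(X)
  n <- nrow(Xm)
  p <- ncol(Xm)
  idx <- outer(seq_len(n), seq_len(p), function(i, j) (i + j) %% folds)
  press <- 0
  ss <- 0
  for (g in 0:(folds - 1)) {
    del <- idx == g & !is.na(Xm)
    if (!any(del)) next
    Xd <- Xm
    Xd[del] <- NA
    # a fully deleted row or column cannot be refit; skip those cells
    ok_row <- rowSums(!is.na(Xd)) > 0
    ok_col <- colSums(!is.na(Xd)) > 0
    if (!all(ok_row) || !all(ok_col)) {
      del[!ok_row, ] <- FALSE
      del[, !ok_col] <- FALSE
      Xd <- Xm
      Xd[del] <- NA
    }
    fit <- fit_pca_nipals(Xd, n_components,
      tol = tol, max_iter = max_iter,
      compute_q2 = FALSE
    )
    Xhat <- fit$scores %*% t(fit$loadings)
    press <- press + sum((Xm[del] - Xhat[del])^2)
    ss <- ss + sum(Xm[del]^2)
  }
  1 - press / ss
}

#' Fit hierarchical PCA base models and append their scores
#'
#' For each named construct (e.g. fall-related concerns, balance, strength,
#' joint position sense) a one-component NIPALS PCA is fit on the
#' corresponding sub-table of variables, the component score is appended as
#' a new column `score_<construct>`, and the constituent variables are
#' removed from the table so that the top model sees each construct once.
#' Input should already be UV-scaled; construct sub-tables are used as-is.
#'
#' Each base-model score is oriented so that it correlates positively with
#' its dominant variable (the NIPALS sign convention), making coefficient
#' directions reproducible.
#'
#' @param table UV-scaled feature tibble (see [scale_uv()]).
#' @param construct_map Named list: construct name -> character vector of at
#'   least two column names.
#' @param ... Passed to [fit_pca_nipals()].
#' @return The modified tibble with an attribute `base_models` (named list
#'   of `pca_nipals` fits).
#' @export
fit_base_models <- function(table, construct_map, ...) {
  out <- as_tibble(table)
  models <- list()
  for (nm in names(construct_map)) {
    vars <- construct_map[[nm]]
    present <- intersect(vars, names(out))
    if (length(present) < 2) {
      abort(paste0(
        "construct '", nm, "' has fewer than 2 available variables"
      ))
    }
    sub <- .as_numeric_matrix(out[present])
    fit <- fit_pca_nipals(sub, n_components = 1, ...)
    out[[paste0("score_", nm)]] <- fit$scores[, 1]
    out <- out[setdiff(names(out), present)]
    models[[nm]] <- fit
  }
  attr(out, "base_models") <- models
  out
}

.as_numeric_matrix <- function(X) {
  if (is.matrix(X)) {
    storage.mode(X) <- "double"
    return(X)
  }
  df <- as.data.frame(X)
  num <- df[vapply(df, is.numeric, logical(1))]
  m <- as.matrix(num)
  rownames(m) <- rownames(df)
  m
}
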