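# encode a binary class vector as 0/1 with a declared positive class
.encode_class <- function(y, positive = NULL) {
  if (is.logical(y)) y <- ifelse(y, "TRUE", "FALSE")
  if (is.factor(y)) y <- as.character(y)
  lev <- sort(unique(as.character(y)))
  if (length(lev) < 2) abort("class label has a single level; need two")
  if (length(lev) > 2) abort("only binary class labels are supported")
  positive <- positive %||% lev[2]
  if (!positive %in% lev) abort(paste0("positive class '", positive, "' absent"))
  list(
    y01 = as.numeric(as.character(y) == positive),
    levels = lev, positive = positive
  )
}

# prepare the predictor matrix: numeric, NAs imputed to the (scaled) mean
.prepare_X <- function(X) {
  Xm <- .as_numeric_matrix(X)
  if (anyNA(Xm)) Xm[is.na(Xm)] <- 0 # UV-scaled input: 0 is the column mean
  Xm
}

# centre a training block and fit the core model; returns a closure that
# predicts new (uncentred) rows on the response scale
.opls_fit <- function(Xtr, ytr, n_orth) {
  mu <- colMeans(Xtr)
  core <- .opls_core(sweep(Xtr, 2, mu), ytr - mean(ytr), n_orth)
  list(
    core = core, x_center = mu, y_mean = mean(ytr),
    predict = function(Xnew) {
      mean(ytr) + as.numeric(sweep(Xnew, 2, mu) %*% core$b)
    }
  )
}

# core OPLS fit on centred X and y; returns the pieces needed for prediction
.opls_core <- function(Xm, yc, n_orth) {
  p <- ncol(Xm)
  W_o <- P_o <- matrix(0, p, 0)
  T_o <- matrix(0, nrow(Xm), 0)
  Xf <- Xm
  for (j in seq_len(n_orth)) {
    w <- as.numeric(crossprod(Xf, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- as.numeric(Xf %*% w)
    pv <- as.numeric(crossprod(Xf, t)) / sum(t^2)
    w_o <- pv - sum(w * pv) * w
    nwo <- sqrt(sum(w_o^2))
    if (nwo < 1e-10) break # no orthogonal variation left
    w_o <- w_o / nwo
    t_o <- as.numeric(Xf %*% w_o)
    p_o <- as.numeric(crossprod(Xf, t_o)) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
  }
  w <- as.numeric(crossprod(Xf, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) abort("predictor matrix carries no covariance with the class")
  w <- w / nw
  t <- as.numeric(Xf %*% w)
  pv <- as.numeric(crossprod(Xf, t)) / sum(t^2)
  cq <- sum(t * yc) / sum(t^2)
  # coefficients on the original (scaled) X: compose the orthogonal
  # filtering projections with the predictive direction
  M <- diag(p)
  for (j in seq_len(ncol(W_o))) {
    M <- M %*% (diag(p) - tcrossprod(W_o[, j], P_o[, j]))
  }
  b <- as.numeric(M %*% w) * cq
  list(
    w = w, p = pv, c = cq, t = t, W_o = W_o, P_o = P_o, T_o = T_o, b = b
  )
}

#' Fit an OPLS-DA discriminant model
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' binary class: the class is encoded 0/1 (positive class = 1), variation in
#' `X` orthogonal to the class is removed as `n_orth` orthogonal components,
#' and a single predictive PLS component is fit on the filtered matrix.
#' With `n_orth = 0` the model coincides with one-component PLS1.
#'
#' `X` is expected UV-scaled (see [scale_uv()]); any remaining missing
#' entries are imputed at the column mean (zero on the scaled scale). R2Y is
#' the fraction of class variance explained on the training data; Q2 is the
#' 7-fold cross-validated predictive ability from [cross_validated_q2()].
#'
#' @param X UV-scaled numeric matrix or data frame (subjects x variables).
#' @param y_class Binary class vector (factor/character/logical).
#' @param n_orth Number of orthogonal components (default 1).
#' @param positive Class encoded as 1 (default: last level alphabetically);
#'   coefficients are reported relative to this class.
#' @param folds CV folds for Q2 (default 7).
#' @param compute_q2 Set `FALSE` to skip cross-validation.
#' @param ids Optional subject identifiers for deterministic fold
#'   assignment (defaults to rownames or row order).
#' @return An object of class `oplsda`: predictive weights/loadings/score
#'   (`w`, `p`, `c`, `t_pred`), orthogonal blocks (`W_o`, `P_o`, `T_o`),
#'   `coefficients` (named, mapping scaled X to the 0/1 class), `y_mean`,
#'   `R2Y`, `Q2`, `fitted`, class metadata.
#' @export
fit_oplsda <- function(X, y_class, n_orth = 1, positive = NULL, folds = 7,
                       compute_q2 = TRUE, ids = NULL) {
  if (n_orth < 0) abort("n_orth must be >= 0")
  enc <- .encode_class(y_class, positive)
  Xm <- .prepare_X(X)
  if (nrow(Xm) != length(enc$y01)) abort("X and y_class sizes differ")
  y01 <- enc$y01
  yc <- y01 - mean(y01)
  fit <- .opls_fit(Xm, y01, n_orth)
  core <- fit$core
  fitted <- fit$predict(Xm)
  r2y <- 1 - sum((y01 - fitted)^2) / sum(yc^2)
  out <- structure(
    list(
      w = setNames(core$w, colnames(Xm)),
      p = setNames(core$p, colnames(Xm)),
      c = core$c, t_pred = core$t,
      W_o = core$W_o, P_o = core$P_o, T_o = core$T_o,
      coefficients = setNames(core$b, colnames(Xm)),
      x_center = fit$x_center,
      y_mean = mean(y01), R2Y = r2y, Q2 = NA_real_,
      n_orth = ncol(core$W_o), fitted = fitted,
      levels = enc$levels, positive = enc$positive,
      n = nrow(Xm), variables = colnames(Xm)
    ),
    class = "oplsda"
  )
  if (compute_q2) {
    out$Q2 <- cross_validated_q2(Xm, y01,
      folds = folds, n_orth = n_orth,
      positive = "1", ids = ids
    )
  }
  out
}

#' @export
predict.oplsda <- function(object, newdata, ...) {
  Xm <- .prepare_X(newdata)
  Xm <- Xm[, object$variables, drop = FALSE]
  object$y_mean +
    as.numeric(sweep(Xm, 2, object$x_center) %*% object$coefficients)
}

#' @export
print.oplsda <- function(x, ...) {
  cat(
    "OPLS-DA model: 1 predictive +", x$n_orth, "orthogonal component(s)\n",
    "n =", x$n, ", positive class =", x$positive, "\n",
    sprintf(" R2Y = %.3f, Q2 = %.3f\n", x$R2Y, x$Q2)
  )
  invisible(x)
}

# deterministic round-robin fold assignment over sorted subject ids;
# falls back to class-stratified round-robin if a training split would be
# single-class (possible when all positives share one fold)
.assign_folds <- function(y01, folds, ids = NULL) {
  n <- length(y01)
  ids <- ids %||% seq_len(n)
  fold <- integer(n)
  fold[order(ids)] <- (seq_len(n) - 1L) %% folds + 1L
  degenerate <- any(vapply(
    seq_len(folds),
    function(g) length(unique(y01[fold != g])) < 2, logical(1)
  ))
  if (degenerate) {
    for (cls in unique(y01)) {
      sel <- which(y01 == cls)
      fold[sel[order(ids[sel])]] <- (seq_along(sel) - 1L) %% folds + 1L
    }
  }
  fold
}

#' Cross-validated predictive ability (Q2) of an OPLS-DA model
#'
#' `Q2 = 1 - PRESS / SS`, where `SS = sum((y - mean(y))^2)` and PRESS
#' accumulates squared prediction errors for each subject when predicted by
#' a model refit without their fold. Folds are assigned deterministically,
#' round-robin over sorted subject ids (class-stratified only if a plain
#' assignment would leave a training split with a single class).
#'
#' @inheritParams fit_oplsda
#' @param y Binary class vector, or a continuous numeric response (used as
#'   is, centred).
#' @param folds Number of folds (default 7); must be between 2 and `n`.
#' @return Scalar Q2; negative when the model predicts worse than the mean.
#' @export
cross_validated_q2 <- function(X, y, folds = 7, n_orth = 1, positive = NULL,
                               ids = NULL) {
  Xm <- .prepare_X(X)
  n <- nrow(Xm)
  if (folds > n) abort("folds cannot exceed the number of subjects")
  if (folds < 2) abort("folds must be at least 2")
  if (is.numeric(y) && length(unique(y)) > 2) {
    y01 <- y
  } else {
    y01 <- .encode_class(y, positive)$y01
  }
  fold <- .assign_folds(y01, folds, ids)
  press <- 0
  for (g in seq_len(folds)) {
    test <- fold == g
    if (!any(test)) next
    fit <- .opls_fit(Xm[!test, , drop = FALSE], y01[!test], n_orth)
    pred <- fit$predict(Xm[test, , drop = FALSE])
    press <- press + sum((y01[test] - pred)^2)
  }
  1 - press / sum((y01 - mean(y01))^2)
}

#' Coefficient confidence intervals by jackknifing over CV folds
#'
#' Refits the OPLS-DA model leaving out each cross-validation segment in
#' turn, and converts the spread of the per-segment coefficient vectors
#' into a jackknife standard error:
#' `SE_j = sqrt((G - 1) / G * sum_g (b_gj - mean_g(b_gj))^2)`.
#' The confidence interval is centred on the full-model coefficient,
#' `b_j +/- t(level, G - 1) * SE_j`, and a variable is flagged significant
#' when the interval excludes zero.
#'
#' @inheritParams fit_oplsda
#' @param level Confidence level (default 0.95).
#' @return A tibble of class `coefficient_report`: `variable`,
#'   `coefficient`, `se`, `ci_low`, `ci_high`, `significant`; attributes
#'   `level`, `folds`, `positive`.
#' @export
coefficient_significance <- function(X, y_class, n_orth = 1, folds = 7,
                                     level = 0.95, positive = NULL,
                                     ids = NULL) {
  enc <- .encode_class(y_class, positive)
  Xm <- .prepare_X(X)
  y01 <- enc$y01
  full <- .opls_fit(Xm, y01, n_orth)$core
  fold <- .assign_folds(y01, folds, ids)
  G <- max(fold)
  B <- matrix(NA_real_, ncol(Xm), G, dimnames = list(colnames(Xm), NULL))
  for (g in seq_len(G)) {
    keep <- fold != g
    fit_g <- tryCatch(
      .opls_fit(Xm[keep, , drop = FALSE], y01[keep], n_orth),
      error = function(e) {
        abort(paste0("model refit failed for fold ", g, ": ", conditionMessage(e)))
      }
    )
    B[, g] <- fit_g$core$b
  }
  bbar <- rowMeans(B)
  se <- sqrt((G - 1) / G * rowSums((B - bbar)^2))
  tq <- stats::qt(1 - (1 - level) / 2, df = G - 1)
  out <- tibble(
    variable = colnames(Xm),
    coefficient = full$b,
    se = se,
    ci_low = full$b - tq * se,
    ci_high = full$b + tq * se
  )
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  structure(out,
    class = c("coefficient_report", class(out)),
    level = level, folds = G, positive = enc$positive
  )
}

#' Permutation validation of an OPLS-DA model
#'
#' Refits the model on permuted class labels: for each permutation the
#' absolute correlation between the permuted and original class vectors,
#' the training R2Y and the cross-validated Q2 are recorded. Straight lines
#' are fit through the (correlation, R2Y) and (correlation, Q2) points,
#' including the original model at correlation 1; their intercepts at
#' correlation 0 summarise how much apparent fit survives label
#' scrambling. The model is judged `"weak"` if the Q2 intercept exceeds
#' 0.05 or if at least 5% of permuted models reach the original Q2,
#' otherwise `"strong"`.
#'
#' @inheritParams fit_oplsda
#' @param n_perms Number of label permutations (default 200).
#' @param seed Optional seed making the permutation set reproducible.
#' @return An object of class `permutation_result`: `points` (tibble with
#'   `permutation`, `correlation`, `R2Y`, `Q2`; permutation 0 is the
#'   original model), `r2y_intercept`, `q2_intercept`, `prop_q2_ge`,
#'   `verdict`.
#' @export
permutation_validation <- function(X, y_class, n_perms = 200, seed = NULL,
                                   n_orth = 1, folds = 7, positive = NULL,
                                   ids = NULL) {
  if (n_perms < 1) abort("n_perms must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  enc <- .encode_class(y_class, positive)
  Xm <- .prepare_X(X)
  y01 <- enc$y01
  fit1 <- function(yv) {
    yc <- yv - mean(yv)
    fit <- .opls_fit(Xm, yv, n_orth)
    fitted <- fit$predict(Xm)
    r2y <- 1 - sum((yv - fitted)^2) / sum(yc^2)
    q2 <- cross_validated_q2(Xm, yv,
      folds = folds, n_orth = n_orth,
      positive = "1", ids = ids
    )
    c(r2y = r2y, q2 = q2)
  }
  orig <- fit1(y01)
  rows <- vector("list", n_perms)
  for (k in seq_len(n_perms)) {
    yp <- sample(y01)
    m <- fit1(yp)
    rows[[k]] <- tibble(
      permutation = k,
      correlation = abs(stats::cor(yp, y01)),
      R2Y = m[["r2y"]], Q2 = m[["q2"]]
    )
  }
  points <- dplyr::bind_rows(
    tibble(
      permutation = 0L, correlation = 1,
      R2Y = orig[["r2y"]], Q2 = orig[["q2"]]
    ),
    dplyr::bind_rows(rows)
  )
  r2y_int <- unname(coef(lm(R2Y ~ correlation, data = points))[1])
  q2_int <- unname(coef(lm(Q2 ~ correlation, data = points))[1])
  perm_q2 <- points$Q2[points$permutation > 0]
  prop_ge <- mean(perm_q2 >= orig[["q2"]])
  verdict <- if (q2_int > 0.05 || prop_ge >= 0.05) "weak" else "strong"
  structure(
    list(
      points = points, r2y_intercept = r2y_int, q2_intercept = q2_int,
      prop_q2_ge = prop_ge, verdict = verdict, n_perms = n_perms
    ),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(
    "Permutation validation (", x$n_perms, " permutations)\n",
    sprintf(
    "  R2Y intercept = %.3f, Q2 intercept = %.3f\n",
    x$r2y_intercept, x$q2_intercept
    ),
    sprintf(
      "  %.1f%% of permuted Q2 >= original; verdict: %s\n",
      100 * x$prop_q2_ge, x$verdict
    ),
    sep = ""
  )
  invisible(x)
}
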