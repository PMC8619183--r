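test_that("UV scaling standardizes columns and drops constants", {
  tab <- tibble::tibble(a = c(1, 2, 3), b = c(10, 10, 10), id = c("x", "y", "z"))
  expect_warning(out <- scale_uv(tab), "zero-variance")
  expect_equal(out$a, c(-1, 0, 1))
  expect_false("b" %in% names(out))
  expect_equal(out$id, tab$id)
  expect_error(scale_uv(tab[1, ]), "2 rows")
})

test_that("scaled columns are numerically centred with unit variance,
          also under missingness", {
  withr::with_seed(1, {
    tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(60), 10, 6)))
    tab$V2[c(2, 5)] <- NA
  })
  out <- scale_uv(tab)
  means <- vapply(out, function(x) mean(x, na.rm = TRUE), numeric(1))
  sds <- vapply(out, function(x) sd(x, na.rm = TRUE), numeric(1))
  expect_true(all(abs(means) < 1e-12))
  expect_true(all(abs(sds - 1) < 1e-12))
})

test_that("NIPALS reproduces eigendecomposition PCA on complete matrices", {
  withr::with_seed(2, {
    X <- scale(matrix(rnorm(24), 6, 4), scale = FALSE)
  })
  fit <- fit_pca_nipals(X, 3, compute_q2 = FALSE)
  ora <- eigen_pca_oracle(X, 3)
  for (k in 1:3) {
    expect_gt(abs(cor(fit$scores[, k], ora$scores[, k])), 0.999)
    expect_equal(fit$R2[k], ora$r2[k], tolerance = 1e-6)
  }
  # loadings are unit norm, scores mutually orthogonal
  expect_equal(colSums(fit$loadings^2), rep(1, 3), tolerance = 1e-8)
  expect_lt(abs(sum(fit$scores[, 1] * fit$scores[, 2])), 1e-6)
})

test_that("a rank-1 matrix is fully explained by one component", {
  withr::with_seed(3, {
    X <- outer(rnorm(8), rnorm(5))
  })
  fit <- fit_pca_nipals(X, 1, compute_q2 = FALSE)
  expect_equal(fit$R2[1], 1, tolerance = 1e-9)
})

test_that("NIPALS tolerates missing entries and stays close to the
          complete-data solution", {
  withr::with_seed(4, {
    X <- scale(matrix(rnorm(200), 20, 10) +
      outer(rnorm(20, sd = 2), rnorm(10)), scale = FALSE)
    Xm <- X
    Xm[sample(length(X), 15)] <- NA
  })
  fit <- fit_pca_nipals(Xm, 1, compute_q2 = FALSE)
  ora <- eigen_pca_oracle(X, 1)
  expect_gt(abs(cor(fit$scores[, 1], ora$scores[, 1])), 0.98)
})

test_that("component count beyond the rank bound is rejected", {
  expect_error(
    fit_pca_nipals(matrix(rnorm(12), 3, 4), 4, compute_q2 = FALSE),
    "rank bound"
  )
})

test_that("PCA Q2 is high for strong structure and low for noise", {
  withr::with_seed(5, {
    strong <- scale(outer(rnorm(20), rnorm(6)) + matrix(rnorm(120, sd = 0.05), 20, 6),
      scale = FALSE
    )
    noise <- scale(matrix(rnorm(120), 20, 6), scale = FALSE)
  })
  expect_gt(pca_q2(strong, 1), 0.9)
  expect_lt(pca_q2(noise, 1), 0.5)
})

test_that("base models append one oriented score per construct and drop the
          constituent columns", {
  withr::with_seed(6, {
    n <- 20
    u1 <- rnorm(n)
    u2 <- rnorm(n)
    tab <- tibble::tibble(
      a1 = u1 + rnorm(n, sd = 0.3), a2 = u1 + rnorm(n, sd = 0.3),
      a3 = u1 + rnorm(n, sd = 0.3),
      b1 = u2 + rnorm(n, sd = 0.3), b2 = u2 + rnorm(n, sd = 0.3),
      keep = rnorm(n)
    )
  })
  sc <- scale_uv(tab)
  out <- fit_base_models(sc, list(A = c("a1", "a2", "a3"), B = c("b1", "b2")))
  expect_true(all(c("score_A", "score_B", "keep") %in% names(out)))
  expect_false(any(c("a1", "b2") %in% names(out)))
  models <- attr(out, "base_models")
  expect_equal(names(models), c("A", "B"))
  # the appended score equals a direct one-component fit on the sub-table
  direct <- fit_pca_nipals(sc[c("a1", "a2", "a3")], 1, compute_q2 = FALSE)
  expect_equal(out$score_A, direct$scores[, 1], tolerance = 1e-6)
  # empty construct map leaves the table unchanged
  expect_equal(
    names(fit_base_models(sc, list())), names(sc)
  )
  expect_error(
    fit_base_models(sc, list(A = c("a1", "missing_col"))),
    "fewer than 2"
  )
})
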