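sim_class_data <- function(n = 40, p = 8, effect = 0, seed = 1,
                           n_pos = n / 2) {
  withr::with_seed(seed, {
    y <- c(rep("Faller", n_pos), rep("Non-faller", n - n_pos))
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    X[y == "Faller", 1] <- X[y == "Faller", 1] + effect
    list(X = scale(X), y = y)
  })
}

test_that("with no orthogonal components OPLS-DA coincides with PLS1", {
  d <- sim_class_data(effect = 1.5, seed = 10)
  fit <- fit_oplsda(d$X, d$y, n_orth = 0, positive = "Faller", compute_q2 = FALSE)
  ora <- pls1_oracle(d$X, as.numeric(d$y == "Faller"))
  expect_equal(unname(fit$coefficients), ora$b, tolerance = 1e-8)
  expect_equal(fit$fitted, ora$fitted, tolerance = 1e-8)
})

test_that("widely separated classes are perfectly ordered by the
          predictive score", {
  d <- sim_class_data(effect = 5, seed = 11)
  fit <- fit_oplsda(d$X, d$y, n_orth = 1, positive = "Faller", compute_q2 = FALSE)
  pos <- fit$t_pred[d$y == "Faller"]
  neg <- fit$t_pred[d$y == "Non-faller"]
  expect_gt(min(pos), max(neg))
  expect_gt(fit$R2Y, 0.8)
})

test_that("the predictive score is orthogonal to every orthogonal score", {
  d <- sim_class_data(effect = 1, seed = 12)
  for (k in 1:2) {
    fit <- fit_oplsda(d$X, d$y, n_orth = k, positive = "Faller", compute_q2 = FALSE)
    if (ncol(fit$T_o) > 0) {
      dots <- abs(crossprod(fit$t_pred, fit$T_o)) /
        (sqrt(sum(fit$t_pred^2)) * sqrt(colSums(fit$T_o^2)))
      expect_true(all(dots < 1e-8))
    }
  }
})

test_that("degenerate inputs are rejected", {
  d <- sim_class_data(seed = 13)
  expect_error(fit_oplsda(d$X, rep("A", 40)), "single level")
  expect_error(fit_oplsda(d$X, d$y, n_orth = -1), "n_orth")
  expect_error(cross_validated_q2(d$X, d$y, folds = 41), "exceed")
  expect_error(cross_validated_q2(d$X, d$y, folds = 1), "at least 2")
})

test_that("Q2 recovers a noiseless linear response and stays near zero or
          below for pure noise", {
  withr::with_seed(14, {
    X <- matrix(rnorm(35), 35, 1)
  })
  y <- 2 * X[, 1] # exactly linear, no noise
  expect_gt(cross_validated_q2(X, y, n_orth = 0), 0.99)

  q2s <- vapply(1:50, function(s) {
    withr::with_seed(1000 + s, {
      Xn <- scale(matrix(rnorm(35 * 8), 35, 8))
      yn <- sample(c(rep("Faller", 5), rep("Non-faller", 30)))
    })
    cross_validated_q2(Xn, yn, positive = "Faller")
  }, numeric(1))
  expect_lte(mean(q2s), 0.05)
})

test_that("Q2 does not exceed R2Y on the same model", {
  for (s in 1:5) {
    d <- sim_class_data(effect = 2, seed = 20 + s)
    fit <- fit_oplsda(d$X, d$y, positive = "Faller")
    expect_lte(fit$Q2, fit$R2Y + 1e-9)
  }
})

test_that("fold assignment is deterministic and stratifies only when a
          split would lose a class", {
  y <- c(rep(1, 5), rep(0, 30))
  f1 <- posturadapt:::.assign_folds(y, 7, ids = sprintf("S%02d", 1:35))
  f2 <- posturadapt:::.assign_folds(y, 7, ids = sprintf("S%02d", 1:35))
  expect_identical(f1, f2)
  expect_true(all(table(f1) == 5))
  # all positives in what would be one fold: training sets keep both classes
  for (g in 1:7) {
    expect_gt(length(unique(y[f1 != g])), 1)
  }
})

test_that("jackknife CIs bracket the coefficient and drive the
          significance flag", {
  d <- sim_class_data(effect = 3, seed = 30)
  rep <- coefficient_significance(d$X, d$y, positive = "Faller")
  expect_true(all(rep$ci_low <= rep$coefficient + 1e-12))
  expect_true(all(rep$ci_high >= rep$coefficient - 1e-12))
  expect_equal(rep$significant, rep$ci_low > 0 | rep$ci_high < 0)
  expect_true(rep$significant[rep$variable == "v1"])
  expect_gt(rep$coefficient[rep$variable == "v1"], 0)
})

test_that("permutation validation is seed-reproducible, includes the
          original model, and judges noise as weak", {
  d <- sim_class_data(effect = 0, seed = 31, n = 35, n_pos = 5)
  p1 <- permutation_validation(d$X, d$y, n_perms = 30, seed = 77, positive = "Faller")
  p2 <- permutation_validation(d$X, d$y, n_perms = 30, seed = 77, positive = "Faller")
  expect_identical(p1$points, p2$points)
  expect_equal(p1$points$correlation[p1$points$permutation == 0], 1)
  expect_equal(p1$verdict, "weak")
  expect_error(permutation_validation(d$X, d$y, n_perms = 0), "n_perms")
})

test_that("permutation validation endorses a strongly separated model", {
  d <- sim_class_data(effect = 5, seed = 32)
  p <- permutation_validation(d$X, d$y, n_perms = 100, seed = 5, positive = "Faller")
  expect_equal(p$verdict, "strong")
  expect_lt(p$prop_q2_ge, 0.05)
})

test_that("tidy and glance expose model summaries", {
  d <- sim_class_data(effect = 2, seed = 33)
  fit <- fit_oplsda(d$X, d$y, positive = "Faller")
  td <- tidy(fit)
  expect_named(td, c("variable", "weight", "loading", "coefficient"))
  gl <- glance(fit)
  expect_equal(gl$n, 40)
  expect_equal(gl$positive, "Faller")
  pr <- permutation_validation(d$X, d$y, n_perms = 10, seed = 1, positive = "Faller")
  expect_named(
    glance(pr),
    c("n_perms", "r2y_intercept", "q2_intercept", "prop_q2_ge", "verdict")
  )
})
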