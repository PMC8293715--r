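test_that("standardize yields mean 0, sample SD 1, and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(51)
  x <- rnorm(40, 5, 3)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "constant")
})

test_that("single-predictor OLS slope equals the Pearson correlation", {
  set.seed(52)
  x <- rnorm(10); y <- 0.3 * x + rnorm(10)
  res <- ols_single(y, x)
  expect_equal(res$coef, cor(y, x), tolerance = 1e-10)
  expect_identical(res$model_kind, "OLS")

  res_id <- ols_single(x, x)
  expect_equal(res_id$coef, 1, tolerance = 1e-10)
  expect_equal(res_id$adj_r2, 1, tolerance = 1e-7)

  y_orth <- rnorm(20)
  x_orth <- rnorm(20)
  y_orth <- residuals(lm(y_orth ~ x_orth))  # constructed orthogonal
  expect_lt(abs(ols_single(y_orth, x_orth)$coef), 1e-10)
  expect_error(ols_single(rnorm(5), rnorm(6)), "length")
})

test_that("Rapoport support requires a positive, significant slope", {
  elev <- seq(1800, 5400, length.out = 30)
  lin <- data.frame(group = "overall", elevation_m = elev,
                    mean_range_m = 100 + 0.2 * elev)
  res <- suppressWarnings(rapoport_regression(lin))
  expect_true(res$supported)
  expect_gt(res$slope_m_per_m, 0)
  expect_equal(res$adj_r2, 1, tolerance = 1e-7)

  flat <- transform(lin, mean_range_m = 500)
  expect_false(suppressWarnings(rapoport_regression(flat))$supported)

  few <- lin[1:2, ]
  expect_error(rapoport_regression(few), ">= 3")

  # antisymmetry: mirroring the gradient flips the sign and the call
  set.seed(53)
  noisy <- transform(lin, mean_range_m = mean_range_m + rnorm(30, 0, 40))
  up <- rapoport_regression(noisy)
  flipped <- transform(noisy, elevation_m = -elevation_m)
  down <- rapoport_regression(flipped)
  expect_equal(down$slope_m_per_m, -up$slope_m_per_m)
  expect_true(up$supported); expect_false(down$supported)
  # the p-gate is removable
  expect_true(rapoport_regression(noisy, require_significance = FALSE)$supported)
})

test_that("kNN weights use the union rule and row-standardize", {
  w <- build_weights(c(0, 10, 20), k = 1)
  # middle plot gains two neighbours after union symmetrization
  expect_equal(sum(w$adjacency[2, ]), 2)
  expect_equal(unname(rowSums(w$W)), rep(1, 3))
  expect_equal(unname(diag(w$W)), rep(0, 3))
  expect_true(isSymmetric(w$adjacency))

  n <- 7
  w_full <- build_weights(seq_len(n), k = n - 1)
  off <- w_full$W[upper.tri(w_full$W) | lower.tri(w_full$W)]
  expect_equal(off, rep(1 / (n - 1), n * (n - 1)))
  expect_error(build_weights(1:4, k = 4), "k \\+ 1")
})

test_that("SAR error model collapses to OLS without spatial structure", {
  set.seed(54)
  n <- 60
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  fit0 <- sar_error_fit(y, x, matrix(0, n, n), predictor = "x")
  ols <- ols_single(y, x, predictor = "x")
  slope <- fit0$coefficients[fit0$coefficients$term == "x", ]
  expect_equal(fit0$lambda, 0)
  expect_equal(slope$coef, ols$coef, tolerance = 1e-9)
  expect_true(is.finite(fit0$AIC))
})

test_that("SAR recovers lambda near zero on independent-error data", {
  set.seed(55)
  n <- 200
  W <- build_weights(runif(n, 0, 100), k = 5)
  x <- rnorm(n); y <- 0.7 * x + rnorm(n)
  fit <- sar_error_fit(y, x, W, predictor = "x")
  ols <- ols_single(y, x, predictor = "x")
  slope <- fit$coefficients[fit$coefficients$term == "x", ]
  expect_lt(abs(fit$lambda), 0.15)
  expect_lt(abs(slope$coef - ols$coef), 2 * ols$se)
})

test_that("SAR recovers a planted spatial signal", {
  set.seed(56)
  n <- 300
  W <- build_weights(runif(n, 0, 100), k = 5)
  d <- simulate_sar_data(n, lambda = 0.6, W)
  fit <- sar_error_fit(d$y, d$x, W, predictor = "x")
  expect_lt(abs(fit$lambda - 0.6), 0.15)
  expect_gt(fit$logLik,
            sar_error_fit(d$y, d$x, matrix(0, n, n))$logLik)
})

test_that("random-forest importance is deterministic and sanely ranked", {
  set.seed(57)
  n <- 120
  X <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  y <- 2 * X$signal + rnorm(n, 0, 0.3)
  a <- rf_importance(y, X, n_runs = 3, seed = 11, ntree = 100)
  b <- rf_importance(y, X, n_runs = 3, seed = 11, ntree = 100)
  expect_identical(a$importance, b$importance)
  expect_identical(a$importance$predictor[1], "signal")
  expect_equal(dim(a$runs), c(3L, 3L))
  expect_error(rf_importance(rep(1, n), X, 2, seed = 1), "constant")
  expect_error(rf_importance(y[1:10], X[1:10, ], 2, seed = 1), "n >= 20")
})

test_that("%IncMSE ranking is invariant to affine rescaling of the response", {
  set.seed(58)
  n <- 80
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- X$a + 0.5 * X$b + rnorm(n, 0, 0.5)
  r1 <- rf_importance(y, X, n_runs = 2, seed = 19, ntree = 100)
  r2 <- rf_importance(10 * y + 100, X, n_runs = 2, seed = 19, ntree = 100)
  expect_identical(r1$importance$predictor, r2$importance$predictor)
  expect_equal(r1$importance$mean_inc_mse, r2$importance$mean_inc_mse,
               tolerance = 1e-6)
})

test_that("authored %IncMSE agrees in rank with the reference forest", {
  set.seed(59)
  n <- 150
  X <- data.frame(strong = rnorm(n), weak = rnorm(n), none = rnorm(n))
  y <- 2 * X$strong + 0.7 * X$weak + rnorm(n, 0, 0.5)
  ours <- rf_importance(y, X, n_runs = 5, seed = 23, ntree = 300)
  set.seed(23)
  ref <- randomForest::randomForest(X, y, ntree = 500, importance = TRUE)
  ref_rank <- rownames(ref$importance)[order(-ref$importance[, "%IncMSE"])]
  expect_identical(ours$importance$predictor, ref_rank)
})
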