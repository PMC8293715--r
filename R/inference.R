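#' Standardize to mean 0, sample SD 1
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return z-scores ((x - mean) / sd, n - 1 denominator).
#' @export
standardize <- function(x) {
  if (!has_spread(x)) abort_("cannot standardize a constant input (SD = 0)")
  as.numeric((x - mean(x)) / stats::sd(x))
}

#' Single-predictor OLS on standardized variables
#'
#' Both variables are z-scored internally (so the slope equals the Pearson
#' correlation), then an ordinary least-squares fit returns the coefficient,
#' its standard error, the two-sided p-value and the adjusted R-squared.
#'
#' @param y,x Numeric vectors of equal length.
#' @param predictor Label carried into the result.
#' @return One-row data frame `predictor`, `coef`, `se`, `p_value`, `adj_r2`,
#'   `model_kind = "OLS"`, `n`.
#' @export
ols_single <- function(y, x, predictor = deparse1(substitute(x))) {
  force(predictor)
  if (length(y) != length(x))
    abort_("y and x differ in length (", length(y), " vs ", length(x), ")")
  keep <- is.finite(y) & is.finite(x)
  y <- standardize(y[keep]); x <- standardize(x[keep])
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  data.frame(predictor = predictor,
             coef = unname(s$coefficients["x", "Estimate"]),
             se = unname(s$coefficients["x", "Std. Error"]),
             p_value = unname(s$coefficients["x", "Pr(>|t|)"]),
             adj_r2 = s$adj.r.squared,
             model_kind = "OLS", n = length(y), row.names = NULL)
}

#' Test an elevational range-size gradient against Rapoport's prediction
#'
#' OLS of the per-plot mean range size on plot elevation over the
#' non-missing plots. The rule is scored as supported when the slope is
#' positive; by default a significance gate (two-sided p below `alpha`) is
#' applied as well, and can be lifted.
#'
#' @param profile [stevens_profile()] output (`elevation_m`,
#'   `mean_range_m`); plots with missing means are dropped.
#' @param alpha Significance threshold for the support gate (default 0.05).
#' @param require_significance Apply the p-value gate (default `TRUE`).
#' @return One-row data frame `group`, `slope_m_per_m`, `se`, `p_value`,
#'   `adj_r2`, `n_plots`, `supported`.
#' @export
rapoport_regression <- function(profile, alpha = 0.05,
                                require_significance = TRUE) {
  d <- profile[is.finite(profile$mean_range_m), , drop = FALSE]
  if (nrow(d) < 3)
    abort_("need >= 3 plots with a defined mean range size (got ",
           nrow(d), ")")
  fit <- stats::lm(mean_range_m ~ elevation_m, data = d)
  s <- summary(fit)
  slope <- unname(s$coefficients["elevation_m", "Estimate"])
  p <- unname(s$coefficients["elevation_m", "Pr(>|t|)"])
  data.frame(group = if (!is.null(profile$group)) profile$group[1] else NA,
             slope_m_per_m = slope,
             se = unname(s$coefficients["elevation_m", "Std. Error"]),
             p_value = p,
             adj_r2 = s$adj.r.squared,
             n_plots = nrow(d),
             supported = slope > 0 && (!require_significance || p < alpha),
             row.names = NULL)
}

#' Symmetric k-nearest-neighbour spatial weights
#'
#' Builds the kNN graph on the supplied coordinates (a vector of elevations
#' for along-gradient distance, or a two-column matrix), symmetrizes it with
#' the union rule (i ~ j if either is among the other's k nearest) and
#' row-standardizes. Distance ties are broken deterministically by plot
#' order.
#'
#' @param coords Numeric vector (elevations) or two-column matrix/data frame
#'   of coordinates.
#' @param k Number of nearest neighbours (default 5); needs `n >= k + 1`.
#' @return Object of class `spatial_weights`: list with the row-standardized
#'   matrix `W`, the binary `adjacency`, `k`, `rule` and `row_standardized`.
#' @export
build_weights <- function(coords, k = 5) {
  X <- if (is.null(dim(coords))) cbind(as.numeric(coords), 0)
       else as.matrix(coords)
  n <- nrow(X)
  if (n < k + 1) abort_("need at least k + 1 = ", k + 1, " plots")
  D <- as.matrix(stats::dist(X))
  A <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i], seq_len(n)[-i])  # tie-break by plot order
    nb <- (seq_len(n)[-i])[ord[seq_len(k)]]
    A[i, nb] <- 1L
  }
  A <- (A | t(A)) * 1L  # union symmetrization
  diag(A) <- 0L
  W <- A / rowSums(A)
  structure(list(W = W, adjacency = A, k = k,
                 rule = "symmetric kNN (union), row-standardized",
                 row_standardized = TRUE),
            class = "spatial_weights")
}

# accept a spatial_weights object or a bare matrix
weights_matrix <- function(W) {
  if (inherits(W, "spatial_weights")) W$W else as.matrix(W)
}

#' Maximum-likelihood simultaneous autoregressive error model
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ N(0, sigma^2 I)` by
#' profile maximum likelihood: for a candidate `lambda` the spatially
#' filtered regression of `(I - lambda W) y` on `(I - lambda W) X` yields
#' `beta` and `sigma^2`, and the log-likelihood adds the Jacobian
#' `log|I - lambda W|` evaluated through the eigenvalues of `W`. `lambda` is
#' searched by bounded scalar optimization on the feasible interval
#' `(1/min(eig), 1)`. With a zero weights matrix the model collapses to OLS
#' exactly (`lambda` reported as 0). Variables are z-scored internally by
#' default so coefficients are comparable across predictors.
#'
#' @param y Response vector.
#' @param X Predictor vector or matrix (an intercept is added internally).
#' @param W [build_weights()] object or a row-standardized matrix.
#' @param standardize_vars Standardize `y` and each column of `X` first.
#' @param predictor Optional label(s) for the slope terms.
#' @return List of class `sar_fit`: `coefficients` (data frame `term`,
#'   `coef`, `se`, `z`, `p_value`), `lambda`, `sigma2`, `logLik`, `AIC`
#'   (`2k - 2 logL`, `k = #beta + 2` for `lambda` and `sigma^2`),
#'   `pseudo_r2` (squared correlation of trend and response), `n`.
#' @export
sar_error_fit <- function(y, X, W, standardize_vars = TRUE,
                          predictor = NULL) {
  Wm <- weights_matrix(W)
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || nrow(Wm) != n || ncol(Wm) != n)
    abort_("dimension mismatch between y, X and W")
  if (standardize_vars) {
    y <- standardize(y)
    X <- apply(X, 2, standardize)
  }
  labs <- predictor %||% (colnames(X) %||% paste0("x", seq_len(ncol(X))))
  Xd <- cbind(`(Intercept)` = 1, X)
  colnames(Xd) <- c("(Intercept)", labs)

  ev <- eigen(Wm, only.values = TRUE)$values
  if (max(abs(Im(ev))) > 1e-8 * max(1, max(abs(ev))))
    warning("weights matrix has notably complex eigenvalues; using real parts",
            call. = FALSE)
  ev <- Re(ev)

  zero_W <- all(Wm == 0)
  loglik_at <- function(lambda) {
    A <- diag(n) - lambda * Wm
    ys <- A %*% y
    Xs <- A %*% Xd
    fit <- stats::lm.fit(Xs, ys)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / n
    ld <- sum(log(pmax(1 - lambda * ev, .Machine$double.eps)))
    list(logLik = -n / 2 * (log(2 * pi * sigma2) + 1) + ld,
         beta = fit$coefficients, sigma2 = sigma2, Xs = Xs)
  }

  if (zero_W) {
    lambda_hat <- 0
  } else {
    lo <- if (min(ev) < 0) 1 / min(ev) + 1e-6 else -0.999
    opt <- stats::optimize(function(l) loglik_at(l)$logLik,
                           interval = c(lo, 0.9999), maximum = TRUE,
                           tol = 1e-8)
    lambda_hat <- opt$maximum
  }
  fin <- loglik_at(lambda_hat)
  if (!is.finite(fin$logLik))
    abort_("SAR likelihood did not converge (lambda = ",
           signif(lambda_hat, 4), ")")
  XtX <- crossprod(fin$Xs)
  vc <- fin$sigma2 * solve(XtX)
  se <- sqrt(diag(vc))
  z <- fin$beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  p_beta <- length(fin$beta)
  aic <- 2 * (p_beta + 2) - 2 * fin$logLik
  trend <- as.numeric(Xd %*% fin$beta)
  structure(list(
    coefficients = data.frame(term = colnames(Xd), coef = unname(fin$beta),
                              se = unname(se), z = unname(z),
                              p_value = unname(pv), row.names = NULL),
    lambda = lambda_hat, sigma2 = fin$sigma2, logLik = fin$logLik,
    AIC = aic, pseudo_r2 = suppressWarnings(stats::cor(trend, y))^2,
    n = n), class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat("SAR error model (ML): lambda =", signif(x$lambda, 4),
      " AIC =", round(x$AIC, 2), " n =", x$n, "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

# OOB predictions of a randomForest for a (possibly permuted) design matrix
oob_predictions <- function(rf, X) {
  pred <- stats::predict(rf, X, predict.all = TRUE)$individual
  oob <- rf$inbag == 0
  n_oob <- rowSums(oob)
  rowSums(pred * oob) / n_oob
}

#' Repeated random-forest permutation importance (%IncMSE)
#'
#' Fits `n_runs` random-forest regressions (each with its own derived seed).
#' Per run, the baseline out-of-bag MSE is compared with the out-of-bag MSE
#' after permuting one predictor column at a time:
#' `%IncMSE_j = 100 (MSE_perm_j - MSE_oob) / MSE_oob`. Reported importances
#' are the means across runs (per-run values are kept for dispersion
#' checks), alongside the mean percentage of variance explained,
#' `100 (1 - MSE_oob / var(y))`.
#'
#' @param y Response vector (non-constant, `n >= 20`).
#' @param X Predictor matrix or data frame with at least two columns.
#' @param n_runs Number of repeated forests (the field default is 1,000;
#'   tests use far fewer).
#' @param seed Integer seed controlling all runs.
#' @param ntree Trees per forest.
#' @return Object of class `rf_importance`: `importance` (data frame
#'   `predictor`, `mean_inc_mse`, `sd_inc_mse`), `pct_var_explained`,
#'   `runs` (n_runs x predictors matrix), `n_runs`, `seed`.
#' @export
rf_importance <- function(y, X, n_runs = 1000, seed, ntree = 200) {
  if (missing(seed)) abort_("seed is required for rf_importance")
  X <- as.data.frame(X)
  if (length(y) < 20) abort_("need n >= 20 observations")
  if (ncol(X) < 2) abort_("need >= 2 predictors")
  if (!has_spread(y)) abort_("constant response")
  if (!is_num1(n_runs) || n_runs < 1) abort_("n_runs must be >= 1")

  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  p <- ncol(X)
  runs <- matrix(NA_real_, n_runs, p, dimnames = list(NULL, colnames(X)))
  pve <- numeric(n_runs)
  var_y <- mean((y - mean(y))^2)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    rf <- randomForest::randomForest(x = X, y = y, ntree = ntree,
                                     keep.inbag = TRUE, importance = FALSE)
    base_mse <- mean((y - rf$predicted)^2)
    pve[r] <- 100 * (1 - base_mse / var_y)
    for (j in seq_len(p)) {
      Xp <- X
      Xp[[j]] <- X[[j]][sample.int(nrow(X))]
      perm_mse <- mean((y - oob_predictions(rf, Xp))^2)
      runs[r, j] <- 100 * (perm_mse - base_mse) / base_mse
    }
  }
  imp <- data.frame(predictor = colnames(X),
                    mean_inc_mse = colMeans(runs),
                    sd_inc_mse = apply(runs, 2, stats::sd),
                    row.names = NULL)
  imp <- imp[order(-imp$mean_inc_mse), , drop = FALSE]
  structure(list(importance = imp, pct_var_explained = mean(pve),
                 runs = runs, n_runs = n_runs, seed = as.integer(seed)),
            class = "rf_importance")
}

#' @export
print.rf_importance <- function(x, ...) {
  cat("random-forest permutation importance over", x$n_runs, "runs;",
      "variance explained:", round(x$pct_var_explained, 2), "%\n")
  print(x$importance, digits = 3, row.names = FALSE)
  invisible(x)
}
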