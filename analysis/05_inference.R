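#!/usr/bin/env Rscript
# Stage 5: the statistical layer.
#
# Rapoport regressions (per-plot mean range size on elevation, per group),
# standardized single-predictor OLS and SAR error models for each of the
# eight environmental variables, and repeated random-forest permutation
# importance (%IncMSE, 200 repeated forests per group).

suppressPackageStartupMessages(library(elevrange))

profiles_df <- read.csv("results/range_profile.csv")
env <- read.csv("results/env_table.csv")
groups <- unique(profiles_df$group)
profiles <- split(profiles_df, profiles_df$group)[groups]

rapoport <- do.call(rbind, lapply(profiles, rapoport_regression))
write.csv(rapoport, "results/rapoport.csv", row.names = FALSE)
cat("Rapoport support by group:\n")
print(rapoport[, c("group", "slope_m_per_m", "p_value", "adj_r2",
                   "supported")], row.names = FALSE, digits = 3)

vars <- c("mat", "map", "matr", "ts", "tc", "pc", "mde", "pop")
t1 <- t2 <- list()
for (g in groups) {
  prof <- profiles[[g]]
  keep <- is.finite(prof$mean_range_m)
  y <- prof$mean_range_m[keep]
  W <- build_weights(prof$elevation_m[keep], k = 5)
  for (v in vars) {
    o <- ols_single(y, env[[v]][keep], predictor = toupper(v))
    t1[[paste(g, v)]] <- data.frame(group = g, o)
    s <- sar_error_fit(y, env[[v]][keep], W, predictor = toupper(v))
    sl <- s$coefficients[s$coefficients$term == toupper(v), ]
    t2[[paste(g, v)]] <- data.frame(group = g, predictor = toupper(v),
                                    coef = sl$coef, se = sl$se,
                                    p_value = sl$p_value,
                                    lambda = s$lambda, AIC = s$AIC)
  }
}
table1 <- do.call(rbind, t1); table2 <- do.call(rbind, t2)
write.csv(table1, "results/table1.csv", row.names = FALSE)
write.csv(table2, "results/table2.csv", row.names = FALSE)

set.seed(20260105L)
rf_seeds <- sample.int(.Machine$integer.max - 1L, length(groups))
Xenv <- env[vars]; names(Xenv) <- toupper(vars)
imp <- list()
for (i in seq_along(groups)) {
  g <- groups[i]
  keep <- is.finite(profiles[[g]]$mean_range_m)
  r <- rf_importance(standardize(profiles[[g]]$mean_range_m[keep]),
                     as.data.frame(lapply(Xenv[keep, ], standardize)),
                     n_runs = 200, seed = rf_seeds[i])
  imp[[g]] <- data.frame(group = g, r$importance,
                         pct_var_explained = r$pct_var_explained)
}
importance <- do.call(rbind, imp)
write.csv(importance, "results/importance.csv", row.names = FALSE)

cat("\nOLS coefficients (overall group):\n")
print(table1[table1$group == "overall",
             c("predictor", "coef", "se", "adj_r2")],
      row.names = FALSE, digits = 3)
cat("\ntop random-forest predictors per group:\n")
for (g in groups)
  cat(sprintf("%-11s %s (%.0f%% IncMSE), %.1f%% variance explained\n", g,
              imp[[g]]$predictor[1], imp[[g]]$mean_inc_mse[1],
              imp[[g]]$pct_var_explained[1]))
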