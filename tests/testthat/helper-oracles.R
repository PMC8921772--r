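# Independent brute-force oracles used to verify the model-fitting code.

# OLS via the normal equations, with classical SEs; independent of lm().
ols_oracle <- function(X, y) {
  X1 <- cbind(`(Intercept)` = 1, X)
  XtX <- crossprod(X1)
  b <- solve(XtX, crossprod(X1, y))
  res <- y - X1 %*% b
  df <- nrow(X1) - ncol(X1)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * s2)
  tstat <- drop(b) / se
  list(coef = drop(b)[-1L], se = se[-1L], t = tstat[-1L],
       p = 2 * pt(-abs(tstat[-1L]), df), df = df)
}

# VIF by definition: 1 / (1 - R^2_j) with R^2_j computed from raw sums of
# squares of the normal-equations residuals.
vif_oracle <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    Z <- cbind(1, X[, -j, drop = FALSE])
    b <- solve(crossprod(Z), crossprod(Z, X[, j]))
    res <- X[, j] - Z %*% b
    r2 <- 1 - sum(res^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

# Balanced fixed-effects sums of squares computed from cell means, for
# checking sequential ANOVA on balanced designs.
balanced_ss_oracle <- function(y, f1, f2) {
  gm <- mean(y)
  m1 <- tapply(y, f1, mean)[f1]
  m2 <- tapply(y, f2, mean)[f2]
  m12 <- tapply(y, interaction(f1, f2), mean)[interaction(f1, f2)]
  list(ss1 = sum((m1 - gm)^2),
       ss2 = sum((m2 - gm)^2),
       ss12 = sum((m12 - m1 - m2 + gm)^2),
       ssres = sum((y - m12)^2))
}

# Small single-cell simulated dataset for gradient tests.
sim_one_cell <- function(n = 60, seed = 1, beta = NULL, gamma = NULL,
                         pollination = "C", baseline = 100,
                         pl_intensity = 1) {
  cfg <- sim_config(
    "two_site_two_year",
    cells = data.frame(site = "high_water", year = 2019L,
                       pollination = pollination, n = as.integer(n),
                       stringsAsFactors = FALSE),
    true_beta = beta, true_gamma = gamma, baseline_fitness = baseline,
    pl_intensity = pl_intensity, seed = seed)
  simulate_experiment(cfg)$records
}

# A standardized one-trait design with an exactly quadratic, noiseless
# fitness surface: w = c + coef * z^2 with the intercept chosen so that
# mean(w) = 1.
noiseless_quadratic_design <- function(n = 21, coef = 0.1) {
  x <- seq_len(n)
  z <- (x - mean(x)) / sd(x)
  w <- coef * z^2
  w <- w + (1 - mean(w))
  new_standardized_design(matrix(z, ncol = 1), w, trait_names = "trait1")
}
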