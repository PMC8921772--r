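traits6 <- trait_spec("exp1")

test_that("standardization centres, scales and relativizes within the cell", {
  recs <- data.frame(a = c(1, 2, 3), seeds_per_plant = c(10, 20, 30))
  d <- standardize_cell(recs, "a")
  expect_equal(d$z[, "a"], c(-1, 0, 1))
  expect_equal(d$w_rel, c(0.5, 1.0, 1.5))
  recs$b <- c(5, 9, 10, 7)[1:3]
  d2 <- standardize_cell(rbind(recs, data.frame(a = 5, seeds_per_plant = 25,
                                                b = 7)), c("a", "b"))
  expect_equal(mean(d2$z[, "b"]), 0)
  expect_equal(var(d2$z[, "b"]), 1)

  cell <- sim_one_cell(n = 50, seed = 41)
  d2 <- standardize_cell(cell, traits6)
  expect_true(all(abs(colMeans(d2$z)) < 1e-10))
  expect_true(all(abs(apply(d2$z, 2, var) - 1) < 1e-10))
  expect_equal(mean(d2$w_rel), 1, tolerance = 1e-12)
})

test_that("the zero-fitness policy is applied before moments are computed", {
  recs <- data.frame(a = c(1, 2, 3, 4, 9), b = c(2, 1, 5, 3, 4),
                     seeds_per_plant = c(0, 10, 20, 30, 40))
  inc <- standardize_cell(recs, c("a", "b"), "include")
  exc <- standardize_cell(recs, c("a", "b"), "exclude")
  expect_equal(length(exc$w_rel), 4L)
  expect_equal(mean(exc$w_rel), 1, tolerance = 1e-12)
  expect_true(all(abs(colMeans(exc$z)) < 1e-10))
  expect_equal(min(inc$w_rel), 0)
  expect_identical(attr(fit_directional(exc), "zero_fitness_policy"),
                   "exclude")
})

test_that("degenerate cells are refused with informative errors", {
  recs <- data.frame(a = rep(1, 10), b = rnorm(10),
                     seeds_per_plant = rpois(10, 20))
  expect_error(standardize_cell(recs, c("a", "b")), "constant within cell: a")
  recs2 <- data.frame(a = rnorm(10), b = rnorm(10),
                      seeds_per_plant = rep(0, 10))
  expect_error(standardize_cell(recs2, c("a", "b")), "zero fitness")
  expect_error(standardize_cell(recs[1:3, ], c("a", "b")), "at least 4")
})

test_that("a noiseless linear surface is fitted exactly", {
  z <- (1:11 - 6) / sd(1:11)
  w <- 1 + 0.5 * z
  d <- new_standardized_design(matrix(z, ncol = 1), w, "t1")
  g <- suppressWarnings(fit_directional(d))  # lm warns on a perfect fit
  expect_equal(g$estimate, 0.5, tolerance = 1e-12)
  expect_equal(g$std_error, 0, tolerance = 1e-10)
})

test_that("directional and quadratic fits match the normal-equations oracle", {
  set.seed(51)
  for (rep in 1:10) {
    k <- sample(2:6, 1)
    n <- sample((2 * k + 4):30, 1)
    recs <- as.data.frame(matrix(rnorm(n * k), n, k))
    names(recs) <- paste0("t", 1:k)
    recs$seeds_per_plant <- rpois(n, 30)
    if (mean(recs$seeds_per_plant) == 0) next
    d <- standardize_cell(recs, paste0("t", 1:k))
    g <- fit_directional(d)
    o <- ols_oracle(d$z, d$w_rel)
    expect_equal(g$estimate, unname(o$coef), tolerance = 1e-10)
    expect_equal(g$std_error, unname(o$se), tolerance = 1e-10)
    expect_equal(g$p_value, unname(o$p), tolerance = 1e-10)

    q <- fit_quadratic(d)
    oq <- ols_oracle(cbind(d$z, d$z^2), d$w_rel)
    expect_equal(q$estimate, unname(2 * oq$coef[(k + 1):(2 * k)]),
                 tolerance = 1e-10)
    expect_equal(q$std_error, unname(2 * oq$se[(k + 1):(2 * k)]),
                 tolerance = 1e-10)
  }
})

test_that("the quadratic gradient is exactly twice the raw coefficient", {
  d <- noiseless_quadratic_design(n = 21, coef = 0.1)
  q <- suppressWarnings(fit_quadratic(d))
  expect_equal(q$estimate, 0.2, tolerance = 1e-12)
  expect_equal(q$std_error, 0, tolerance = 1e-10)

  # with noise: gamma and its SE are 2x the raw quadratic fit, p unchanged
  cell <- sim_one_cell(n = 80, seed = 52)
  d2 <- standardize_cell(cell, traits6)
  q2 <- fit_quadratic(d2)
  raw <- ols_oracle(cbind(d2$z, d2$z^2), d2$w_rel)
  expect_equal(q2$estimate, unname(2 * raw$coef[7:12]), tolerance = 1e-10)
  expect_equal(q2$std_error, unname(2 * raw$se[7:12]), tolerance = 1e-10)
  expect_equal(q2$p_value, unname(raw$p[7:12]), tolerance = 1e-10)
})

test_that("gradients are invariant to rescaling absolute fitness", {
  cell <- sim_one_cell(n = 60, seed = 53)
  d1 <- standardize_cell(cell, traits6)
  cell$seeds_per_plant <- cell$seeds_per_plant * 17.3
  d2 <- standardize_cell(cell, traits6)
  for (f in list(fit_directional, fit_quadratic)) {
    g1 <- f(d1); g2 <- f(d2)
    expect_equal(g1$estimate, g2$estimate, tolerance = 1e-12)
    expect_equal(g1$std_error, g2$std_error, tolerance = 1e-12)
    expect_equal(g1$p_value, g2$p_value, tolerance = 1e-12)
  }
})

test_that("mild injected gradients are recovered at n = 2000", {
  beta <- c(0.2, 0.1, 0.15, 0.1, 0, 0.05)
  recs <- sim_one_cell(n = 2000, seed = 54, beta = beta)
  g <- fit_directional(standardize_cell(recs, traits6))
  expect_true(all(abs(g$estimate - beta) < 0.05))
})

test_that("strong selection is recovered up to the truncation of the surface", {
  # With beta = (0.3, 0.3, 0.4, 0.2, 0, 0) and correlated traits the linear
  # surface goes negative for >10% of plants; the generator floors expected
  # fitness there (and warns), so the estimable quantity is the OLS
  # projection of the floored surface, computed here by a large-n oracle.
  beta <- c(0.3, 0.3, 0.4, 0.2, 0, 0)
  sim <- suppressWarnings(make_fixture("strong_selection", n = 2000))
  cell <- sim$records[sim$records$site == "high_water" &
                      sim$records$year == 2019 &
                      sim$records$pollination == "C", ]
  g <- fit_directional(standardize_cell(cell, traits6))
  set.seed(55)
  R <- matrix(0.3, 6, 6); diag(R) <- 1
  Z <- scale(MASS::mvrnorm(100000, rep(0, 6), R))
  surf <- pmax(1 + drop(Z %*% beta), 1e-3)
  target <- ols_oracle(Z, surf / mean(surf))$coef
  expect_true(all(abs(g$estimate - target) < 0.05))
})

test_that("VIFs follow the closed form and flag collinearity", {
  set.seed(56)
  # mutually uncorrelated columns -> all VIFs 1
  X <- qr.Q(qr(cbind(1, matrix(rnorm(200), 50, 4))))[, 2:5]
  expect_equal(as.numeric(compute_vif(X)), rep(1, 4), tolerance = 1e-10)
  # exact pairwise correlation 0.8 -> VIF = 1/(1-0.64) for both columns
  x1 <- rnorm(200)
  x2 <- rnorm(200)
  e1 <- residuals(lm(x1 ~ 1)); e2 <- residuals(lm(x2 ~ x1))
  a <- e1 / sd(e1); b <- 0.8 * a + sqrt(1 - 0.64) * e2 / sd(e2)
  v <- suppressWarnings(compute_vif(cbind(a, b)))
  expect_equal(as.numeric(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-10)
  expect_false(any(attr(v, "flagged")))
  # duplicated column -> infinite and flagged
  vdup <- suppressWarnings(compute_vif(cbind(x1, x1, x2)))
  expect_equal(vdup[[1]], Inf)
  expect_true(attr(vdup, "flagged")[1])
  # matches the brute-force oracle and car's implementation on random data
  X <- matrix(rnorm(300), 60, 5)
  X[, 2] <- X[, 1] * 0.7 + X[, 2]
  expect_equal(as.numeric(compute_vif(X)), vif_oracle(X), tolerance = 1e-10)
  dfr <- data.frame(y = rnorm(60), X)
  expect_equal(as.numeric(compute_vif(X)),
               unname(car::vif(lm(y ~ ., dfr))), tolerance = 1e-8)
})
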