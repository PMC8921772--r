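test_that("one balanced factor: F equals the squared two-sample t statistic", {
  set.seed(71)
  recs <- data.frame(g = rep(c("a", "b"), each = 20),
                     y = exp(rnorm(40, 2, 0.3)))
  at <- factorial_anova(recs, "y", "g", transform = "log10")
  tt <- t.test(log10(y) ~ g, data = recs, var.equal = TRUE)
  expect_equal(at$F_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(at$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("sequential sums of squares match the balanced-design oracle", {
  set.seed(72)
  d <- expand.grid(f1 = c("a", "b", "c"), f2 = c("x", "y", "z"),
                   rep = 1:4)
  d$y <- rnorm(nrow(d)) + as.integer(d$f1) + 0.5 * as.integer(d$f2)
  at <- factorial_anova(d, "y", c("f1", "f2"), transform = "none")
  o <- balanced_ss_oracle(d$y, d$f1, d$f2)
  ss <- attr(at, "sum_sq")
  expect_equal(ss[1], o$ss1, tolerance = 1e-10)
  expect_equal(ss[2], o$ss2, tolerance = 1e-10)
  expect_equal(ss[3], o$ss12, tolerance = 1e-10)
  dfden <- at$df_den[1]
  msres <- o$ssres / dfden
  expect_equal(at$F_statistic,
               c(o$ss1 / 2, o$ss2 / 2, o$ss12 / 4) / msres,
               tolerance = 1e-10)
  # sequential components account for the total sum of squares
  expect_equal(sum(ss) + o$ssres, sum((d$y - mean(d$y))^2),
               tolerance = 1e-8)
})

test_that("Type I and Type III coincide on balanced designs, not unbalanced", {
  set.seed(73)
  d <- expand.grid(f1 = c("a", "b"), f2 = c("x", "y"), rep = 1:10)
  d$y <- rnorm(nrow(d), 10 + (d$f1 == "a") * 2, 1)
  a1 <- factorial_anova(d, "y", c("f1", "f2"), "log10", ss_type = "I")
  a3 <- factorial_anova(d, "y", c("f1", "f2"), "log10", ss_type = "III")
  expect_equal(a1$F_statistic, a3$F_statistic[match(a1$term, a3$term)],
               tolerance = 1e-8)
  du <- d[-(1:7), ]
  b1 <- factorial_anova(du, "y", c("f1", "f2"), "log10", ss_type = "I")
  b3 <- factorial_anova(du, "y", c("f1", "f2"), "log10", ss_type = "III")
  expect_gt(max(abs(b1$F_statistic -
                    b3$F_statistic[match(b1$term, b3$term)])), 1e-6)
})

test_that("log10 transform refuses non-positive responses, naming rows", {
  d <- data.frame(g = rep(c("a", "b"), 5), y = c(1, 2, 0, 4, 5, -1, 7:10))
  err <- tryCatch(factorial_anova(d, "y", "g"), error = conditionMessage)
  expect_match(err, "3")
  expect_match(err, "6")
  at <- factorial_anova(d, "y", "g", transform = "none")
  expect_s3_class(at, "anova_table")
})

test_that("a known site effect is detected with high power", {
  detected <- 0L
  for (r in 1:25) {
    sim <- make_fixture("exp1_default", seed = 800 + r)
    at <- factorial_anova(sim$records, "plant_height",
                          c("year", "site", "pollination"),
                          transform = "log10")
    detected <- detected + (at$p_value[at$term == "site"] < 0.05)
  }
  # published cell means differ by ~20% between sites; power should be high
  expect_gte(detected / 25, 0.9)
})

test_that("the ANCOVA detects a site-specific C-HP gradient difference", {
  traits <- trait_spec("exp1")
  beta_fun <- function(cell) {
    if (cell$site == "low_water" && cell$pollination == "C") {
      c(0, 0.4, 0, 0, 0, 0)
    } else {
      rep(0, 6)
    }
  }
  detected <- 0L
  for (r in 1:15) {
    cfg <- sim_config("two_site_two_year",
                      cells = data.frame(
                        site = rep(c("high_water", "low_water"), each = 4),
                        year = rep(rep(c(2019L, 2020L), each = 2), 2),
                        pollination = rep(c("C", "HP"), 4), n = 500L),
                      true_beta = beta_fun, baseline_fitness = 100,
                      seed = 900 + r)
    recs <- simulate_experiment(cfg)$records
    at <- ancova_selection_variation(recs, traits, c("site", "year"))
    p3 <- at$p_value[at$term == "plant_height:site:pollination"]
    detected <- detected + (length(p3) == 1L && p3 < 0.05)
  }
  expect_gte(detected / 15, 0.8)
})

test_that("the ANCOVA refuses degenerate designs", {
  sim <- make_fixture("exp1_default")
  one_site <- sim$records[sim$records$site == "high_water", ]
  expect_error(ancova_selection_variation(one_site, trait_spec("exp1"),
                                          c("site", "year")),
               "fewer than 2 observed levels")
  tiny <- sim$records[1:40, ]
  expect_error(ancova_selection_variation(tiny, trait_spec("exp1"),
                                          c("site", "year")),
               "degrees of freedom|fewer than 2")
})

test_that("strength ANOVA handles constant, saturated and permuted inputs", {
  st <- expand.grid(trait = paste0("t", 1:6), site = c("a", "b"),
                    year = c(1, 2))
  st$pm_strength <- 0.2
  st$net_strength <- 0.2
  at <- suppressWarnings(strength_anova(st, c("site", "year")))
  expect_equal(at$F_statistic, rep(0, 3))
  one <- st[st$trait == "t1", ]
  one$pm_strength <- rnorm(4)^2
  expect_error(strength_anova(one, c("site", "year")), "saturated")
  # permutation null: p-values approximately uniform
  set.seed(74)
  st$pm_strength <- rexp(24)
  ps <- replicate(300, {
    st$site <- sample(st$site)
    strength_anova(st, c("site", "year"))$p_value[1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("strength differences across sites are detectable", {
  traits <- trait_spec("exp1")
  beta_fun <- function(cell) {
    base <- if (cell$pollination == "C") c(0.25, 0.25, 0.25, 0.2, 0.15, 0.15)
            else c(0.25, 0.25, 0.25, 0.2, 0.15, 0.15) * 0
    if (cell$site == "low_water") base else base * 0
  }
  detected <- 0L
  for (r in 1:10) {
    cfg <- sim_config("two_site_two_year",
                      cells = data.frame(
                        site = rep(c("high_water", "low_water"), each = 4),
                        year = rep(rep(c(2019L, 2020L), each = 2), 2),
                        pollination = rep(c("C", "HP"), 4), n = 400L),
                      true_beta = beta_fun, baseline_fitness = 100,
                      seed = 1100 + r)
    recs <- suppressWarnings(simulate_experiment(cfg))$records
    net <- list(); pm <- list()
    for (s in c("high_water", "low_water")) for (y in c(2019, 2020)) {
      gs <- lapply(c("C", "HP"), function(p) {
        cell <- recs[recs$site == s & recs$year == y &
                     recs$pollination == p, ]
        fit_directional(standardize_cell(
          cell, traits, cell = list(site = s, year = y, pollination = p)))
      })
      net <- c(net, gs[1])
      pm <- c(pm, list(contrast_gradients(gs[[1]], gs[[2]])))
    }
    st <- strength_table(net, pm)
    at <- strength_anova(st, c("site", "year"))
    detected <- detected + (at$p_value[at$term == "site"] < 0.05)
  }
  expect_gte(detected / 10, 0.7)
})

test_that("variance homogeneity diagnostic runs and returns a p-value", {
  sim <- make_fixture("exp1_default")
  lev <- variance_homogeneity(sim$records, "plant_height",
                              c("site", "year"))
  expect_true(lev$p_value >= 0 && lev$p_value <= 1)
})
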