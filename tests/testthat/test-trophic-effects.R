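test_that("predation intensity and its one-sample Wilcoxon behave correctly", {
  expect_equal(predation_intensity(15, 30), 50)
  expect_equal(predation_intensity(0, 30), 0)
  expect_error(predation_intensity(5, 0), "> 0")
  expect_error(predation_intensity(31, 30), "between")
  expect_equal(predation_intensity_test(rep(0, 5))$p, 1)
  # strictly positive intensities, n = 6: exact signed-rank p = 2/2^6
  res <- predation_intensity_test(c(40, 50, 33, 47, 60, 27))
  expect_equal(res$p, 2 / 64)
  expect_lt(res$p, 0.05)
})

test_that("log response ratio and variance follow the delta-method formulas", {
  expect_equal(lrr_effect(3, 1, 5, 3, 1, 5)$lrr, 0)
  eff <- lrr_effect(2, 0, 4, 1, 0, 4)
  expect_equal(eff$lrr, log(2))
  expect_equal(eff$var, 0)
  # antisymmetry of the ratio; symmetry of the variance
  a <- lrr_effect(2.5, 0.4, 6, 1.2, 0.3, 8)
  b <- lrr_effect(1.2, 0.3, 8, 2.5, 0.4, 6)
  expect_equal(a$lrr, -b$lrr)
  expect_equal(a$var, b$var)
  expect_error(lrr_effect(0, 1, 5, 1, 1, 5), "> 0")
})

test_that("LRR sampling variance matches a Monte-Carlo oracle", {
  withr::with_seed(202, {
    mu_p <- 5
    mu_e <- 2
    sd_p <- 1
    sd_e <- 0.6
    n <- 20
    sims <- replicate(4000, {
      xp <- rnorm(n, mu_p, sd_p)
      xe <- rnorm(n, mu_e, sd_e)
      log(mean(xp)) - log(mean(xe))
    })
    v_formula <- lrr_effect(mu_p, sd_p, n, mu_e, sd_e, n)$var
    expect_lt(abs(var(sims) - v_formula) / v_formula, 0.12)
  })
})

test_that("DerSimonian-Laird pooling matches metafor and its edge cases", {
  # one study: pooled equals that study
  one <- pooled_random_effects(0.4, 0.02)
  expect_equal(one$estimate, 0.4)
  expect_equal(one$tau2, 0)
  # two studies, equal variances, Q below df: plain average
  two <- pooled_random_effects(c(0.1, 0.2), c(1, 1))
  expect_equal(two$estimate, 0.15)
  expect_equal(two$tau2, 0)
  # heterogeneous set against the reference implementation
  withr::with_seed(33, {
    y <- rnorm(8, 0.5, 0.4)
    v <- runif(8, 0.01, 0.2)
    ours <- pooled_random_effects(y, v)
    ref <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(ours$estimate, unname(ref$beta[1, 1]), tolerance = 1e-10)
    expect_equal(ours$tau2, unname(ref$tau2), tolerance = 1e-10)
    expect_equal(ours$Q, unname(ref$QE), tolerance = 1e-10)
    expect_equal(ours$se, unname(ref$se), tolerance = 1e-10)
    # pooled estimate is a weighted mean: inside the effect range
    expect_gte(ours$estimate, min(y))
    expect_lte(ours$estimate, max(y))
  })
})

test_that("monthly exclusion effect sizes use the exclusion/control orientation", {
  # identical arms: zero effect
  ser <- manual_series(c(2, 3, 4, 5), c(2, 3, 4, 5))
  eff <- exclusion_effect_on_crabs(ser)
  expect_equal(eff$lrr, 0)
  expect_equal(eff$orientation, "exclusion_over_control")
  # general case: log ratio of +1-shifted arm means, reversed sign vs the
  # control/exclusion convention of lrr_effect()
  ser2 <- manual_series(c(6, 8, 10, 12), c(1, 2, 3, 4))
  eff2 <- exclusion_effect_on_crabs(ser2)
  expect_equal(eff2$lrr, log(mean(c(6, 8, 10, 12) + 1) / mean(c(1, 2, 3, 4) + 1)))
  swapped <- lrr_effect(
    mean(c(1, 2, 3, 4) + 1), sd(c(1, 2, 3, 4)), 4,
    mean(c(6, 8, 10, 12) + 1), sd(c(6, 8, 10, 12)), 4
  )
  expect_equal(eff2$lrr, -swapped$lrr)
  expect_equal(eff2$var, swapped$var)
})

test_that("meta-regression matches metafor and degenerates to OLS", {
  withr::with_seed(44, {
    k <- 12
    x <- runif(k, 0, 50)
    v <- runif(k, 0.01, 0.05)
    y <- -0.3 + 0.02 * x + rnorm(k, 0, sqrt(v + 0.05))
    ours <- moderator_regression(y, v, x)
    ref <- metafor::rma(yi = y, vi = v, mods = ~x, method = "DL")
    expect_equal(ours$slope, unname(ref$beta["x", 1]), tolerance = 1e-8)
    expect_equal(ours$tau2, unname(ref$tau2), tolerance = 1e-8)
    expect_equal(ours$se, unname(ref$se[2]), tolerance = 1e-8)
    # zero sampling variances reduce to ordinary least squares
    ols <- moderator_regression(y, rep(0, k), x)
    expect_equal(ols$slope, unname(coef(lm(y ~ x))[2]))
    # constant moderator: slope not identifiable, reported as 0
    expect_warning(flat <- moderator_regression(y, v, rep(3, k)), "constant")
    expect_equal(flat$slope, 0)
  })
})

test_that("meta-regression recovers a generating slope with near-nominal coverage", {
  withr::with_seed(55, {
    beta <- 0.02
    k <- 36 # three years of monthly effect sizes, as in the monitoring design
    x <- rep(default_bird_profile(), 3)
    covered <- replicate(500, {
      v <- runif(k, 0.01, 0.05)
      y <- -0.5 + beta * x + rnorm(k, 0, 0.1) + rnorm(k, 0, sqrt(v))
      fit <- moderator_regression(y, v, x)
      fit$ci_lower <= beta && beta <= fit$ci_upper
    })
    expect_gte(mean(covered), 0.93)
  })
})

test_that("historical back-projection follows the proportional-suppression rule", {
  # no exclusion effect, or no population change: today's density
  expect_equal(back_project_crabs(10, 10, 0.8, 10, 1), 10)
  expect_equal(back_project_crabs(10, 30, 0.8, 5, 5), 10)
  # hand-computed case
  expect_equal(back_project_crabs(10, 30, 0.8, 10, 1), -215)
  # decreasing in the historical population when exclusion increases crabs
  n_then <- seq(1, 20, by = 0.5)
  d <- sapply(n_then, function(nt) back_project_crabs(10, 30, 0.8, nt, 1))
  expect_true(all(diff(d) < 0))
  expect_error(back_project_crabs(10, 30, 1.2, 10, 1), "p")
})
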