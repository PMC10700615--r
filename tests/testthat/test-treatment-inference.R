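test_that("compact letter display separates exactly the significant pairs", {
  # no significant pairs: everyone shares "a"
  expect_equal(
    unname(compact_letters(c("x", "y", "z"), matrix(character(0), ncol = 2))),
    c("a", "a", "a")
  )
  # x vs z significant, y overlaps both
  out <- compact_letters(c("x", "y", "z"), cbind("x", "z"))
  expect_equal(unname(out), c("a", "ab", "b"))
  # all pairs significant: three distinct letters
  out <- compact_letters(
    c("x", "y", "z"),
    rbind(c("x", "y"), c("x", "z"), c("y", "z"))
  )
  expect_equal(unname(out), c("a", "b", "c"))
})

test_that("one-way ANOVA with Tukey HSD matches a studentized-range oracle", {
  # two identical groups: F = 0, p = 1
  res <- anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(unname(res$letters), c("a", "a"))

  # a distant third group earns its own letter
  value <- c(1, 2, 3, 1, 2, 3, 101, 102, 103)
  group <- rep(c("g1", "g2", "g3"), each = 3)
  res <- anova_tukey(value, group)
  expect_equal(unname(res$letters[c("g3", "g1", "g2")]), c("a", "b", "b"))

  # Tukey adjusted p via direct studentized-range computation
  k <- 3
  n <- 3
  mse <- sum((value - ave(value, group))^2) / (length(value) - k)
  q_obs <- abs(mean(value[group == "g1"]) - mean(value[group == "g3"])) /
    sqrt(mse / n)
  p_oracle <- 1 - ptukey(q_obs, nmeans = k, df = length(value) - k)
  p_pkg <- res$pairs$p_adj[
    (res$pairs$group1 == "g3" & res$pairs$group2 == "g1") |
      (res$pairs$group1 == "g1" & res$pairs$group2 == "g3")
  ]
  expect_equal(unname(p_pkg), unname(p_oracle), tolerance = 1e-8)

  # relabelling groups permutes letters consistently
  relab <- c(g1 = "B", g2 = "C", g3 = "A")
  res2 <- anova_tukey(value, relab[group])
  expect_equal(unname(res2$letters[relab[c("g3", "g1", "g2")]]), c("a", "b", "b"))

  expect_error(
    anova_tukey(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3)),
    "zero within-group variance"
  )
})

test_that("pairwise Wilcoxon applies the Bonferroni rule to exact p values", {
  # identical groups: all adjusted p = 1
  v <- rep(c(1, 2, 3, 4, 5, 6, 7, 8), 3)
  g <- rep(c("a", "b", "c"), each = 8)
  res <- suppressWarnings(wilcoxon_pairwise(v, g))
  expect_true(all(res$pairs$p_adj == 1))
  expect_equal(unname(res$letters), c("a", "a", "a"))

  # Bonferroni: adjusted = min(1, m * p) against the exact rank-sum p
  withr::with_seed(77, {
    v <- c(rnorm(8), rnorm(8, 3), rnorm(8, 6))
    g <- rep(c("a", "b", "c"), each = 8)
    res <- wilcoxon_pairwise(v, g)
    raw <- mapply(function(g1, g2) {
      wilcox.test(v[g == g1], v[g == g2])$p.value
    }, res$pairs$group1, res$pairs$group2)
    expect_equal(res$pairs$p_adj, pmin(1, 3 * unname(raw)))
  })

  # a large shift at n = 8 per group is detected
  withr::with_seed(78, {
    v <- c(rnorm(8), rnorm(8, 10))
    res <- wilcoxon_pairwise(v, rep(c("a", "b"), each = 8))
    expect_lt(res$pairs$p_adj[1], 0.05)
    expect_equal(unname(res$letters), c("a", "b"))
  })
})

test_that("pairwise proportion tests detect extreme splits and are symmetric", {
  eq <- pairwise_proportions(c(a = 10, b = 10), c(a = 20, b = 20))
  expect_equal(eq$pairs$p_adj, 1)
  ex <- pairwise_proportions(c(a = 0, b = 20), c(a = 20, b = 20))
  expect_lt(ex$pairs$p_adj, 0.001)
  sw <- pairwise_proportions(c(b = 20, a = 0), c(b = 20, a = 20))
  expect_equal(ex$pairs$p_adj, sw$pairs$p_adj)
  # chi-square oracle with continuity correction
  oracle <- prop.test(c(0, 20), c(20, 20))$p.value
  expect_equal(ex$pairs$p, oracle)
})

test_that("first-week loss rate is the OLS slope of counts on days", {
  expect_equal(first_week_loss_rate(rep(12, 4), c(0, 2, 4, 6)), 0)
  expect_equal(first_week_loss_rate(c(135, 129, 123, 117), c(0, 2, 4, 6)), -3)
  withr::with_seed(12, {
    days <- c(0, 2, 4, 6)
    counts <- 135 - 5 * days + rnorm(4, 0, 3)
    closed <- sum((days - mean(days)) * (counts - mean(counts))) /
      sum((days - mean(days))^2)
    expect_equal(first_week_loss_rate(counts, days), closed)
  })
})

test_that("plant-loss comparison separates the grazed and protected arms", {
  ds <- generate_experiment(experiment_config(seed = 21))
  res <- plant_loss_comparison(ds$plants)
  slopes <- res$slopes |>
    dplyr::group_by(treatment) |>
    dplyr::summarise(m = mean(slope))
  m <- setNames(slopes$m, slopes$treatment)
  expect_lt(m[["planting_exclusion"]], m[["planting_control"]])
  expect_gt(m[["planting_predation_sim"]], m[["planting_control"]])
  expect_false(
    res$comparison$letters[["planting_predation_sim"]] %in%
      res$comparison$letters[["planting_exclusion"]]
  )
})

test_that("AICc model selection prefers the generating polynomial form", {
  x <- seq(-3, 3, length.out = 30)
  withr::with_seed(89, {
    lin <- fit_and_select(x, 2 + 3 * x + rnorm(30, 0, 0.5))
    expect_equal(lin$form, "linear")
  })
  withr::with_seed(90, {
    quad <- fit_and_select(x, 1 - 2 * x + 4 * x^2 + rnorm(30, 0, 0.5))
    expect_equal(quad$form, "quadratic")
    # the correction term shrinks with n: AICc -> AIC
    n <- 30
    k <- 4 # quadratic: 3 coefficients + residual variance
    expect_equal(
      quad$aicc[["quadratic"]] - AIC(quad$fit),
      2 * k * (k + 1) / (n - k - 1)
    )
  })
})

test_that("Spearman matrix equals rank-then-Pearson and is transform-invariant", {
  ds <- generate_experiment(experiment_config(seed = 13), include = "functions")
  fm <- ds$functions
  s <- spearman_matrix(fm)
  expect_equal(unname(diag(s)), rep(1, 12))
  oracle <- cor(apply(as.matrix(fm[, marsh_functions()]), 2, rank))
  expect_equal(unname(s), unname(oracle))
  # monotone transform of a column leaves its correlations unchanged
  fm2 <- dplyr::mutate(fm, soil_respiration = exp(soil_respiration))
  expect_equal(spearman_matrix(fm2), s)
})
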