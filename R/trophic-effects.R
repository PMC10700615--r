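# Effect-size machinery for the trophic cascade: predation intensity, log
# response ratios with sampling variances, DerSimonian-Laird random-effects
# pooling, monthly exclusion effect sizes on crab abundance, meta-regression
# against bird abundance, and the historical grazer back-projection.

#' Shorebird predation intensity on tethered crabs
#'
#' Percentage of tethered crabs eaten: `n_eaten * 100 / n_total`.
#' [predation_intensity_test()] runs the companion two-sided one-sample
#' Wilcoxon signed-rank test of site-level intensities against zero.
#'
#' @param n_eaten Number of crabs that died from predation (0 <= eaten <=
#'   total).
#' @param n_total Number of crabs tethered (> 0).
#' @return Percent (vectorised).
#' @export
#' @examples
#' predation_intensity(15, 30) # 50
predation_intensity <- function(n_eaten, n_total) {
  if (any(n_total <= 0)) stop("`n_total` must be > 0", call. = FALSE)
  if (any(n_eaten < 0) || any(n_eaten > n_total)) {
    stop("`n_eaten` must be between 0 and `n_total`", call. = FALSE)
  }
  n_eaten * 100 / n_total
}

#' @rdname predation_intensity
#' @param intensities Site-level predation intensities (percent).
#' @return `predation_intensity_test()`: list with `statistic` (V) and `p`.
#' @export
predation_intensity_test <- function(intensities) {
  if (all(intensities == 0)) {
    # signed-rank test drops zeros; no evidence against the null
    return(list(statistic = 0, p = 1))
  }
  ht <- wilcox.test(intensities, mu = 0, alternative = "two.sided")
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Log response ratio and its sampling variance
#'
#' The natural log response ratio `LRR = ln(x_p) - ln(x_e)` between a
#' plant-present/control arm (P) and an exclusion arm (E), with delta-method
#' sampling variance `Var = s_e^2/(n_e x_e^2) + s_p^2/(n_p x_p^2)`. With the
#' control mean as the numerator, negative values indicate that grazers
#' suppress plant biomass.
#'
#' @param x_p,x_e Group means (> 0).
#' @param s_p,s_e Group standard deviations (>= 0).
#' @param n_p,n_e Group sample sizes (>= 1).
#' @param group Optional label carried through to the result.
#' @return One-row tibble `group, lrr, var, x_p, s_p, n_p, x_e, s_e, n_e`.
#' @export
lrr_effect <- function(x_p, s_p, n_p, x_e, s_e, n_e, group = NA_character_) {
  if (any(c(x_p, x_e) <= 0)) stop("means must be > 0", call. = FALSE)
  if (any(c(s_p, s_e) < 0)) stop("sds must be >= 0", call. = FALSE)
  if (any(c(n_p, n_e) < 1)) stop("sample sizes must be >= 1", call. = FALSE)
  tibble::tibble(
    group = group,
    lrr = log(x_p) - log(x_e),
    var = s_e^2 / (n_e * x_e^2) + s_p^2 / (n_p * x_p^2),
    x_p = x_p, s_p = s_p, n_p = n_p, x_e = x_e, s_e = s_e, n_e = n_e
  )
}

#' Random-effects pooling of effect sizes (DerSimonian-Laird)
#'
#' Inverse-variance pooling with DerSimonian-Laird between-study variance:
#' from the fixed-effect Q statistic, `tau2 = max(0, (Q - (k-1)) /
#' (sum(w) - sum(w^2)/sum(w)))`; studies are then reweighted by
#' `1/(var + tau2)` and the pooled mean gets a normal-theory 95% CI. The
#' pooled effect is considered significant when the CI excludes zero.
#'
#' @param lrr Effect sizes.
#' @param var Their sampling variances (all > 0 unless a single effect is
#'   supplied, which is returned as-is with `tau2 = 0`).
#' @param conf_level Confidence level, default 0.95.
#' @return List: `estimate`, `se`, `ci_lower`, `ci_upper`, `tau2`, `Q`,
#'   `df`, `k`.
#' @export
pooled_random_effects <- function(lrr, var, conf_level = 0.95) {
  k <- length(lrr)
  if (k != length(var)) stop("`lrr` and `var` lengths differ", call. = FALSE)
  if (k == 0) stop("no effects to pool", call. = FALSE)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (k == 1) {
    se <- sqrt(var)
    return(list(
      estimate = lrr, se = se, ci_lower = lrr - z * se,
      ci_upper = lrr + z * se, tau2 = 0, Q = 0, df = 0, k = 1
    ))
  }
  if (any(var <= 0)) stop("variances must be > 0 to pool", call. = FALSE)
  w <- 1 / var
  fe <- sum(w * lrr) / sum(w)
  Q <- sum(w * (lrr - fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (var + tau2)
  est <- sum(ws * lrr) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(
    estimate = est, se = se, ci_lower = est - z * se, ci_upper = est + z * se,
    tau2 = tau2, Q = Q, df = k - 1, k = k
  )
}

#' Monthly shorebird-exclusion effect size on crab abundance
#'
#' For each calendar month, the log response ratio of crab (burrow) abundance
#' with the exclusion arm as the numerator:
#' `ln(mean exclusion) - ln(mean control)` - positive values mean exclusion
#' *increased* crabs. This is the reverse of the [lrr_effect()] control/
#' exclusion orientation, recorded in the `orientation` column. Counts are
#' shifted by `shift` (default +1) before taking means so months with zero
#' burrows stay usable.
#'
#' @param series Monthly series tibble with columns `plot_id, treatment,
#'   year, month, count` (see [generate_experiment()]); only the
#'   `planting_exclusion` and `planting_control` arms are used.
#' @param shift Added to every count before analysis, default 1.
#' @return Tibble with one row per year-month: `year, month, lrr, var`,
#'   means/sds/sizes for both arms, and `orientation =
#'   "exclusion_over_control"`.
#' @export
exclusion_effect_on_crabs <- function(series, shift = 1) {
  need <- c("planting_exclusion", "planting_control")
  ser <- series[series$treatment %in% need & !is.na(series$count), ]
  if (nrow(ser) == 0) stop("series has no exclusion/control rows", call. = FALSE)
  ser$count <- ser$count + shift
  per_arm <- ser |>
    dplyr::group_by(.data$year, .data$month, .data$treatment) |>
    dplyr::summarise(
      mean = mean(.data$count), sd = sd(.data$count),
      n = dplyr::n(), .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "treatment",
      values_from = c("mean", "sd", "n")
    )
  eff <- lrr_effect(
    x_p = per_arm$mean_planting_exclusion,
    s_p = per_arm$sd_planting_exclusion,
    n_p = per_arm$n_planting_exclusion,
    x_e = per_arm$mean_planting_control,
    s_e = per_arm$sd_planting_control,
    n_e = per_arm$n_planting_control
  )
  tibble::tibble(
    year = per_arm$year, month = per_arm$month,
    lrr = eff$lrr, var = eff$var,
    mean_exclusion = eff$x_p, sd_exclusion = eff$s_p, n_exclusion = eff$n_p,
    mean_control = eff$x_e, sd_control = eff$s_e, n_control = eff$n_e,
    orientation = "exclusion_over_control"
  )
}

#' Meta-regression of effect sizes on a moderator
#'
#' Inverse-variance weighted regression of effect sizes on a moderator (e.g.
#' monthly bird abundance) with an additive between-month heterogeneity
#' component estimated by the method of moments: the fixed-effects weighted
#' residual Q_E gives `tau2 = max(0, (Q_E - (k - p)) / tr(P))` with
#' `P = W - W X (X' W X)^-1 X' W`, after which the model is refit with
#' weights `1/(var + tau2)` and Wald confidence intervals are reported.
#' When every `var` is 0 this reduces to ordinary least squares.
#'
#' @param lrr Effect sizes (>= 3).
#' @param var Sampling variances (>= 0).
#' @param moderator Moderator values, same length.
#' @param conf_level Confidence level, default 0.95.
#' @return List: `slope`, `se`, `ci_lower`, `ci_upper`, `p`, `intercept`,
#'   `tau2`, `k`.
#' @export
moderator_regression <- function(lrr, var, moderator, conf_level = 0.95) {
  k <- length(lrr)
  if (k < 3) stop("need at least 3 effects", call. = FALSE)
  if (length(var) != k || length(moderator) != k) {
    stop("`lrr`, `var`, `moderator` lengths differ", call. = FALSE)
  }
  if (sd(moderator) == 0) {
    warning("moderator is constant; slope is not identifiable, returning 0")
    return(list(
      slope = 0, se = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
      p = 1, intercept = NA_real_, tau2 = NA_real_, k = k
    ))
  }
  X <- cbind(1, moderator)
  p <- ncol(X)
  fit_wls <- function(w) {
    W <- diag(w)
    xtwx_inv <- solve(t(X) %*% W %*% X)
    beta <- xtwx_inv %*% t(X) %*% (w * lrr)
    list(beta = drop(beta), cov = xtwx_inv, W = W, xtwx_inv = xtwx_inv)
  }
  if (all(var == 0)) {
    # degenerate case: ordinary least squares with empirical residual variance
    fit <- lm(lrr ~ moderator)
    sm <- summary(fit)
    est <- coef(sm)["moderator", ]
    z <- qnorm(1 - (1 - conf_level) / 2)
    return(list(
      slope = est[["Estimate"]], se = est[["Std. Error"]],
      ci_lower = est[["Estimate"]] - z * est[["Std. Error"]],
      ci_upper = est[["Estimate"]] + z * est[["Std. Error"]],
      p = est[["Pr(>|t|)"]], intercept = coef(fit)[[1]], tau2 = NA_real_,
      k = k
    ))
  }
  w <- 1 / var
  f0 <- fit_wls(w)
  resid <- lrr - drop(X %*% f0$beta)
  QE <- sum(w * resid^2)
  P <- f0$W - f0$W %*% X %*% f0$xtwx_inv %*% t(X) %*% f0$W
  tau2 <- max(0, (QE - (k - p)) / sum(diag(P)))
  f1 <- fit_wls(1 / (var + tau2))
  se <- sqrt(diag(f1$cov))
  z <- qnorm(1 - (1 - conf_level) / 2)
  slope <- f1$beta[2]
  list(
    slope = unname(slope), se = unname(se[2]),
    ci_lower = unname(slope - z * se[2]), ci_upper = unname(slope + z * se[2]),
    p = unname(2 * pnorm(-abs(slope / se[2]))),
    intercept = unname(f1$beta[1]), tau2 = tau2, k = k
  )
}

#' Back-project historical grazer density from an exclusion contrast
#'
#' Assuming shorebirds suppress crabs in proportion to their abundance, the
#' crab density before the shorebird population collapse is
#' `D_then = D_c + [(D_c - D_e) / (p * N_now)] * (N_then - N_now)`, where
#' `D_c`/`D_e` are mean crab densities in control/exclusion arms today, `p`
#' the proportional footprint change between the arms, and `N_then`/`N_now`
#' the historical and present shorebird populations. A negative result is
#' interpreted as potential elimination of crab grazers at historical
#' shorebird abundance.
#'
#' @param d_control,d_exclusion Present mean crab burrow densities
#'   (burrows m-2) in the control and exclusion arms.
#' @param p Proportional change in shorebird activity between arms,
#'   in (0, 1].
#' @param n_then,n_now Shorebird population counts then and now (> 0).
#' @return Back-projected historical density (may be negative).
#' @export
#' @examples
#' back_project_crabs(10, 30, 0.8, n_then = 10, n_now = 1) # -215
back_project_crabs <- function(d_control, d_exclusion, p, n_then, n_now) {
  if (p <= 0 || p > 1) stop("`p` must be in (0, 1]", call. = FALSE)
  if (n_then <= 0 || n_now <= 0) {
    stop("population counts must be > 0", call. = FALSE)
  }
  d_control + ((d_control - d_exclusion) / (p * n_now)) * (n_then - n_now)
}
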