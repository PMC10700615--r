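# Treatment-comparison statistics: one-way ANOVA with Tukey HSD and compact
# letter displays, pairwise Wilcoxon rank-sum tests with Bonferroni
# adjustment, pairwise proportion tests, first-week plant-loss slopes, AICc
# model selection, and Spearman correlations among functions.

#' Compact letter display from significant pairs
#'
#' Assigns letters to groups so that two groups share a letter exactly when
#' they are *not* significantly different, using the insert-and-absorb
#' algorithm: start from a single letter containing all groups; for each
#' significant pair, split every letter containing both members; absorb
#' letters whose group set is contained in another's. Groups are ordered by
#' descending mean so "a" is attached to the highest-mean group.
#'
#' @param groups Group names ordered by descending mean.
#' @param sig_pairs Two-column character matrix (or data frame) of group
#'   pairs judged significantly different; may have zero rows.
#' @return Named character vector of letters, one per group.
#' @export
compact_letters <- function(groups, sig_pairs) {
  cols <- list(stats::setNames(rep(TRUE, length(groups)), groups))
  sig_pairs <- as.matrix(sig_pairs)
  if (nrow(sig_pairs) > 0) {
    for (r in seq_len(nrow(sig_pairs))) {
      g1 <- sig_pairs[r, 1]
      g2 <- sig_pairs[r, 2]
      new_cols <- list()
      for (col in cols) {
        if (col[[g1]] && col[[g2]]) {
          c1 <- col
          c1[[g1]] <- FALSE
          c2 <- col
          c2[[g2]] <- FALSE
          new_cols <- c(new_cols, list(c1, c2))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop columns whose membership is a subset of another's
      keep <- rep(TRUE, length(new_cols))
      for (i in seq_along(new_cols)) {
        for (j in seq_along(new_cols)) {
          if (i != j && keep[j] &&
            all(!new_cols[[i]] | new_cols[[j]]) &&
            !identical(new_cols[[i]], new_cols[[j]])) {
            keep[i] <- FALSE
            break
          }
        }
      }
      # deduplicate identical columns
      cols <- unique(new_cols[keep])
    }
  }
  # order letters by the first (highest-mean) group they contain
  first_member <- vapply(
    cols, function(col) min(which(col)), numeric(1)
  )
  cols <- cols[order(first_member)]
  out <- vapply(groups, function(g) {
    paste0(letters[which(vapply(cols, function(col) col[[g]], logical(1)))],
      collapse = ""
    )
  }, character(1))
  out
}

new_treatment_comparison <- function(method, statistic, df, p, pairs,
                                     letters, means) {
  means <- setNames(as.numeric(means), names(means)) # drop tapply's dims
  structure(
    list(
      method = method, statistic = statistic, df = df, p = p,
      pairs = pairs, letters = letters, means = means
    ),
    class = "treatment_comparison"
  )
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(x$method, "\n")
  cat(
    "  statistic =", format(x$statistic, digits = 4),
    " df =", paste(x$df, collapse = ", "),
    " p =", format.pval(x$p, digits = 3), "\n"
  )
  cat("  groups:\n")
  print(tibble::tibble(
    group = names(x$letters),
    mean = unname(x$means[names(x$letters)]),
    letter = unname(x$letters)
  ))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Classical one-way ANOVA across treatment groups followed by Tukey's HSD on
#' all pairs; letters are assigned with [compact_letters()] (groups ordered by
#' descending mean, pairs with adjusted p below `alpha` separated).
#'
#' @param value Numeric response.
#' @param group Treatment labels (coerced to factor); >= 2 groups with >= 2
#'   observations each.
#' @param alpha Significance level for separating letters, default 0.05.
#' @return A `treatment_comparison`: F statistic, df pair, p, per-pair tibble
#'   (`group1, group2, diff, p_adj`), letters, and group means.
#' @export
anova_tukey <- function(value, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(group) < 2)) {
    stop("need >= 2 observations per group", call. = FALSE)
  }
  if (all(tapply(value, group, var) == 0)) {
    stop("zero within-group variance everywhere; F undefined", call. = FALSE)
  }
  fit <- aov(value ~ group)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pair_names <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- tibble::tibble(
    group1 = vapply(pair_names, `[`, character(1), 1),
    group2 = vapply(pair_names, `[`, character(1), 2),
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"]
  )
  means <- sort(tapply(value, group, mean), decreasing = TRUE)
  sig <- pairs[pairs$p_adj < alpha, c("group1", "group2")]
  new_treatment_comparison(
    method = "one-way ANOVA + Tukey HSD",
    statistic = an[["F value"]][1],
    df = c(an[["Df"]][1], an[["Df"]][2]),
    p = an[["Pr(>F)"]][1],
    pairs = pairs,
    letters = compact_letters(names(means), sig),
    means = means
  )
}

#' Pairwise Wilcoxon rank-sum tests with Bonferroni adjustment
#'
#' Nonparametric alternative to [anova_tukey()] for responses that violate
#' ANOVA assumptions: all pairwise two-sample Wilcoxon rank-sum tests with
#' Bonferroni-adjusted p values (`min(1, m * p)`), plus a Kruskal-Wallis
#' statistic as the omnibus test. Letters as in [anova_tukey()].
#'
#' @inheritParams anova_tukey
#' @param adjust Multiplicity adjustment passed to [stats::p.adjust()],
#'   default `"bonferroni"`.
#' @return A `treatment_comparison` (statistic is the Kruskal-Wallis chi2).
#' @export
wilcoxon_pairwise <- function(value, group, alpha = 0.05,
                              adjust = "bonferroni") {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups", call. = FALSE)
  lev <- levels(group)
  combos <- utils::combn(lev, 2)
  raw_p <- apply(combos, 2, function(pr) {
    suppressWarnings(
      wilcox.test(value[group == pr[1]], value[group == pr[2]])$p.value
    )
  })
  p_adj <- p.adjust(raw_p, method = adjust)
  pairs <- tibble::tibble(
    group1 = combos[1, ], group2 = combos[2, ],
    p = raw_p, p_adj = p_adj
  )
  kw <- kruskal.test(value, group)
  means <- sort(tapply(value, group, mean), decreasing = TRUE)
  sig <- pairs[pairs$p_adj < alpha, c("group1", "group2")]
  new_treatment_comparison(
    method = paste0("pairwise Wilcoxon rank-sum (", adjust, ")"),
    statistic = unname(kw$statistic),
    df = unname(kw$parameter),
    p = kw$p.value,
    pairs = pairs,
    letters = compact_letters(names(means), sig),
    means = means
  )
}

#' Pairwise proportion tests with Bonferroni adjustment
#'
#' Two-sided pairwise comparisons of success proportions (e.g. tethered crabs
#' eaten per treatment) using the chi-square test with continuity correction,
#' Bonferroni-adjusted. Letters as in [anova_tukey()], ordered by descending
#' proportion.
#'
#' @param successes,totals Named integer vectors per group (same names).
#' @param alpha Significance level, default 0.05.
#' @param adjust Adjustment method, default `"bonferroni"`.
#' @return A `treatment_comparison` (statistic/df/p are from the omnibus
#'   chi-square test over all groups; `means` are the proportions).
#' @export
pairwise_proportions <- function(successes, totals, alpha = 0.05,
                                 adjust = "bonferroni") {
  if (is.null(names(successes))) {
    names(successes) <- paste0("group", seq_along(successes))
  }
  if (length(successes) != length(totals)) {
    stop("`successes` and `totals` lengths differ", call. = FALSE)
  }
  lev <- names(successes)
  combos <- utils::combn(lev, 2)
  raw_p <- apply(combos, 2, function(pr) {
    suppressWarnings(
      prop.test(successes[pr], totals[pr])$p.value
    )
  })
  p_adj <- p.adjust(raw_p, method = adjust)
  pairs <- tibble::tibble(
    group1 = combos[1, ], group2 = combos[2, ],
    p = raw_p, p_adj = p_adj
  )
  omni <- suppressWarnings(prop.test(successes, totals))
  props <- sort(successes / totals, decreasing = TRUE)
  sig <- pairs[pairs$p_adj < alpha, c("group1", "group2")]
  new_treatment_comparison(
    method = paste0("pairwise proportion test (", adjust, ")"),
    statistic = unname(omni$statistic),
    df = unname(omni$parameter),
    p = omni$p.value,
    pairs = pairs,
    letters = compact_letters(names(props), sig),
    means = props
  )
}

#' Initial plant-loss rate over the first week
#'
#' Ordinary least-squares slope of plant counts against day over the first
#' week after planting, in plants per day, for one plot.
#' [plant_loss_comparison()] computes per-plot slopes from a plant count
#' series and compares treatments with [anova_tukey()].
#'
#' @param counts Plant counts.
#' @param days Days since planting (same length, within the first week).
#' @return Slope (plants day-1).
#' @export
first_week_loss_rate <- function(counts, days) {
  if (length(counts) != length(days) || length(counts) < 2) {
    stop("need >= 2 paired observations", call. = FALSE)
  }
  unname(coef(lm(counts ~ days))[2])
}

#' @rdname first_week_loss_rate
#' @param plants Tibble `plot_id, treatment, day, count` (day <= `window`
#'   rows are used); treatments without plants should be excluded upstream.
#' @param window Last day included, default 7.
#' @param alpha Significance level for the treatment comparison.
#' @return `plant_loss_comparison()`: list with `slopes` (per-plot tibble)
#'   and `comparison` (a `treatment_comparison`).
#' @export
plant_loss_comparison <- function(plants, window = 7, alpha = 0.05) {
  first <- plants[plants$day <= window, ]
  slopes <- first |>
    dplyr::group_by(.data$plot_id, .data$treatment) |>
    dplyr::summarise(
      slope = first_week_loss_rate(.data$count, .data$day),
      .groups = "drop"
    )
  list(
    slopes = slopes,
    comparison = anova_tukey(slopes$slope, slopes$treatment, alpha = alpha)
  )
}

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n-k-1)` with k the number of estimated parameters
#' (including the residual variance); infinite when `n <= k + 1`.
#'
#' @param fit An `lm` fit.
#' @return AICc value.
#' @export
aicc <- function(fit) {
  ll <- logLik(fit)
  k <- attr(ll, "df")
  n <- attr(ll, "nobs")
  if (n - k - 1 <= 0) {
    return(Inf)
  }
  AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit linear and quadratic regressions and select by AICc
#'
#' Fits `y ~ x` and `y ~ x + x^2` by OLS and returns the form with the lower
#' small-sample-corrected AIC.
#'
#' @param x,y Numeric vectors.
#' @return List: `form` ("linear" or "quadratic"), `fit` (the selected `lm`),
#'   `coefficients`, `aicc` (named vector for both forms), `r_squared`, `n`.
#' @export
fit_and_select <- function(x, y) {
  if (length(x) != length(y)) stop("`x`, `y` lengths differ", call. = FALSE)
  lin <- lm(y ~ x)
  quad <- lm(y ~ x + I(x^2))
  scores <- c(linear = aicc(lin), quadratic = aicc(quad))
  form <- names(scores)[which.min(scores)]
  fit <- if (form == "linear") lin else quad
  list(
    form = form,
    fit = fit,
    coefficients = coef(fit),
    aicc = scores,
    r_squared = summary(fit)$r.squared,
    n = length(x)
  )
}

#' Spearman correlation matrix among the twelve functions
#'
#' @param fm Function matrix ([build_function_matrix()]).
#' @param columns Columns to correlate, default [marsh_functions()].
#' @return 12 x 12 Spearman correlation matrix.
#' @export
spearman_matrix <- function(fm, columns = marsh_functions()) {
  cor(as.matrix(fm[, columns, drop = FALSE]), method = "spearman")
}
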