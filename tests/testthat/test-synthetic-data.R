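test_that("generation is deterministic given the seed and sensitive to it", {
  a <- generate_experiment(experiment_config(seed = 42))
  b <- generate_experiment(experiment_config(seed = 42))
  expect_identical(a, b)
  c <- generate_experiment(experiment_config(seed = 43), include = "functions")
  expect_false(identical(a$functions, c$functions))
})

test_that("datasets satisfy the design invariants", {
  cfg <- experiment_config(seed = 8)
  ds <- generate_experiment(cfg)
  expect_equal(nrow(ds$plots), 4 * cfg$n_reps)
  expect_setequal(unique(ds$plots$treatment), marsh_treatments())
  # every plot has a complete raw record: same measurement set everywhere
  per_plot <- ds$raw |>
    dplyr::group_by(plot_id) |>
    dplyr::summarise(ms = paste(sort(unique(measurement)), collapse = "|"))
  expect_equal(length(unique(per_plot$ms)), 1)
  expect_false(any(is.na(ds$raw$value)))
  expect_false(any(!is.finite(ds$functions[[3]])))
  # counts are non-negative integers; masses and concentrations non-negative
  expect_true(all(ds$series$count >= 0 & ds$series$count %% 1 == 0))
  expect_true(all(ds$birds$count >= 0 & ds$birds$count %% 1 == 0))
  expect_true(all(ds$plants$count >= 0 & ds$plants$count %% 1 == 0))
  expect_true(all(ds$tethering$n_eaten >= 0 &
    ds$tethering$n_eaten <= ds$tethering$n_placed))
  masses <- ds$raw[ds$raw$measurement %in%
    c("belowground_core_g", "macrofauna_wet_g", "litter_mass_g"), ]
  expect_true(all(masses$value >= 0))
  gyp <- tidyr::pivot_wider(
    ds$raw[grepl("^gypsum", ds$raw$measurement), c("plot_id", "measurement", "value")],
    names_from = "measurement", values_from = "value"
  )
  expect_true(all(gyp$gypsum_final_g <= gyp$gypsum_initial_g))
})

test_that("adding replicates does not shift existing plots' draws", {
  small <- generate_experiment(
    experiment_config(n_reps = 4, seed = 10),
    include = "functions"
  )$functions
  large <- generate_experiment(
    experiment_config(n_reps = 6, seed = 10),
    include = "functions"
  )$functions
  shared <- dplyr::semi_join(large, small, by = "plot_id") |>
    dplyr::arrange(plot_id)
  expect_equal(dplyr::arrange(small, plot_id), shared)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(experiment_config(n_reps = 1), "n_reps")
  expect_error(experiment_config(noise_cv = -0.1), "noise_cv")
  fe <- default_function_effects()
  fe$planting_exclusion[3] <- -2
  expect_error(experiment_config(function_effects = fe), "planting_exclusion")
  fe2 <- default_function_effects()[-1, ]
  expect_error(experiment_config(function_effects = fe2), "12 functions")
  expect_error(
    experiment_config(seasonal_bird_profile = c(1, 2, 3)),
    "seasonal_bird_profile"
  )
  cfg <- experiment_config()
  cfg$treatments <- c("a", "b", "c", "d")
  expect_error(validate_experiment_config(cfg), "canonical")
})

test_that("marginal function means converge to baseline times multiplier", {
  cfg <- experiment_config(n_reps = 400, seed = 3)
  fm <- generate_experiment(cfg, include = "functions")$functions
  fe <- default_function_effects()
  for (fn in c("sediment_accretion", "soil_respiration", "metal_reduction")) {
    base <- fe$baseline[fe$fn == fn]
    for (tr in c("planting_control", "planting_exclusion")) {
      mult <- if (tr == "planting_control") 1 else fe$planting_exclusion[fe$fn == fn]
      est <- mean(fm[[fn]][fm$treatment == tr])
      # lognormal cv 0.25, n = 400: relative MC error well under 5%
      expect_lt(abs(est / (base * mult) - 1), 0.05)
    }
  }
})

test_that("re-deriving functions from raw measurements recovers the truth", {
  ds <- generate_experiment(experiment_config(seed = 17))
  fm <- build_function_matrix(ds$raw) |> dplyr::arrange(plot_id)
  lat <- dplyr::arrange(ds$functions, plot_id)
  direct <- setdiff(
    marsh_functions(),
    c("wave_dissipation", "metal_reduction")
  )
  for (fn in direct) expect_equal(fm[[fn]], lat[[fn]], tolerance = 1e-10)
  # benefit-transformed functions are recovered up to the anchor shift the
  # transform imposes: latent minus the mean of its three smallest values
  for (fn in c("wave_dissipation", "metal_reduction")) {
    anchor <- mean(sort(lat[[fn]])[1:3])
    expect_equal(fm[[fn]], lat[[fn]] - anchor, tolerance = 1e-10)
  }
})

test_that("exclusion effect on crabs grows with seasonal bird abundance", {
  cfg <- experiment_config(seed = 29)
  ds <- generate_experiment(cfg, include = "series")
  eff <- exclusion_effect_on_crabs(ds$series)
  by_month <- eff |>
    dplyr::group_by(month) |>
    dplyr::summarise(lrr = mean(lrr))
  expect_gt(cor(by_month$lrr, cfg$seasonal_bird_profile[by_month$month]), 0.5)
  # and the pooled monthly effect is positive (exclusion releases crabs)
  pooled <- pooled_random_effects(eff$lrr, eff$var)
  expect_gt(pooled$ci_lower, 0)
})

test_that("mimic experiment decays only under the shorebird model", {
  ser <- generate_mimic_experiment(seed = 5)
  means <- ser |>
    dplyr::group_by(treatment, week) |>
    dplyr::summarise(m = mean(count), .groups = "drop")
  final <- means[means$week == max(means$week), ]
  expect_lt(final$m[final$treatment == "model"], 1)
  expect_gt(final$m[final$treatment == "control"], 5)
  expect_identical(ser, generate_mimic_experiment(seed = 5))

  # null decay: treatments indistinguishable (per-week ANOVA rarely rejects)
  withr::with_seed(61, {
    rej <- replicate(40, {
      null_ser <- generate_mimic_experiment(
        decay_rate = 0,
        seed = sample.int(1e6, 1)
      )
      mean(mimic_per_week_anova(null_ser)$p < 0.05, na.rm = TRUE)
    })
    expect_lt(mean(rej), 0.15)
  })

  # strong decay: significant from week 2 onward in nearly all runs
  withr::with_seed(62, {
    power <- replicate(100, {
      s <- generate_mimic_experiment(seed = sample.int(1e6, 1))
      aw <- mimic_per_week_anova(s)
      all(aw$p[aw$week >= 2] < 0.05)
    })
    expect_gte(mean(power), 0.95)
  })
})
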