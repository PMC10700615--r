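# Per-plot estimators for the twelve ecosystem functions, from raw field
# measurements to the values collected in the function matrix.

#' Names and partition of the twelve ecosystem functions
#'
#' `marsh_functions()` returns the canonical names (and column order) of the
#' twelve ecosystem functions. `function_partition()` returns the above- vs
#' belowground classification used for partitioned multifunctionality; note
#' that for this purpose primary production is split into its aboveground and
#' belowground biomass components, which [build_function_matrix()] emits as
#' auxiliary columns.
#'
#' @return `marsh_functions()`: character vector of length 12.
#'   `function_partition()`: named list with elements `above` (4 column names)
#'   and `below` (9 column names).
#' @export
marsh_functions <- function() {
  c(
    "primary_production", "secondary_production", "microbial_production",
    "wave_dissipation", "marsh_infiltration", "sediment_accretion",
    "soil_respiration", "n_mineralization", "litter_decomposition",
    "carbon_burial", "n_accumulation", "metal_reduction"
  )
}

#' @rdname marsh_functions
#' @export
function_partition <- function() {
  list(
    above = c(
      "aboveground_biomass", "wave_dissipation", "sediment_accretion",
      "litter_decomposition"
    ),
    below = c(
      "belowground_biomass", "secondary_production", "microbial_production",
      "marsh_infiltration", "soil_respiration", "n_mineralization",
      "carbon_burial", "n_accumulation", "metal_reduction"
    )
  )
}

# area of one soil core (m^2) for a given diameter in cm
core_area_m2 <- function(diameter_cm = 11) pi * (diameter_cm / 200)^2

#' Allometric aboveground biomass of a sedge ramet from stem height
#'
#' Dry aboveground biomass (g) of a single ramet as a power function of stem
#' height: M = a * H^b, with coefficients fitted for *Scirpus mariqueter*
#' (a = 0.0004, b = 1.72).
#'
#' @param height_cm Stem height in cm (vectorised, must be >= 0).
#' @param a,b Allometric coefficients.
#' @return Dry mass in grams, same length as `height_cm`.
#' @export
#' @examples
#' allometric_biomass(c(0, 10, 25))
allometric_biomass <- function(height_cm, a = 0.0004, b = 1.72) {
  if (any(height_cm < 0, na.rm = TRUE)) {
    stop("`height_cm` must be non-negative", call. = FALSE)
  }
  a * height_cm^b
}

#' Primary production from stem heights, density, and belowground cores
#'
#' Aboveground biomass per unit area is the allometric mass of a ramet of the
#' plot's mean stem height multiplied by ramet density; belowground biomass is
#' the mean core dry mass scaled to per-m2 by the core cross-sectional area.
#' Primary production is their sum. Plots with no plants (zero density) have a
#' zero aboveground term.
#'
#' @param stem_heights_cm Stem heights of sampled ramets (cm); may be empty
#'   when `density_per_m2` is 0.
#' @param density_per_m2 Ramet density (ramets per m2).
#' @param core_masses_g Dry *Scirpus* belowground mass of each soil core (g).
#' @param core_diameter_cm Soil-core diameter, default 11 cm.
#' @return List with `aboveground`, `belowground`, and `total` (g m-2).
#' @export
primary_production <- function(stem_heights_cm, density_per_m2, core_masses_g,
                               core_diameter_cm = 11) {
  if (length(core_masses_g) == 0) {
    stop("at least one belowground core is required", call. = FALSE)
  }
  if (density_per_m2 < 0) stop("`density_per_m2` must be >= 0", call. = FALSE)
  above <- if (density_per_m2 > 0) {
    allometric_biomass(mean(stem_heights_cm)) * density_per_m2
  } else {
    0
  }
  below <- mean(core_masses_g) / core_area_m2(core_diameter_cm)
  list(aboveground = above, belowground = below, total = above + below)
}

#' Secondary production from pooled macrofauna cores
#'
#' Wet macrofauna biomass summed over the pooled soil cores of a plot, scaled
#' to g wet biomass per m2 by the total pooled core area.
#'
#' @param macrofauna_wet_g Summed wet biomass over the pooled cores (g).
#' @param n_cores Number of pooled cores (default 3).
#' @param core_diameter_cm Core diameter, default 11 cm.
#' @return g wet biomass m-2.
#' @export
secondary_production <- function(macrofauna_wet_g, n_cores = 3,
                                 core_diameter_cm = 11) {
  if (macrofauna_wet_g < 0) stop("biomass must be >= 0", call. = FALSE)
  macrofauna_wet_g / (n_cores * core_area_m2(core_diameter_cm))
}

#' Gypsum dissolution rate
#'
#' Grams of gypsum dissolved per day over a deployment; a proxy for
#' hydrodynamic energy (faster dissolution = more wave exposure).
#'
#' @param initial_g,final_g Block masses before/after deployment (g).
#' @param days Deployment length in days (default 14).
#' @return g per day.
#' @export
gypsum_dissolution_rate <- function(initial_g, final_g, days = 14) {
  if (any(final_g > initial_g)) {
    stop("`final_g` cannot exceed `initial_g` (negative dissolution)",
      call. = FALSE
    )
  }
  (initial_g - final_g) / days
}

#' Benefit transform: reorient a cost so larger values mean greater benefit
#'
#' Converts values for which *smaller* is better (e.g. gypsum dissolution
#' rate, Nemerow pollution index) into a benefit scale via
#' `-f_i + max3(f)`, where `max3(f)` is the mean of the `top_k` (default 3)
#' largest values across all plots. The plots with the largest cost map to a
#' mean benefit of 0; the output order is the reverse of the input order.
#'
#' @param f Numeric vector of per-plot cost values (one per plot, >= 3 plots).
#' @param top_k How many of the largest values to average for the reference
#'   maximum (default 3).
#' @return Benefit values, same length as `f`.
#' @export
#' @examples
#' benefit_transform(c(1, 2, 3, 4)) # -> 2 1 0 -1
benefit_transform <- function(f, top_k = 3) {
  if (length(f) < top_k) {
    stop("need at least `top_k` (", top_k, ") plots", call. = FALSE)
  }
  ref <- mean(sort(f, decreasing = TRUE)[seq_len(top_k)])
  -f + ref
}

#' Sediment accretion rate from marker-pole readings
#'
#' Accretion is the decrease in mark-to-surface distance between the first and
#' last monthly readings, divided by the number of elapsed months; multiple
#' poles per plot are averaged.
#'
#' @param pole_marks_cm Numeric vector of monthly readings for one pole, or a
#'   list of such vectors (one per pole). Each vector needs >= 2 readings.
#' @param n_months Elapsed months between first and last reading; defaults to
#'   `length(readings) - 1` (monthly visits).
#' @return cm per month (positive = surface rising).
#' @export
sediment_accretion <- function(pole_marks_cm, n_months = NULL) {
  poles <- if (is.list(pole_marks_cm)) pole_marks_cm else list(pole_marks_cm)
  rates <- vapply(poles, function(m) {
    if (length(m) < 2) stop("need >= 2 readings per pole", call. = FALSE)
    nm <- if (is.null(n_months)) length(m) - 1 else n_months
    (m[1] - m[length(m)]) / nm
  }, numeric(1))
  mean(rates)
}

#' Net nitrogen mineralization rate
#'
#' Change in soil inorganic nitrogen over an in-situ incubation, per day.
#' Negative values indicate net immobilization.
#'
#' @param sin_t0,sin_t30 Soil inorganic N (mg kg-1) at day 0 and at the end of
#'   the incubation.
#' @param days Incubation length (default 30).
#' @return mg kg-1 day-1.
#' @export
n_mineralization <- function(sin_t0, sin_t30, days = 30) {
  (sin_t30 - sin_t0) / days
}

#' Litter decomposition rate from mass-remaining data
#'
#' Fits the exponential decay model L_t = L0 * exp(-k t) to litter mass
#' remaining at monthly retrievals. Because the initial mass placed in the
#' field is known (10 g), the intercept is fixed at log(L0) by default and k
#' is the least-squares slope of log(L_t) against t through that intercept;
#' `fixed_intercept = FALSE` frees the intercept (ordinary regression of
#' log mass on time).
#'
#' @param masses_g Litter dry masses at `times` (g). Non-positive masses are
#'   floored at `floor_g` with a warning (log undefined).
#' @param times Retrieval times in months, default `0:3`.
#' @param L0 Initial litter mass (g), default 10.
#' @param fixed_intercept Fix the intercept at `log(L0)`? Default TRUE.
#' @param floor_g Floor for non-positive masses, default 1e-6 g.
#' @return Decay constant k (mo-1), positive for mass loss.
#' @export
#' @examples
#' decomposition_rate(10 * exp(-0.2 * (0:3))) # exactly 0.2
decomposition_rate <- function(masses_g, times = seq_along(masses_g) - 1,
                               L0 = 10, fixed_intercept = TRUE,
                               floor_g = 1e-6) {
  if (length(masses_g) != length(times)) {
    stop("`masses_g` and `times` lengths differ", call. = FALSE)
  }
  if (sum(masses_g > 0) < 2 && !all(masses_g > 0)) {
    stop("need at least 2 positive masses", call. = FALSE)
  }
  if (any(masses_g <= 0)) {
    warning("non-positive litter mass floored at ", floor_g, " g")
    masses_g <- pmax(masses_g, floor_g)
  }
  y <- log(masses_g)
  if (fixed_intercept) {
    # regression through the known intercept log(L0); t = 0 contributes nothing
    -sum(times * (y - log(L0))) / sum(times^2)
  } else {
    -unname(coef(lm(y ~ times))[2])
  }
}

#' Soil bulk density from an intact core
#'
#' @param dry_mass_g Dry mass of the intact core (g).
#' @param volume_cm3 Core volume (default 100 cm3).
#' @return g cm-3.
#' @export
bulk_density <- function(dry_mass_g, volume_cm3 = 100) dry_mass_g / volume_cm3

#' Sediment carbon burial and nitrogen accumulation rates
#'
#' Carbon burial is the sediment accretion rate multiplied by soil carbon
#' density (SOC fraction times bulk density), converted to per-m2:
#' `accretion (cm/mo) * soc_pct/100 * bd (g/cm3) * 1e4 (cm2/m2)`.
#' Nitrogen accumulation uses soil total nitrogen in the same way.
#'
#' @param accretion_cm_mo Sediment accretion rate (cm mo-1).
#' @param soc_pct Soil organic carbon concentration (%).
#' @param tn_pct Soil total nitrogen concentration (%).
#' @param bd_g_cm3 Soil bulk density (g cm-3).
#' @return g C (or N) m-2 mo-1.
#' @export
#' @examples
#' carbon_burial(0.5, 1, 1) # 50 g C m-2 mo-1
carbon_burial <- function(accretion_cm_mo, soc_pct, bd_g_cm3) {
  accretion_cm_mo * (soc_pct / 100) * bd_g_cm3 * 1e4
}

#' @rdname carbon_burial
#' @export
n_accumulation <- function(accretion_cm_mo, tn_pct, bd_g_cm3) {
  carbon_burial(accretion_cm_mo, tn_pct, bd_g_cm3)
}

#' Default soil screening values for the Nemerow index
#'
#' A documented, configurable table of reference limits (mg kg-1) for the
#' seven heavy metals, in the style of agricultural soil screening standards.
#' These are package defaults for synthetic work; supply site-appropriate
#' standards for real data.
#'
#' @return Named numeric vector (cd, as, pb, zn, cr, cu, ni).
#' @export
default_metal_standards <- function() {
  c(cd = 0.3, as = 25, pb = 80, zn = 200, cr = 150, cu = 100, ni = 60)
}

#' Nemerow multifactor pollution index
#'
#' Single-factor ratios P_j = C_j / S_j of measured concentration to the
#' reference limit are combined as
#' `P = sqrt((mean(P_j)^2 + max(P_j)^2) / 2)` (classical Nemerow form).
#'
#' @param conc Named concentrations (mg kg-1) for the measured metals.
#' @param standards Named reference limits; every metal in `conc` must have a
#'   matching standard.
#' @return Unitless index (1 when every ratio is 1).
#' @export
nemerow_index <- function(conc, standards = default_metal_standards()) {
  if (is.null(names(conc)) || !all(names(conc) %in% names(standards))) {
    missing <- setdiff(names(conc), names(standards))
    stop(
      "missing standard for metal(s): ",
      paste(if (length(missing)) missing else "<unnamed>", collapse = ", "),
      call. = FALSE
    )
  }
  if (any(conc < 0) || any(standards <= 0)) {
    stop("concentrations must be >= 0 and standards > 0", call. = FALSE)
  }
  p <- conc / standards[names(conc)]
  sqrt((mean(p)^2 + max(p)^2) / 2)
}

#' Marsh infiltration rate
#'
#' Water drainage expressed in liters per hour from the time taken for a known
#' volume to infiltrate.
#'
#' @param drain_time_h Hours for the volume to drain (> 0).
#' @param volume_l Volume applied (default 1 L).
#' @return L h-1.
#' @export
marsh_infiltration <- function(drain_time_h, volume_l = 1) {
  if (any(drain_time_h <= 0)) stop("`drain_time_h` must be > 0", call. = FALSE)
  volume_l / drain_time_h
}

#' Soil respiration from replicate chamber readings
#'
#' @param readings CO2 flux readings (umol CO2 m-2 s-1), averaged per plot.
#' @return umol CO2 m-2 s-1.
#' @export
soil_respiration <- function(readings) mean(readings)

#' Build the per-plot function matrix from raw measurements
#'
#' Applies the twelve function estimators to a long-format raw measurement
#' table (see [read_plot_table()] for the schema) and returns one row per plot
#' with the twelve function columns plus the `aboveground_biomass` and
#' `belowground_biomass` components used by the above/belowground partition.
#' Wave dissipation and heavy-metal reduction are benefit-transformed across
#' all plots ([benefit_transform()]), so at least `top_k` plots are required.
#'
#' @param raw Long tibble of raw measurements with columns
#'   `plot_id, treatment, measurement, replicate, time, value`.
#' @param standards Metal reference limits for [nemerow_index()].
#' @param top_k Benefit-transform top-k (default 3).
#' @param decomp_fixed_intercept Passed to [decomposition_rate()].
#' @return Tibble: `plot_id`, `treatment`, 12 function columns (in
#'   [marsh_functions()] order) and the two biomass component columns.
#' @export
build_function_matrix <- function(raw, standards = default_metal_standards(),
                                  top_k = 3, decomp_fixed_intercept = TRUE) {
  validate_plot_table(raw)
  plots <- dplyr::distinct(raw, .data$plot_id, .data$treatment)

  val <- function(df, meas) unname(df$value[df$measurement == meas])
  one_plot <- function(df) {
    pp <- primary_production(
      stem_heights_cm = val(df, "stem_height_cm"),
      density_per_m2 = val(df, "plant_density_per_m2"),
      core_masses_g = val(df, "belowground_core_g")
    )
    poles <- df[df$measurement == "pole_mark_cm", ]
    pole_list <- lapply(
      split(poles, poles$replicate),
      function(p) p$value[order(p$time)]
    )
    metals <- df[grepl("^metal_", df$measurement), ]
    conc <- setNames(metals$value, sub("^metal_", "", metals$measurement))
    sin_ <- df[df$measurement == "soil_inorganic_n", ]
    litter <- df[df$measurement == "litter_mass_g", ]
    litter <- litter[order(litter$time), ]
    tibble::tibble(
      aboveground_biomass = pp$aboveground,
      belowground_biomass = pp$belowground,
      primary_production = pp$total,
      secondary_production = secondary_production(val(df, "macrofauna_wet_g")),
      microbial_production = val(df, "gene_copies_per_g"),
      gypsum_rate = gypsum_dissolution_rate(
        val(df, "gypsum_initial_g"), val(df, "gypsum_final_g"),
        val(df, "gypsum_days")
      ),
      marsh_infiltration = marsh_infiltration(val(df, "drain_time_h")),
      sediment_accretion = sediment_accretion(pole_list),
      soil_respiration = soil_respiration(val(df, "co2_flux")),
      n_mineralization = n_mineralization(
        sin_$value[sin_$time == 0], sin_$value[sin_$time == 30]
      ),
      litter_decomposition = decomposition_rate(
        litter$value,
        times = litter$time,
        fixed_intercept = decomp_fixed_intercept
      ),
      soc_pct = val(df, "soc_pct"),
      tn_pct = val(df, "tn_pct"),
      bd = bulk_density(val(df, "bulk_core_dry_g"), val(df, "bulk_core_cm3")),
      nemerow = nemerow_index(conc, standards)
    )
  }

  per_plot <- raw |>
    dplyr::group_by(.data$plot_id, .data$treatment) |>
    dplyr::group_modify(~ one_plot(.x)) |>
    dplyr::ungroup()

  per_plot |>
    dplyr::mutate(
      wave_dissipation = benefit_transform(.data$gypsum_rate, top_k),
      metal_reduction = benefit_transform(.data$nemerow, top_k),
      carbon_burial = carbon_burial(
        .data$sediment_accretion, .data$soc_pct, .data$bd
      ),
      n_accumulation = n_accumulation(
        .data$sediment_accretion, .data$tn_pct, .data$bd
      )
    ) |>
    dplyr::select(
      "plot_id", "treatment",
      dplyr::all_of(marsh_functions()),
      "aboveground_biomass", "belowground_biomass"
    )
}
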