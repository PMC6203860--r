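#' Define a thermal forcing scenario for one streambed site
#'
#' A thermal scenario describes a vertical lance of temperature sensors in a
#' streambed subject to a sinusoidal diurnal surface signal, conducted and
#' advected downward (or upward) through saturated sediment. The forward model
#' [simulate_temperature()] generates sensor time series from it with a known
#' vertical thermal-front velocity, so that the amplitude-ratio inversion in
#' [solve_hatch_velocity()] has recoverable ground truth.
#'
#' Depths follow the convention used throughout the package: positive
#' downward, sediment--water interface at 0 cm, so a sensor suspended in the
#' water column sits at a negative depth. The default layout mirrors a
#' field lance with one sensor above the bed and seven below, 10-minute
#' cadence and 0.04 degC resolution.
#'
#' @param velocity_v Thermal front velocity in m/day; positive values mean
#'   downwelling (surface water pushed into the bed), negative upwelling.
#' @param kappa_e Effective thermal diffusivity of the saturated sediment,
#'   m^2/day.
#' @param period_p Period of the forcing signal in days (diurnal = 1).
#' @param surface_mean,surface_amplitude Mean and amplitude (degC) of the
#'   sinusoidal surface water temperature.
#' @param sensor_depths Signed sensor depths in cm (positive downward).
#' @param noise_sd Gaussian sensor noise, degC.
#' @param cadence_min Sampling cadence in minutes; must divide one day.
#' @param duration_days Length of the record in days (>= 2).
#' @param site_id Site label carried into the generated series.
#' @param origin Timestamp (UTC) of the first observation.
#' @param seed Integer seed; together with the scenario it fully determines
#'   the simulated output.
#'
#' @return An object of class `thermal_scenario` (a named list).
#' @seealso [simulate_temperature()], [flux_profile()]
#' @export
thermal_scenario <- function(velocity_v = 0,
                             kappa_e = 0.05,
                             period_p = 1,
                             surface_mean = 15,
                             surface_amplitude = 3,
                             sensor_depths = c(-2.5, 2.5, 12.5, 17.5, 22.5,
                                               27.5, 37.5, 57.5),
                             noise_sd = 0.02,
                             cadence_min = 10,
                             duration_days = 14,
                             site_id = "site_1",
                             origin = as.POSIXct("2016-05-16 00:00:00", tz = "UTC"),
                             seed = 1L) {
  stopifnot_scalar_number(kappa_e, "kappa_e", positive = TRUE)
  stopifnot_scalar_number(period_p, "period_p", positive = TRUE)
  stopifnot_scalar_number(surface_amplitude, "surface_amplitude", nonneg = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  stopifnot_scalar_number(velocity_v, "velocity_v")
  stopifnot_scalar_number(duration_days, "duration_days")
  if (duration_days < 2) abort("`duration_days` must be at least 2.")
  if ((1440 %% cadence_min) != 0) abort("`cadence_min` must divide one day (1440 min).")
  if (anyDuplicated(sensor_depths)) abort("`sensor_depths` must be distinct.")
  structure(
    list(
      velocity_v = velocity_v, kappa_e = kappa_e, period_p = period_p,
      surface_mean = surface_mean, surface_amplitude = surface_amplitude,
      sensor_depths = sort(sensor_depths), noise_sd = noise_sd,
      cadence_min = cadence_min, duration_days = duration_days,
      site_id = site_id, origin = origin, seed = seed
    ),
    class = "thermal_scenario"
  )
}

#' @export
print.thermal_scenario <- function(x, ...) {
  cat("<thermal_scenario>", x$site_id, "\n")
  cat("  v =", x$velocity_v, "m/day, kappa_e =", x$kappa_e,
      "m^2/day, P =", x$period_p, "day\n")
  cat("  surface:", x$surface_mean, "+/-", x$surface_amplitude, "degC;",
      "noise sd", x$noise_sd, "degC\n")
  cat("  sensors (cm):", paste(x$sensor_depths, collapse = ", "), "\n")
  cat("  ", x$duration_days, "days @", x$cadence_min, "min; seed", x$seed, "\n")
  invisible(x)
}

default_taxon_pools <- function() {
  tibble::tribble(
    ~pool,       ~taxon,              ~group,         ~shape_class,       ~meanlog_l, ~sdlog_l, ~width_ratio,
    "benthic",   "Chironomidae",      "invertebrate", "cylinder",         log(1200),  0.35,     0.12,
    "benthic",   "Naididae",          "invertebrate", "cylinder",         log(1500),  0.40,     0.08,
    "benthic",   "Cyclopoida",        "invertebrate", "prolate_spheroid", log(600),   0.30,     0.30,
    "benthic",   "Ostracoda",         "invertebrate", "prolate_spheroid", log(500),   0.25,     0.55,
    "benthic",   "Hypotrichia",       "ciliate",      "prolate_spheroid", log(80),    0.30,     0.40,
    "benthic",   "Peritrichia",       "ciliate",      "prolate_spheroid", log(60),    0.30,     0.50,
    "benthic",   "Prostomatea",       "ciliate",      "sphere",           log(40),    0.25,     1.00,
    "benthic",   "Chrysomonadida",    "flagellate",   "sphere",           log(8),     0.30,     1.00,
    "benthic",   "Euglenida",         "flagellate",   "prolate_spheroid", log(15),    0.30,     0.40,
    "hyporheic", "Parastenocaris",    "invertebrate", "cylinder",         log(400),   0.30,     0.10,
    "hyporheic", "Bathynellacea",     "invertebrate", "cylinder",         log(700),   0.30,     0.15,
    "hyporheic", "Nematoda",          "invertebrate", "cylinder",         log(900),   0.40,     0.04,
    "hyporheic", "Rotifera",          "invertebrate", "prolate_spheroid", log(250),   0.30,     0.35,
    "hyporheic", "Karyorelictea",     "ciliate",      "cylinder",         log(150),   0.35,     0.15,
    "hyporheic", "Colpodea",          "ciliate",      "prolate_spheroid", log(50),    0.25,     0.55,
    "hyporheic", "Scuticociliatia",   "ciliate",      "prolate_spheroid", log(35),    0.25,     0.45,
    "hyporheic", "Choanoflagellida",  "flagellate",   "sphere",           log(6),     0.25,     1.00,
    "hyporheic", "Bodonida",          "flagellate",   "prolate_spheroid", log(10),    0.30,     0.50
  )
}

#' Define a synthetic streambed community scenario
#'
#' Describes a multi-site sampling campaign of 5-cm sediment layers (0--35 cm,
#' seven strata) repeated over weekly dates, with three taxonomic size-groups
#' (eumetazoan invertebrates, ciliates, flagellates). Expected densities decay
#' exponentially with depth at a group-specific rate, are elevated under
#' downwelling (DW) relative to upwelling (UW) conditions, and the taxonomic
#' composition switches from a benthic to a hyporheic taxon pool across a
#' logistic turnover centred on a condition-specific boundary depth. Counts
#' are Poisson around the expectation; body sizes are lognormal per taxon.
#'
#' @param n_sites Number of sites; conditions alternate UW, DW, UW, ... unless
#'   `conditions` is given.
#' @param conditions Character vector of "UW"/"DW" per site.
#' @param n_dates Number of weekly sampling dates.
#' @param n_layers Number of 5-cm strata starting at the interface.
#' @param surface_density Named numeric, expected density (ind/L) of each
#'   group in the 0--5 cm stratum of a UW site.
#' @param decay_rate Named numeric, exponential depth-decay rate per cm for
#'   each group. Steeper for larger organisms by default.
#' @param dw_multiplier Multiplier (>= 1) applied to densities under DW.
#' @param boundary_depth Named numeric `c(UW = ..., DW = ...)`: depth (cm) at
#'   which the benthic-pool mixing weight crosses 0.5.
#' @param turnover_sharpness Logistic steepness of the pool turnover, per cm.
#' @param site_effect_sd SD of a lognormal site-level density multiplier
#'   (log scale); induces the site-level intra-class correlation that the
#'   random-intercept models absorb.
#' @param date_effect_sd SD of a lognormal date-level multiplier (log scale).
#' @param sample_volume Named numeric, litres of sample examined per group
#'   (counting-chamber volumes differ by orders of magnitude across groups).
#' @param overdispersion Optional Gamma-mixing parameter; `0` (default) keeps
#'   pure Poisson counts, a positive value `k` draws negative-binomial counts
#'   with size `1/k`.
#' @param taxon_pools Data frame of taxa (see `default_taxon_pools()`): pool
#'   ("benthic"/"hyporheic"), taxon, group, shape_class, lognormal length
#'   parameters and width ratio.
#' @param start_date First sampling date.
#' @param seed Integer seed.
#'
#' @return An object of class `community_scenario`.
#' @seealso [simulate_community()], [delineate_boundary()]
#' @export
community_scenario <- function(n_sites = 6,
                               conditions = NULL,
                               n_dates = 4,
                               n_layers = 7,
                               surface_density = c(invertebrate = 400,
                                                   ciliate = 4000,
                                                   flagellate = 40000),
                               decay_rate = c(invertebrate = 0.12,
                                              ciliate = 0.08,
                                              flagellate = 0.05),
                               dw_multiplier = 2,
                               boundary_depth = c(UW = 10, DW = 15),
                               turnover_sharpness = 1.5,
                               site_effect_sd = 0.3,
                               date_effect_sd = 0.1,
                               sample_volume = c(invertebrate = 0.5,
                                                 ciliate = 0.005,
                                                 flagellate = 0.001),
                               overdispersion = 0,
                               taxon_pools = default_taxon_pools(),
                               start_date = as.Date("2016-05-16"),
                               seed = 1L) {
  if (is.null(conditions)) {
    conditions <- rep(c("UW", "DW"), length.out = n_sites)
  }
  if (length(conditions) != n_sites || !all(conditions %in% c("UW", "DW"))) {
    abort("`conditions` must be a UW/DW vector of length `n_sites`.")
  }
  groups <- c("invertebrate", "ciliate", "flagellate")
  for (nm in list(surface_density, decay_rate, sample_volume)) {
    if (!all(groups %in% names(nm))) {
      abort("`surface_density`, `decay_rate` and `sample_volume` must name all three groups.")
    }
  }
  if (any(decay_rate <= 0)) abort("decay rates must be > 0.")
  if (any(surface_density < 0)) abort("densities must be >= 0.")
  if (dw_multiplier < 1) abort("`dw_multiplier` must be >= 1.")
  if (!all(c("UW", "DW") %in% names(boundary_depth)) ||
      any(boundary_depth <= 0) || any(boundary_depth >= n_layers * 5)) {
    abort("`boundary_depth` must name UW and DW depths inside (0, 5 * n_layers).")
  }
  if (nrow(taxon_pools) == 0 ||
      !all(c("benthic", "hyporheic") %in% taxon_pools$pool)) {
    abort("`taxon_pools` must contain both a benthic and a hyporheic pool.")
  }
  structure(
    list(
      n_sites = n_sites, conditions = conditions, n_dates = n_dates,
      n_layers = n_layers, surface_density = surface_density,
      decay_rate = decay_rate, dw_multiplier = dw_multiplier,
      boundary_depth = boundary_depth, turnover_sharpness = turnover_sharpness,
      site_effect_sd = site_effect_sd, date_effect_sd = date_effect_sd,
      sample_volume = sample_volume, overdispersion = overdispersion,
      taxon_pools = taxon_pools, start_date = start_date, seed = seed
    ),
    class = "community_scenario"
  )
}

#' @export
print.community_scenario <- function(x, ...) {
  cat("<community_scenario>\n")
  cat("  ", x$n_sites, "sites (", paste(x$conditions, collapse = " "), "),",
      x$n_dates, "dates,", x$n_layers, "x 5 cm layers\n")
  cat("  boundary UW", x$boundary_depth[["UW"]], "cm / DW",
      x$boundary_depth[["DW"]], "cm, sharpness", x$turnover_sharpness, "/cm\n")
  cat("  ", nrow(x$taxon_pools), "taxa; seed", x$seed, "\n")
  invisible(x)
}

#' Benchmark scenario for boundary delineation
#'
#' A [community_scenario()] tuned for studying boundary recovery: sharp
#' compositional turnover (logistic sharpness 3 /cm) planted at 10 cm under
#' UW and 15 cm under DW, a deliberately mild density gradient (decay
#' 0.02 /cm for every group, so that composition rather than total density
#' carries the between-stratum signal), two sampling dates over six
#' alternating UW/DW sites (six replicate cores per stratum and condition),
#' and counting totals of roughly 200/40/80 individuals per sample for
#' invertebrates/ciliates/flagellates.
#'
#' @param seed Integer seed.
#' @return A `community_scenario`.
#' @export
delineation_scenario <- function(seed = 1L) {
  community_scenario(
    n_sites = 6, n_dates = 2,
    surface_density = c(invertebrate = 400, ciliate = 8000,
                        flagellate = 80000),
    decay_rate = c(invertebrate = 0.02, ciliate = 0.02, flagellate = 0.02),
    boundary_depth = c(UW = 10, DW = 15),
    turnover_sharpness = 3,
    seed = seed
  )
}
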