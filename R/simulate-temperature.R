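#' Amplitude damping and phase lag of a diurnal signal in flowing sediment
#'
#' For a sinusoidal surface temperature signal conducted and advected through
#' saturated sediment with effective diffusivity `kappa_e` (m^2/day), period
#' `period_p` (day) and thermal front velocity `v` (m/day, positive downward),
#' the amplitude at depth `z` (m) is damped by
#' \deqn{f(z) = \exp\!\left(\frac{z}{2\kappa_e}\left(v - \sqrt{\frac{\alpha + v^2}{2}}\right)\right),
#'   \qquad \alpha = \sqrt{v^4 + (8\pi\kappa_e/P)^2}.}
#' At \eqn{v = 0} this reduces to the classical conduction-only damping
#' \eqn{\exp(-z\sqrt{\pi/(\kappa_e P)})}. The matching phase lag is
#' \eqn{\phi(z) = (z/2\kappa_e)\sqrt{(\alpha - v^2)/2}} radians.
#'
#' `hatch_amplitude_factor()` is the forward counterpart of the inversion in
#' [solve_hatch_velocity()]; the two are exactly consistent, which is what
#' makes round-trip recovery tests meaningful.
#'
#' @param z_m Depth below the interface in metres (vectorised).
#' @param v Thermal front velocity, m/day.
#' @param kappa_e Effective thermal diffusivity, m^2/day.
#' @param period_p Forcing period, day.
#' @return Dimensionless damping factor in (0, 1], or phase lag in radians.
#' @export
hatch_amplitude_factor <- function(z_m, v, kappa_e, period_p = 1) {
  stopifnot_scalar_number(kappa_e, "kappa_e", positive = TRUE)
  stopifnot_scalar_number(period_p, "period_p", positive = TRUE)
  alpha <- sqrt(v^4 + (8 * pi * kappa_e / period_p)^2)
  exp((z_m / (2 * kappa_e)) * (v - sqrt((alpha + v^2) / 2)))
}

#' @rdname hatch_amplitude_factor
#' @export
stallman_phase_lag <- function(z_m, v, kappa_e, period_p = 1) {
  stopifnot_scalar_number(kappa_e, "kappa_e", positive = TRUE)
  stopifnot_scalar_number(period_p, "period_p", positive = TRUE)
  alpha <- sqrt(v^4 + (8 * pi * kappa_e / period_p)^2)
  (z_m / (2 * kappa_e)) * sqrt((alpha - v^2) / 2)
}

#' Simulate streambed temperature sensor series with known vertical flux
#'
#' Forward-simulates the diurnal temperature signal at every sensor of a
#' [thermal_scenario()]: a sinusoid of known mean and amplitude at the
#' surface, damped and phase-lagged with depth according to the
#' conduction--advection solution (see [hatch_amplitude_factor()]), plus iid
#' Gaussian sensor noise. Sensors above the sediment--water interface
#' (negative depth) record the undamped surface signal.
#'
#' @param scenario A [thermal_scenario()].
#' @return A tibble with columns `site_id`, `depth_cm`, `timestamp` (POSIXct,
#'   UTC), `temp_c` -- one regular series per sensor, the sensor-log layout
#'   accepted by [fit_diurnal_harmonic()] and written by [write_sensor_log()].
#' @examples
#' sc <- thermal_scenario(velocity_v = 0.3, duration_days = 3, noise_sd = 0)
#' sim <- simulate_temperature(sc)
#' dplyr::count(sim, depth_cm)
#' @export
simulate_temperature <- function(scenario) {
  if (!inherits(scenario, "thermal_scenario")) {
    abort("`scenario` must be a thermal_scenario.")
  }
  sc <- scenario
  n_per_day <- 1440L %/% sc$cadence_min
  n_t <- as.integer(round(sc$duration_days * n_per_day))
  t_days <- (seq_len(n_t) - 1L) / n_per_day
  omega <- 2 * pi / sc$period_p
  z_m <- pmax(sc$sensor_depths, 0) / 100  # above-bed sensors: undamped
  damp <- hatch_amplitude_factor(z_m, sc$velocity_v, sc$kappa_e, sc$period_p)
  lag <- stallman_phase_lag(z_m, sc$velocity_v, sc$kappa_e, sc$period_p)

  with_seed(sc$seed, {
    out <- purrr::map2_dfr(seq_along(sc$sensor_depths), sc$sensor_depths,
      function(i, z) {
        temp <- sc$surface_mean +
          sc$surface_amplitude * damp[i] * cos(omega * t_days - lag[i])
        if (sc$noise_sd > 0) temp <- temp + rnorm(n_t, sd = sc$noise_sd)
        tibble::tibble(
          site_id = sc$site_id,
          depth_cm = z,
          timestamp = sc$origin + t_days * 86400,
          temp_c = temp
        )
      })
    out
  })
}
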