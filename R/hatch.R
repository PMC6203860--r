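#' Invert an amplitude ratio for vertical thermal-front velocity
#'
#' Solves the one-dimensional conduction--advection amplitude relation for
#' the vertical thermal front velocity \eqn{v} given the ratio
#' \eqn{A_r = A_{lower}/A_{upper}} of diurnal amplitudes at two sensors
#' separated by `dz_m` metres (the Hatch amplitude method):
#' \deqn{\ln A_r = \frac{\Delta z}{2\kappa_e}\left(v - \sqrt{\frac{\alpha + v^2}{2}}\right),
#'   \qquad \alpha = \sqrt{v^4 + (8\pi\kappa_e/P)^2}.}
#' The right-hand side is strictly increasing in \eqn{v}, so the root is
#' found by bracketed root-finding on \eqn{v \in [-10, 10]} m/day to a
#' residual below 1e-10. Positive \eqn{v} means downwelling. The Darcy flux
#' is \eqn{q = \gamma v}, with \eqn{\gamma} the ratio of volumetric heat
#' capacity of the saturated medium to that of water.
#'
#' @param ar Amplitude ratio in (0, 1).
#' @param dz_m Vertical sensor separation, metres (> 0).
#' @param kappa_e Effective thermal diffusivity, m^2/day.
#' @param period_p Forcing period, day.
#' @param gamma Heat-capacity ratio converting thermal front velocity to
#'   Darcy flux (default 1: report the thermal front velocity itself).
#' @param bracket Search interval for `v`, m/day.
#' @return A list with `velocity` (m/day), `darcy_flux` (m/day) and
#'   `converged`.
#' @examples
#' # conduction-only ratio must invert to v = 0
#' ar0 <- exp(-0.1 * sqrt(pi / (0.05 * 1)))
#' solve_hatch_velocity(ar0, dz_m = 0.1, kappa_e = 0.05)$velocity
#' @export
solve_hatch_velocity <- function(ar, dz_m, kappa_e = 0.05, period_p = 1,
                                 gamma = 1, bracket = c(-10, 10)) {
  stopifnot_scalar_number(dz_m, "dz_m", positive = TRUE)
  stopifnot_scalar_number(kappa_e, "kappa_e", positive = TRUE)
  stopifnot_scalar_number(period_p, "period_p", positive = TRUE)
  if (!is.finite(ar) || ar <= 0 || ar >= 1) {
    abort("`ar` must lie strictly between 0 and 1 for a finite solution.")
  }
  g <- function(v) {
    alpha <- sqrt(v^4 + (8 * pi * kappa_e / period_p)^2)
    log(ar) - (dz_m / (2 * kappa_e)) * (v - sqrt((alpha + v^2) / 2))
  }
  glo <- g(bracket[1]); ghi <- g(bracket[2])
  if (!is.finite(glo) || !is.finite(ghi) || sign(glo) == sign(ghi)) {
    abort(sprintf(
      "no sign change in bracket [%g, %g]: g = (%g, %g); Ar = %g, dz = %g m",
      bracket[1], bracket[2], glo, ghi, ar, dz_m))
  }
  root <- uniroot(g, bracket, tol = .Machine$double.eps^0.75)
  v <- root$root
  list(velocity = v, darcy_flux = gamma * v,
       converged = abs(g(v)) < 1e-10)
}

#' Per-pair vertical flux estimates from harmonic amplitude profiles
#'
#' For every adjacent pair of sub-surface sensors (depth >= 0) in every daily
#' window, computes the amplitude ratio `Ar = A_lower / A_upper` and inverts
#' it with [solve_hatch_velocity()]. Pairs where either amplitude falls below
#' the detectability threshold, or where `Ar` does not lie in (0, 1), are
#' flagged `converged = FALSE` and excluded from site means downstream:
#' ratios of amplitudes at or below sensor resolution are noise-dominated.
#'
#' @param fits Harmonic-fit tibble from [fit_diurnal_harmonic()].
#' @param kappa_e,period_p,gamma Thermal parameters, see
#'   [solve_hatch_velocity()].
#' @param amp_threshold Minimum usable amplitude, degC (default the 0.04
#'   sensor resolution).
#' @return A tibble with one row per (site, window, sensor pair): `site_id`,
#'   `window_start`, `upper_z`, `lower_z` (cm), `amplitude_ratio`,
#'   `velocity` (m/day), `darcy_flux`, `converged`.
#' @export
flux_profile <- function(fits, kappa_e = 0.05, period_p = 1, gamma = 1,
                         amp_threshold = 0.04) {
  sub <- dplyr::filter(fits, .data$depth_cm >= 0)
  if (length(unique(sub$depth_cm)) < 2) {
    abort("need harmonic fits at >= 2 sub-surface depths.")
  }
  sub <- dplyr::arrange(sub, .data$site_id, .data$window_start, .data$depth_cm)
  grp <- dplyr::group_by(sub, .data$site_id, .data$window_start)
  pairs <- dplyr::reframe(
    grp,
    upper_z = .data$depth_cm[-dplyr::n()],
    lower_z = .data$depth_cm[-1],
    a_upper = .data$amplitude[-dplyr::n()],
    a_lower = .data$amplitude[-1]
  )
  pairs$amplitude_ratio <- pairs$a_lower / pairs$a_upper
  usable <- pairs$a_upper >= amp_threshold & pairs$a_lower >= amp_threshold &
    is.finite(pairs$amplitude_ratio) &
    pairs$amplitude_ratio > 0 & pairs$amplitude_ratio < 1

  vel <- rep(NA_real_, nrow(pairs))
  conv <- logical(nrow(pairs))
  for (i in which(usable)) {
    sol <- tryCatch(
      solve_hatch_velocity(pairs$amplitude_ratio[i],
                           dz_m = (pairs$lower_z[i] - pairs$upper_z[i]) / 100,
                           kappa_e = kappa_e, period_p = period_p,
                           gamma = gamma),
      error = function(e) NULL
    )
    if (!is.null(sol) && sol$converged) {
      vel[i] <- sol$velocity
      conv[i] <- TRUE
    }
  }
  tibble::tibble(
    site_id = pairs$site_id,
    window_start = pairs$window_start,
    upper_z = pairs$upper_z,
    lower_z = pairs$lower_z,
    amplitude_ratio = pairs$amplitude_ratio,
    velocity = vel,
    darcy_flux = gamma * vel,
    converged = conv
  )
}

#' Classify sites as upwelling or downwelling
#'
#' Averages converged pair-level velocities over sensor pairs and daily
#' windows per site and applies the sign convention: positive mean velocity
#' means downward flux (DW, surface water entering the bed), negative means
#' upward flux (UW, groundwater discharging). Means within `tol` of zero are
#' labelled indeterminate.
#'
#' @param flux Flux tibble from [flux_profile()].
#' @param tol Classification dead band, m/day.
#' @return A tibble: `site_id`, `mean_velocity`, `n_estimates`, `condition`
#'   ("UW", "DW" or "indeterminate").
#' @export
classify_sites <- function(flux, tol = 0.01) {
  conv <- dplyr::filter(flux, .data$converged)
  if (nrow(conv) == 0) abort("no converged flux estimates to classify.")
  out <- dplyr::summarise(
    dplyr::group_by(conv, .data$site_id),
    mean_velocity = mean(.data$velocity),
    n_estimates = dplyr::n(),
    .groups = "drop"
  )
  out$condition <- dplyr::case_when(
    out$mean_velocity > tol ~ "DW",
    out$mean_velocity < -tol ~ "UW",
    TRUE ~ "indeterminate"
  )
  out
}
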