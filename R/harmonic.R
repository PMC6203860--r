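#' Fit daily harmonics to temperature sensor series
#'
#' Splits each (site, depth) series into calendar-day windows and fits the
#' first diurnal harmonic by ordinary least squares,
#' \deqn{T(t) = m + a\cos(\omega t) + b\sin(\omega t), \qquad \omega = 2\pi/\text{day},}
#' reporting the daily amplitude \eqn{A = \sqrt{a^2+b^2}}, phase
#' \eqn{\mathrm{atan2}(-b, a)} and RMSE per window. Amplitude profiles feed
#' the extinction-depth scan and the amplitude-ratio flux inversion.
#'
#' Windows shorter than `min_obs` observations are dropped; the function
#' errors if a series has fewer than 3 distinct timestamps.
#'
#' @param data Sensor-log tibble with columns `site_id`, `depth_cm`,
#'   `timestamp` (POSIXct), `temp_c` (e.g. from [simulate_temperature()] or
#'   [read_sensor_log()]).
#' @param min_obs Minimum observations per daily window (default 24).
#' @return A tibble of harmonic fits: `site_id`, `depth_cm`, `window_start`
#'   (Date), `mean_t`, `amplitude`, `phase` (radians in `[-pi, pi)`),
#'   `rmse`, `n_obs`.
#' @examples
#' sim <- simulate_temperature(thermal_scenario(duration_days = 2, noise_sd = 0))
#' fit_diurnal_harmonic(sim)
#' @export
fit_diurnal_harmonic <- function(data, min_obs = 24) {
  req <- c("site_id", "depth_cm", "timestamp", "temp_c")
  if (!all(req %in% names(data))) {
    abort(paste("`data` must have columns:", paste(req, collapse = ", ")))
  }
  if (length(unique(data$timestamp)) < 3) {
    abort("insufficient data: need at least 3 distinct timestamps.")
  }
  day <- as.Date(data$timestamp, tz = "UTC")
  frac <- as.numeric(data$timestamp) %% 86400 / 86400  # day fraction, UTC
  omega_t <- 2 * pi * frac
  key <- paste(data$site_id, data$depth_cm, day, sep = "\r")
  idx <- split(seq_len(nrow(data)), key)

  fits <- purrr::map(idx, function(i) {
    if (length(i) < min_obs) return(NULL)
    x <- cbind(1, cos(omega_t[i]), sin(omega_t[i]))
    fit <- stats::.lm.fit(x, data$temp_c[i])
    cf <- fit$coefficients
    amp <- sqrt(cf[2]^2 + cf[3]^2)
    ph <- atan2(-cf[3], cf[2])
    if (ph >= pi) ph <- ph - 2 * pi
    tibble::tibble(
      site_id = data$site_id[i[1]],
      depth_cm = data$depth_cm[i[1]],
      window_start = day[i[1]],
      mean_t = cf[1],
      amplitude = amp,
      phase = ph,
      rmse = sqrt(mean(fit$residuals^2)),
      n_obs = length(i)
    )
  })
  out <- dplyr::bind_rows(fits)
  dplyr::arrange(out, .data$site_id, .data$depth_cm, .data$window_start)
}

#' Thermal extinction depth from an amplitude profile
#'
#' The thermal extinction depth is the depth at which the diurnal temperature
#' amplitude becomes undetectable, i.e. falls below the sensor resolution
#' (0.04 degC by default). Window-level amplitudes are averaged per depth;
#' scanning downward, the extinction interval is the pair of adjacent sensor
#' depths bracketing the first crossing below the threshold. If no sensor
#' drops below the threshold the signal penetrates deeper than the deepest
#' sensor and no interval is returned.
#'
#' @param fits Harmonic-fit tibble from [fit_diurnal_harmonic()] (one or more
#'   sites).
#' @param threshold Amplitude detectability threshold, degC.
#' @return A tibble with one row per site: `site_id`, `upper_z`, `lower_z`
#'   (cm; both `NA` when the signal never extinguishes within the profile).
#' @export
thermal_extinction_depth <- function(fits, threshold = 0.04) {
  if (nrow(fits) == 0) abort("empty fit table.")
  prof <- dplyr::summarise(
    dplyr::group_by(fits, .data$site_id, .data$depth_cm),
    amplitude = mean(.data$amplitude),
    .groups = "drop"
  )
  purrr::map_dfr(split(prof, prof$site_id), function(p) {
    p <- dplyr::arrange(p, .data$depth_cm)
    if (nrow(p) < 2) abort("need fits at >= 2 depths per site.")
    if (anyDuplicated(p$depth_cm)) abort("duplicate depths in profile.")
    below <- which(p$amplitude < threshold)
    if (length(below) == 0) {
      tibble::tibble(site_id = p$site_id[1], upper_z = NA_real_,
                     lower_z = NA_real_)
    } else {
      k <- below[1]
      if (k == 1) {
        # already extinct at the shallowest sensor
        tibble::tibble(site_id = p$site_id[1], upper_z = NA_real_,
                       lower_z = p$depth_cm[1])
      } else {
        tibble::tibble(site_id = p$site_id[1], upper_z = p$depth_cm[k - 1],
                       lower_z = p$depth_cm[k])
      }
    }
  })
}
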