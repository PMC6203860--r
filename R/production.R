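#' Turnover-rate parameters
#'
#' Per-group parameters for the daily biomass turnover rate `r`. Two modes
#' are supported. The allometric mode treats `r` as the intrinsic rate of
#' population increase scaling with body mass,
#' \deqn{r = a \cdot f(T) \cdot M^{b},}
#' with the intercept `a` (per day, at reference temperature `t0_k`)
#' temperature-corrected by the Arrhenius factor [temperature_correction()]
#' and body mass `M` in pg C. The growth-equation mode evaluates a per-taxon
#' log-linear daily-growth equation
#' \eqn{r = \exp(c_0 + c_1 \ln M) f(T)} (instantaneous growth method),
#' intended for insect larvae and other temporary meiofauna with published
#' growth equations.
#'
#' The shipped intercepts and exponents are plausible placeholders spanning
#' the published ranges for protozoa and permanent meiofauna; they are
#' configuration, not measured constants, and should be replaced with
#' taxon-specific published coefficients for real analyses.
#'
#' @param groups Named list; one entry per group with elements `mode`
#'   ("allometric" or "growth_equation"), `a` (per day at `t0_k`), `b`
#'   (dimensionless, typically negative).
#' @param growth_coefficients Optional data frame (`taxon`, `c0`, `c1`) for
#'   growth-equation taxa.
#' @param activation_energy_e Arrhenius activation energy, eV.
#' @param boltzmann_k Boltzmann constant, eV/K.
#' @param t0_k Reference temperature, K.
#' @return A list of class `turnover_params`.
#' @export
turnover_params <- function(groups = list(
                              invertebrate = list(mode = "allometric",
                                                  a = 0.3, b = -0.25),
                              ciliate = list(mode = "allometric",
                                             a = 0.6, b = -0.25),
                              flagellate = list(mode = "allometric",
                                                a = 1.0, b = -0.25)),
                            growth_coefficients = NULL,
                            activation_energy_e = 0.63,
                            boltzmann_k = 8.617e-5,
                            t0_k = 288.15) {
  for (g in names(groups)) {
    if (!groups[[g]]$mode %in% c("allometric", "growth_equation")) {
      abort(sprintf("group '%s': unknown turnover mode.", g))
    }
    if (groups[[g]]$mode == "allometric" && groups[[g]]$a <= 0) {
      abort(sprintf("group '%s': allometric intercept must be > 0.", g))
    }
  }
  if (activation_energy_e <= 0) abort("activation energy must be > 0.")
  structure(list(groups = groups,
                 growth_coefficients = growth_coefficients,
                 activation_energy_e = activation_energy_e,
                 boltzmann_k = boltzmann_k, t0_k = t0_k),
            class = "turnover_params")
}

#' Arrhenius temperature correction factor
#'
#' Metabolic-theory correction applied multiplicatively to the allometric
#' turnover intercept:
#' \deqn{f(T) = \exp\!\left(\frac{E}{k}\left(\frac{1}{T_0} - \frac{1}{T}\right)\right),}
#' equal to 1 at the reference temperature and increasing in `T`.
#' Temperatures outside the biologically sensible range (263--323 K) trigger
#' a warning but are still evaluated.
#'
#' @param temp_k Absolute temperature, K (vectorised).
#' @param params A [turnover_params()] list (supplies E, k, T0).
#' @return Dimensionless correction factor.
#' @examples
#' temperature_correction(288.15)  # 1 at the reference temperature
#' temperature_correction(293.15)  # about 1.54 with E = 0.63 eV
#' @export
temperature_correction <- function(temp_k, params = turnover_params()) {
  if (any(temp_k <= 263 | temp_k >= 323)) {
    warn("temperature outside (263, 323) K; correction still computed.")
  }
  exp((params$activation_energy_e / params$boltzmann_k) *
        (1 / params$t0_k - 1 / temp_k))
}

#' Daily biomass turnover rate
#'
#' @param mass Body mass per individual (pg C for the shipped allometric
#'   defaults; the allometry itself is unit-agnostic given matching
#'   intercepts).
#' @param group Group name(s), matched against `params$groups`.
#' @param temp_k Temperature, K (vectorised).
#' @param params A [turnover_params()] list.
#' @param taxon Optional taxon name(s), needed for growth-equation groups.
#' @return Turnover rate, per day.
#' @examples
#' p <- turnover_params(groups = list(x = list(mode = "allometric",
#'                                             a = 0.5, b = -0.25)))
#' turnover_rate(16, "x", 288.15, p)  # 0.5 * 16^-0.25 = 0.25
#' @export
turnover_rate <- function(mass, group, temp_k, params = turnover_params(),
                          taxon = NULL) {
  if (any(mass <= 0)) abort("`mass` must be > 0.")
  missing_g <- setdiff(unique(group), names(params$groups))
  if (length(missing_g) > 0) {
    abort(paste("no turnover coefficients for group:",
                paste(missing_g, collapse = ", ")))
  }
  ft <- temperature_correction(temp_k, params)
  n <- max(length(mass), length(group), length(temp_k))
  mass <- rep_len(mass, n); group <- rep_len(group, n); ft <- rep_len(ft, n)
  r <- numeric(n)
  for (g in unique(group)) {
    gi <- group == g
    cfg <- params$groups[[g]]
    if (cfg$mode == "allometric") {
      r[gi] <- cfg$a * ft[gi] * mass[gi]^cfg$b
    } else {
      if (is.null(params$growth_coefficients) || is.null(taxon)) {
        abort(sprintf("group '%s' uses growth equations but no coefficient table/taxon given.", g))
      }
      tx <- rep_len(taxon, n)[gi]
      cf <- params$growth_coefficients
      idx <- match(tx, cf$taxon)
      if (anyNA(idx)) {
        abort(paste("missing growth coefficients for taxon:",
                    paste(unique(tx[is.na(idx)]), collapse = ", ")))
      }
      r[gi] <- exp(cf$c0[idx] + cf$c1[idx] * log(mass[gi])) * ft[gi]
    }
  }
  if (any(r < 0)) abort("negative turnover rate computed; check coefficients.")
  r
}

#' Interval and total secondary production (non-cohort method)
#'
#' Implements the non-cohort production estimate: for each key (site, layer,
#' group by default) and each interval between consecutive sampling dates,
#' \deqn{P_i = \hat{B} \times r \times \Delta t,}
#' where \eqn{\hat{B}} is the arithmetic mean of the biomass at the interval
#' endpoints (mg C/L), `r` the daily turnover rate evaluated at the interval
#' temperature and mean body mass, and \eqn{\Delta t} the interval length in
#' days (7 for weekly sampling). Total production over the campaign is the
#' sum of interval production, \eqn{P_t = \sum_i P_i} (mg C/L per month for
#' four weekly dates, i.e. three intervals).
#'
#' @param biomass Tibble from [biomass_concentration()].
#' @param temperatures Optional tibble (`site`, `layer`, `temp_c`) or
#'   (`site`, `layer`, `interval`, `temp_c`) giving the sediment temperature
#'   per layer (e.g. from [layer_temperatures()]); defaults to the reference
#'   temperature (correction factor 1) when absent.
#' @param params A [turnover_params()] list.
#' @param dt_days Interval duration in days.
#' @param by Aggregation key for production: "group" (default) sums taxa
#'   within group first, "taxon" keeps taxa separate.
#' @return A tibble with one row per key and interval: `b_hat` (mg C/L),
#'   `mass_pg`, `temp_k`, `r_per_day`, `p_interval` (mg C/L), plus the key's
#'   total `p_total` (mg C/L month) repeated on each row.
#' @export
production <- function(biomass, temperatures = NULL,
                       params = turnover_params(), dt_days = 7,
                       by = c("group", "taxon")) {
  by <- match.arg(by)
  keys <- c("site", "condition", "layer", "depth_mid_cm", "group",
            if (by == "taxon") "taxon")
  b <- dplyr::summarise(
    dplyr::group_by(biomass, dplyr::across(dplyr::all_of(c(keys, "date")))),
    ind_carbon_pg = ifelse(sum(.data$abundance_l) > 0,
                           sum(.data$ind_carbon_pg * .data$abundance_l) /
                             sum(.data$abundance_l),
                           mean(.data$ind_carbon_pg)),
    biomass_mg_l = sum(.data$biomass_mg_l),
    .groups = "drop"
  )
  b <- dplyr::arrange(b, dplyr::across(dplyr::all_of(c(keys, "date"))))
  grp <- dplyr::group_by(b, dplyr::across(dplyr::all_of(keys)))
  if (any(dplyr::group_size(grp) < 2)) {
    abort("need >= 2 sampling dates per key to form production intervals.")
  }
  iv <- dplyr::reframe(
    grp,
    interval = seq_len(dplyr::n() - 1L),
    date_start = .data$date[-dplyr::n()],
    b_hat = (.data$biomass_mg_l[-dplyr::n()] + .data$biomass_mg_l[-1]) / 2,
    mass_pg = (.data$ind_carbon_pg[-dplyr::n()] + .data$ind_carbon_pg[-1]) / 2
  )
  # interval temperature: nearest-layer sensor mean, else reference T
  if (!is.null(temperatures)) {
    tkey <- intersect(c("site", "layer", "interval"), names(temperatures))
    iv <- dplyr::left_join(iv, temperatures, by = tkey)
    iv$temp_k <- ifelse(is.na(iv$temp_c), params$t0_k, iv$temp_c + 273.15)
  } else {
    iv$temp_k <- params$t0_k
  }
  iv$r_per_day <- ifelse(
    iv$b_hat > 0 & iv$mass_pg > 0,
    turnover_rate(pmax(iv$mass_pg, .Machine$double.eps), iv$group, iv$temp_k,
                  params),
    0
  )
  iv$p_interval <- iv$b_hat * iv$r_per_day * dt_days
  tot <- dplyr::mutate(
    dplyr::group_by(iv, dplyr::across(dplyr::all_of(keys))),
    p_total = sum(.data$p_interval)
  )
  dplyr::ungroup(tot)
}

#' Layer temperatures from harmonic fits
#'
#' Maps each 5-cm stratum midpoint to the nearest sensor depth and averages
#' that sensor's fitted daily mean temperature over the requested windows,
#' giving the per-layer sediment temperature used to temperature-correct
#' turnover rates along the depth gradient.
#'
#' @param fits Harmonic-fit tibble from [fit_diurnal_harmonic()].
#' @param n_layers Number of 5-cm strata.
#' @param site_map Optional named vector translating sensor-log `site_id`
#'   to the count-table `site` key (defaults to identity).
#' @return A tibble (`site`, `layer`, `temp_c`).
#' @export
layer_temperatures <- function(fits, n_layers = 7, site_map = NULL) {
  prof <- dplyr::summarise(
    dplyr::group_by(fits, .data$site_id, .data$depth_cm),
    temp_c = mean(.data$mean_t),
    .groups = "drop"
  )
  prof <- dplyr::filter(prof, .data$depth_cm >= 0)
  mids <- (seq_len(n_layers) - 1L) * 5 + 2.5
  out <- purrr::map_dfr(split(prof, prof$site_id), function(p) {
    idx <- vapply(mids, function(z) which.min(abs(p$depth_cm - z)), 1L)
    tibble::tibble(site_id = p$site_id[1], layer = seq_len(n_layers) - 1L,
                   temp_c = p$temp_c[idx])
  })
  if (!is.null(site_map)) {
    out$site <- unname(site_map[out$site_id])
  } else {
    out$site <- out$site_id
  }
  out[, c("site", "layer", "temp_c")]
}
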