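# Small scenario builders shared across test files.

quick_thermal <- function(v = 0.3, noise = 0, days = 3, seed = 1,
                          depths = c(2.5, 7.5, 12.5, 17.5, 22.5, 27.5, 32.5)) {
  thermal_scenario(velocity_v = v, noise_sd = noise, duration_days = days,
                   sensor_depths = depths, seed = seed)
}

quick_community <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_sites = 2, n_dates = 2, seed = seed), list(...))
  do.call(community_scenario, args)
}

# one-day sensor tibble from an explicit signal function of day-fraction
one_day_series <- function(f, n = 144, site = "s", depth = 2.5) {
  frac <- (seq_len(n) - 1) / n
  tibble::tibble(
    site_id = site, depth_cm = depth,
    timestamp = as.POSIXct("2020-06-01", tz = "UTC") + frac * 86400,
    temp_c = f(frac)
  )
}

# small worked measurement table used by the production worksheet oracle
worksheet_measurements <- function() {
  tibble::tibble(
    site = 1, condition = "UW",
    date = rep(as.Date("2020-06-01") + c(0, 7), each = 2),
    layer = 0L, depth_mid_cm = 2.5,
    taxon = "TaxonA", group = rep(c("ciliate", "ciliate"), 2),
    shape_class = "prolate_spheroid",
    length_um = 50, width_um = 20,
    count = c(4, 6, 2, 2), sample_volume_l = 0.01
  )
}
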