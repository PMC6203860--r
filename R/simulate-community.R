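#' Benthic-pool mixing weight along depth
#'
#' Logistic weight of the benthic taxon pool at depth `z_cm`:
#' `1 / (1 + exp(sharpness * (z - boundary)))`. Equals 0.5 exactly at the
#' boundary depth and decays toward 0 below it, where the hyporheic pool
#' takes over.
#'
#' @param z_cm Depth (cm, positive downward), vectorised.
#' @param boundary_cm Turnover midpoint depth (cm).
#' @param sharpness Logistic steepness per cm.
#' @return Weight in (0, 1).
#' @export
benthic_weight <- function(z_cm, boundary_cm, sharpness) {
  1 / (1 + exp(sharpness * (z_cm - boundary_cm)))
}

#' Simulate layered streambed community count tables
#'
#' Draws organism count/measurement tables for every (site, date, layer) of a
#' [community_scenario()]. The expected density of group \eqn{g} at stratum
#' midpoint \eqn{z} under condition \eqn{c} is
#' \deqn{N_{0g}\, e^{-\lambda_g z}\, m_c\, s_{site}\, d_{date},}
#' with \eqn{m_{DW}} the downwelling multiplier and lognormal site and date
#' multipliers. The density is split between the benthic and hyporheic taxon
#' pools by the logistic weight [benthic_weight()] (equal shares within a
#' pool-by-group cell), counts are Poisson (optionally negative-binomial)
#' around expectation times the group's examined volume, and each record
#' carries a lognormal body length and proportional width.
#'
#' @param scenario A [community_scenario()].
#' @return A tibble in the organism-measurement layout: `site`, `condition`,
#'   `date`, `layer` (0-based stratum index), `depth_mid_cm`, `taxon`,
#'   `group`, `shape_class`, `length_um`, `width_um`, `count`,
#'   `sample_volume_l`, `abundance_l` (= count / volume, ind/L).
#' @examples
#' sc <- community_scenario(n_sites = 2, n_dates = 2, seed = 7)
#' comm <- simulate_community(sc)
#' dplyr::count(comm, condition, layer, wt = abundance_l)
#' @export
simulate_community <- function(scenario) {
  if (!inherits(scenario, "community_scenario")) {
    abort("`scenario` must be a community_scenario.")
  }
  sc <- scenario
  pools <- sc$taxon_pools
  if (nrow(pools) == 0) abort("empty taxon pool.")
  # equal share of the pool-by-group expectation for each taxon in the cell
  pools <- dplyr::mutate(
    dplyr::group_by(pools, .data$pool, .data$group),
    share = 1 / dplyr::n()
  )
  pools <- dplyr::ungroup(pools)

  grid <- tidyr::expand_grid(
    site = seq_len(sc$n_sites),
    date_idx = seq_len(sc$n_dates),
    layer = seq_len(sc$n_layers) - 1L
  )
  grid$condition <- sc$conditions[grid$site]
  grid$depth_mid_cm <- grid$layer * 5 + 2.5

  with_seed(sc$seed, {
    site_mult <- exp(rnorm(sc$n_sites, 0, sc$site_effect_sd))
    date_mult <- exp(rnorm(sc$n_sites * sc$n_dates, 0, sc$date_effect_sd))
    dim(date_mult) <- c(sc$n_sites, sc$n_dates)

    rows <- tidyr::expand_grid(grid, pools)
    w_b <- benthic_weight(rows$depth_mid_cm,
                          sc$boundary_depth[rows$condition],
                          sc$turnover_sharpness)
    pool_w <- ifelse(rows$pool == "benthic", w_b, 1 - w_b)
    lambda_g <- sc$decay_rate[rows$group]
    n0_g <- sc$surface_density[rows$group]
    cond_mult <- ifelse(rows$condition == "DW", sc$dw_multiplier, 1)
    density <- n0_g * exp(-lambda_g * rows$depth_mid_cm) * cond_mult *
      site_mult[rows$site] * date_mult[cbind(rows$site, rows$date_idx)] *
      pool_w * rows$share
    vol <- sc$sample_volume[rows$group]
    mu <- density * vol
    count <- if (sc$overdispersion > 0) {
      stats::rnbinom(length(mu), size = 1 / sc$overdispersion, mu = mu)
    } else {
      rpois(length(mu), mu)
    }
    len <- rlnorm(length(mu), rows$meanlog_l, rows$sdlog_l)
    wid <- pmin(len, len * rows$width_ratio)

    tibble::tibble(
      site = rows$site,
      condition = rows$condition,
      date = sc$start_date + 7 * (rows$date_idx - 1L),
      layer = rows$layer,
      depth_mid_cm = rows$depth_mid_cm,
      taxon = rows$taxon,
      group = rows$group,
      shape_class = rows$shape_class,
      length_um = len,
      width_um = wid,
      count = count,
      sample_volume_l = vol,
      abundance_l = count / vol
    )
  })
}

#' Expected group density surface of a community scenario
#'
#' Deterministic expectation (ind/L, before site/date multipliers) used by the
#' simulator; exposed for tests and plots.
#'
#' @inheritParams simulate_community
#' @param group Group name.
#' @param z_cm Depth(s), cm.
#' @param condition "UW" or "DW".
#' @return Expected density, ind/L.
#' @export
expected_density <- function(scenario, group, z_cm, condition) {
  sc <- scenario
  m <- if (condition == "DW") sc$dw_multiplier else 1
  sc$surface_density[[group]] * exp(-sc$decay_rate[[group]] * z_cm) * m
}

#' Simulate a tidy analysis table from a known mixed model
#'
#' Draws a response (log10 biomass scale by default) directly from a Gaussian
#' random-intercept linear mixed model over the standard design: sites x
#' 5-cm layers x groups x dates, UW/DW alternating across sites. This gives
#' the model-fitting machinery transparent ground truth: the true fixed
#' effects are returned alongside the data.
#'
#' The default effect sizes mirror the qualitative field pattern: biomass
#' falls with depth (negative depth slope per cm), is higher under
#' downwelling, and the decline is steepest for invertebrates, intermediate
#' for ciliates and shallowest for flagellates (group-specific depth slopes).
#'
#' @param n_sites,n_layers,n_groups,n_dates Design dimensions.
#' @param beta_depth Depth slope per cm for the reference group (flagellate).
#' @param beta_dw Downwelling main effect.
#' @param beta_group Offsets for ciliate and invertebrate vs flagellate.
#' @param beta_depth_group Additional depth slope for ciliate and
#'   invertebrate (negative = steeper decline than flagellates).
#' @param intercept Reference-group surface intercept.
#' @param sigma_site SD of the site random intercept.
#' @param sigma_resid Residual SD.
#' @param seed Integer seed.
#' @return A tibble with `site`, `condition`, `depth` (stratum midpoint, cm),
#'   `group`, `date`, `y`, plus an attribute `"truth"` holding the named true
#'   coefficient vector on the treatment-contrast scale used by
#'   [fit_assemblage_model()].
#' @export
simulate_lmm_data <- function(n_sites = 6, n_layers = 7, n_groups = 3,
                              n_dates = 4,
                              beta_depth = -0.03,
                              beta_dw = 0.4,
                              beta_group = c(ciliate = -0.5,
                                             invertebrate = -1.0),
                              beta_depth_group = c(ciliate = -0.02,
                                                   invertebrate = -0.05),
                              intercept = 0.5,
                              sigma_site = 0.15,
                              sigma_resid = 0.3,
                              seed = 1L) {
  groups <- c("flagellate", "ciliate", "invertebrate")[seq_len(n_groups)]
  df <- tidyr::expand_grid(
    site = seq_len(n_sites),
    depth = (seq_len(n_layers) - 1L) * 5 + 2.5,
    group = factor(groups, levels = groups),
    date = seq_len(n_dates)
  )
  df$condition <- ifelse(df$site %% 2 == 1, "UW", "DW")
  truth <- c(
    "(Intercept)" = intercept,
    depth = beta_depth,
    hydroDW = beta_dw,
    groupciliate = unname(beta_group["ciliate"]),
    groupinvertebrate = unname(beta_group["invertebrate"]),
    "depth:groupciliate" = unname(beta_depth_group["ciliate"]),
    "depth:groupinvertebrate" = unname(beta_depth_group["invertebrate"])
  )
  if (n_groups < 3) {
    truth <- truth[!grepl("invertebrate", names(truth))]
  }
  with_seed(seed, {
    site_eff <- rnorm(n_sites, 0, sigma_site)
    mu <- intercept +
      beta_depth * df$depth +
      beta_dw * (df$condition == "DW") +
      ifelse(df$group == "ciliate", beta_group["ciliate"] +
               beta_depth_group["ciliate"] * df$depth, 0) +
      ifelse(df$group == "invertebrate", beta_group["invertebrate"] +
               beta_depth_group["invertebrate"] * df$depth, 0) +
      site_eff[df$site]
    df$y <- mu + rnorm(nrow(df), 0, sigma_resid)
    out <- tibble::as_tibble(df[, c("site", "condition", "depth", "group",
                                    "date", "y")])
    attr(out, "truth") <- truth
    out
  })
}
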