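test_that("biovolume shapes match their geometric formulas", {
  expect_equal(biovolume(10, 10, "sphere"), pi / 6 * 1000, tolerance = 1e-12)
  expect_equal(biovolume(50, 20, "prolate_spheroid"), pi / 6 * 50 * 400,
               tolerance = 1e-12)  # 10471.98 um^3
  expect_equal(biovolume(100, 10, "cylinder"), pi / 4 * 100 * 100,
               tolerance = 1e-12)  # 7853.98 um^3
  expect_equal(biovolume(30, 10, "custom", custom_factor = 0.55),
               0.55 * 30 * 100)
  expect_error(biovolume(10, 5, "banana"), "unknown shape_class")
  expect_error(biovolume(10, 5, "custom"), "custom_factor")
})

test_that("carbon conversion follows the group-specific chains", {
  expect_equal(carbon_content(1000, "ciliate"), 140)          # 0.14 pg C/um^3
  expect_equal(carbon_content(1000, "flagellate"), 140)
  expect_equal(carbon_content(1e6, "invertebrate"), 1e6 * 1.05 * 0.25 * 0.4)
  expect_equal(carbon_content(0, "ciliate"), 0)
  p <- carbon_params(invert_specific_gravity = 1.1)
  expect_equal(carbon_content(100, "invertebrate", p), 100 * 1.1 * 0.1)
  expect_error(carbon_params(dry_wet_ratio = 0), "0, 2")
})

test_that("biomass concentration does the unit arithmetic and is linear in counts", {
  m <- tibble::tibble(
    site = 1, condition = "UW", date = as.Date("2020-06-01"),
    layer = 0L, depth_mid_cm = 2.5, taxon = "t1", group = "ciliate",
    shape_class = "sphere", length_um = (6000 / pi)^(1 / 3),  # V = 1000 um^3
    width_um = (6000 / pi)^(1 / 3), count = 10, sample_volume_l = 1e-5
  )
  b <- biomass_concentration(m)
  # 140 pg C x 1e6 ind/L = 1.4e8 pg C/L = 0.14 mg C/L
  expect_equal(b$biomass_mg_l, 0.14, tolerance = 1e-9)
  m2 <- dplyr::mutate(m, count = count * 3)
  expect_equal(biomass_concentration(m2)$biomass_mg_l, 3 * b$biomass_mg_l)
  # empty layer contributes zero biomass
  m0 <- dplyr::mutate(m, count = 0)
  expect_equal(biomass_concentration(m0)$biomass_mg_l, 0)
})

test_that("Arrhenius correction is 1 at T0, ~1.54 at +5K, and increasing", {
  expect_equal(temperature_correction(288.15), 1)
  expect_equal(temperature_correction(293.15),
               exp((0.63 / 8.617e-5) * (1 / 288.15 - 1 / 293.15)),
               tolerance = 1e-12)
  expect_equal(temperature_correction(293.15), 1.5415, tolerance = 1e-4)
  ts <- seq(278, 308, by = 5)
  expect_true(all(diff(temperature_correction(ts)) > 0))
  expect_warning(temperature_correction(250), "outside")
})

test_that("allometric turnover follows a * f(T) * M^b", {
  p <- turnover_params(groups = list(g = list(mode = "allometric",
                                              a = 0.5, b = -0.25)))
  expect_equal(turnover_rate(1, "g", 288.15, p), 0.5)
  expect_equal(turnover_rate(16, "g", 288.15, p), 0.25)  # 16^-0.25 = 0.5
  masses <- c(1, 4, 16, 64)
  expect_true(all(diff(turnover_rate(masses, "g", 288.15, p)) < 0))
  expect_error(turnover_rate(1, "nope", 288.15, p), "no turnover coefficients")
  expect_error(turnover_rate(0, "g", 288.15, p), "mass")
})

test_that("growth-equation mode evaluates per-taxon coefficients", {
  p <- turnover_params(
    groups = list(invertebrate = list(mode = "growth_equation")),
    growth_coefficients = tibble::tibble(taxon = "Chironomidae",
                                         c0 = log(0.2), c1 = 0)
  )
  expect_equal(turnover_rate(100, "invertebrate", 288.15, p,
                             taxon = "Chironomidae"), 0.2)
  expect_error(turnover_rate(100, "invertebrate", 288.15, p, taxon = "x"),
               "missing growth coefficients")
})

test_that("interval production implements B-hat x r x dt and sums to totals", {
  # B-hat = 2, r = 0.1/day, dt = 7 -> P_i = 1.4; three intervals -> 4.2
  dates <- as.Date("2020-06-01") + c(0, 7, 14, 21)
  b <- tibble::tibble(
    site = 1, condition = "UW", date = dates, layer = 0L, depth_mid_cm = 2.5,
    group = "g", taxon = "t", ind_carbon_pg = 1,
    biomass_mg_l = 2, abundance_l = 1
  )
  p <- turnover_params(groups = list(g = list(mode = "allometric",
                                              a = 0.1, b = 0)))
  prod <- production(b, params = p, dt_days = 7)
  expect_equal(prod$b_hat, rep(2, 3))
  expect_equal(prod$p_interval, rep(1.4, 3), tolerance = 1e-12)
  expect_equal(unique(prod$p_total), 4.2, tolerance = 1e-12)

  # zero turnover yields zero production
  p0 <- turnover_params(groups = list(g = list(mode = "allometric",
                                               a = 1e-300, b = 0)))
  expect_equal(unique(production(b, params = p0)$p_total), 0,
               tolerance = 1e-290)

  expect_error(production(b[b$date == dates[1], ], params = p), ">= 2 sampling dates")
})

test_that("the hand-computed worksheet agrees with the pipeline end to end", {
  m <- worksheet_measurements()
  # worksheet: V = (pi/6)*50*400 um^3; ciliate carbon 0.14 V pg
  v <- pi / 6 * 50 * 400
  cpg <- 0.14 * v
  dens <- c(4 + 6, 2 + 2) / 0.01              # ind/L on the two dates
  biom <- cpg * dens / 1e9                    # mg C/L
  b_hat <- mean(biom)
  p <- turnover_params(groups = list(ciliate = list(mode = "allometric",
                                                    a = 0.6, b = -0.25)))
  r <- 0.6 * cpg^-0.25                        # at reference temperature
  expected_pt <- b_hat * r * 7
  got <- production(biomass_concentration(m), params = p, by = "taxon")
  expect_equal(unique(got$p_total), expected_pt, tolerance = 1e-9)
  expect_equal(got$r_per_day, r, tolerance = 1e-9)
})

test_that("production scales linearly with counts", {
  m <- worksheet_measurements()
  g1 <- production(biomass_concentration(m))
  m2 <- dplyr::mutate(m, count = count * 5)
  g5 <- production(biomass_concentration(m2))
  expect_equal(unique(g5$p_total) / unique(g1$p_total), 5, tolerance = 1e-9)
})

test_that("log-biomass depth decay is steepest for invertebrates on synthetic data", {
  sc <- community_scenario(n_sites = 4, n_dates = 2, site_effect_sd = 0,
                           date_effect_sd = 0, seed = 21)
  b <- biomass_concentration(simulate_community(sc))
  slopes <- vapply(c("invertebrate", "ciliate", "flagellate"), function(g) {
    sub <- dplyr::filter(b, group == g, biomass_mg_l > 0)
    agg <- dplyr::summarise(dplyr::group_by(sub, depth_mid_cm),
                            y = log(sum(biomass_mg_l)), .groups = "drop")
    unname(coef(lm(y ~ depth_mid_cm, data = agg))[2])
  }, numeric(1))
  expect_lt(slopes[["invertebrate"]], slopes[["ciliate"]])
  expect_lt(slopes[["ciliate"]], slopes[["flagellate"]])
})

test_that("layer temperatures map strata to the nearest sensor", {
  fits <- tidyr::expand_grid(
    site_id = "1", depth_cm = c(2.5, 12.5, 22.5),
    window_start = as.Date("2020-06-01")
  )
  fits$mean_t <- fits$depth_cm  # label sensors by their depth
  fits$amplitude <- 1; fits$phase <- 0; fits$rmse <- 0; fits$n_obs <- 144
  lt <- layer_temperatures(fits, n_layers = 5)
  expect_equal(lt$temp_c, c(2.5, 2.5, 12.5, 12.5, 22.5))
})
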