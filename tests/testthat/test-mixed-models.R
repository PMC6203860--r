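test_that("a zero site effect is recovered as a singular random intercept", {
  dat <- simulate_lmm_data(sigma_site = 0, seed = 41)
  fit <- fit_assemblage_model(dat, "y", interactions = "depth:group")
  expect_true(fit$singular)
  expect_lt(glance(fit)$sigma.site, 1e-4)
})

test_that("log-likelihood is non-decreasing under model nesting", {
  dat <- simulate_lmm_data(seed = 42)
  small <- fit_assemblage_model(dat, "y", fixed = c("depth", "group"))
  big <- fit_assemblage_model(dat, "y", fixed = c("depth", "hydro", "group"))
  expect_gte(glance(big)$logLik, glance(small)$logLik - 1e-6)
})

test_that("interaction specs respect marginality", {
  dat <- simulate_lmm_data(seed = 43)
  expect_error(fit_assemblage_model(dat, "y", fixed = "depth",
                                    interactions = "depth:group"),
               "both main effects")
})

test_that("log10 transform applies the half-minimum offset only when zeros exist", {
  dat <- simulate_lmm_data(seed = 44)
  dat$b <- 10^dat$y
  fit <- fit_assemblage_model(dat, "b", log10_transform = TRUE)
  expect_true(is.na(fit$offset_used))
  expect_equal(unname(lme4::fixef(fit$fit)["depth"]),
               unname(lme4::fixef(fit_assemblage_model(dat, "y")$fit)["depth"]),
               tolerance = 1e-6)
  dat$b[1] <- 0
  fit0 <- fit_assemblage_model(dat, "b", log10_transform = TRUE)
  expect_equal(fit0$offset_used, min(dat$b[dat$b > 0]) / 2)
})

test_that("posterior sign probabilities behave at the symmetric and extreme ends", {
  dat <- simulate_lmm_data(beta_dw = 0, beta_depth = -0.05, seed = 45)
  fit <- fit_assemblage_model(dat, "y", fixed = c("depth", "hydro"))
  post <- simulate_posterior(fit, n = 5000, seed = 46)
  s <- post$summary
  # a null coefficient has near-symmetric posterior mass
  expect_lt(abs(s$prob.negative[s$term == "hydroDW"] - 0.5), 0.35)
  # |z| >> 6 drives the sign probability to 1.00 at 5000 draws
  expect_equal(s$prob.negative[s$term == "depth"], 1)
  expect_true(all(s$conf.low <= s$conf.high))
  expect_identical(simulate_posterior(fit, n = 200, seed = 9)$summary,
                   simulate_posterior(fit, n = 200, seed = 9)$summary)
})

test_that("Monte-Carlo error of posterior quantiles shrinks with draws", {
  dat <- simulate_lmm_data(seed = 47)
  fit <- fit_assemblage_model(dat, "y")
  sd_at <- function(n) {
    qs <- vapply(1:30, function(i) {
      simulate_posterior(fit, n = n, seed = 1000 + i)$summary$conf.low[2]
    }, numeric(1))
    sd(qs)
  }
  s_small <- sd_at(250)
  s_big <- sd_at(1000)
  # quadrupling draws should roughly halve the MC standard error
  expect_lt(s_big, s_small)
  expect_lt(s_big / s_small, 0.85)
})

test_that("WAIC collapses to -2 logLik under a degenerate posterior", {
  dat <- simulate_lmm_data(seed = 48)
  fit <- fit_assemblage_model(dat, "y")
  post <- simulate_posterior(fit, n = 50, seed = 3)
  # freeze all draws at the estimate: zero spread, p_waic = 0
  post$draws[] <- rep(lme4::fixef(fit$fit), each = nrow(post$draws))
  post$sigma_draws[] <- stats::sigma(fit$fit)
  w <- waic(fit, post)
  expect_equal(w$p_waic, 0, tolerance = 1e-9)
  ll <- sum(hyporheos:::pointwise_loglik(fit, post)[, 1])
  expect_equal(w$waic, -2 * ll, tolerance = 1e-9)
})

test_that("WAIC is invariant to observation order and penalises noise terms", {
  dat <- simulate_lmm_data(seed = 49)
  fit1 <- fit_assemblage_model(dat, "y", fixed = c("depth", "group"))
  w1 <- waic(fit1, n_draws = 400, seed = 5)
  shuf <- dat[withr::with_seed(5, sample(nrow(dat))), ]
  fit2 <- fit_assemblage_model(shuf, "y", fixed = c("depth", "group"))
  w2 <- waic(fit2, n_draws = 400, seed = 5)
  expect_equal(w1$waic, w2$waic, tolerance = 0.5)

  # the true structure should beat a depth-free model decisively
  fit0 <- fit_assemblage_model(dat, "y", fixed = "hydro")
  w0 <- waic(fit0, n_draws = 400, seed = 5)
  expect_lt(w1$waic, w0$waic)
})

test_that("conditional R2 matches the variance-component plug-in", {
  # build data with known components: var_f ~ 1, var_site = 1, var_resid = 2
  n_site <- 40; n_per <- 100
  withr::with_seed(50, {
    site <- rep(seq_len(n_site), each = n_per)
    x <- rnorm(n_site * n_per)
    y <- x + rnorm(n_site, 0, 1)[site] + rnorm(n_site * n_per, 0, sqrt(2))
    dat <- tibble::tibble(site = site, condition = "UW", depth = x, y = y)
  })
  fit <- fit_assemblage_model(dat, "y", fixed = "depth")
  r2 <- conditional_r2(fit)
  expect_equal(r2, 0.5, tolerance = 0.12)

  # a perfect fixed-effect fit has R2 -> 1
  dat$y2 <- 2 + 3 * dat$depth + rnorm(nrow(dat), 0, 1e-4)
  expect_gt(conditional_r2(fit_assemblage_model(dat, "y2", fixed = "depth")), 0.999)
})

test_that("dispersion statistic flags the underdispersed continuous-index regime", {
  withr::with_seed(51, {
    site <- rep(1:6, each = 80)
    mu <- exp(0.8 + 0.2 * rnorm(6)[site])
    dat <- tibble::tibble(site = site, condition = "UW",
                          depth = runif(480, 0, 35),
                          y_pois = rpois(480, mu),
                          y_cont = pmax(0.02, 1.2 + rnorm(480, 0, 0.15)))
  })
  f_pois <- fit_assemblage_model(dat, "y_pois", fixed = "depth",
                                 family = "poisson_log")
  expect_equal(dispersion_check(f_pois), 1, tolerance = 0.25)
  f_cont <- fit_assemblage_model(dat, "y_cont", fixed = "depth",
                                 family = "poisson_log")
  expect_lt(dispersion_check(f_cont), 0.3)
  expect_gte(dispersion_check(f_cont), 0)
  expect_error(dispersion_check(fit_assemblage_model(dat, "y_cont",
                                                     fixed = "depth")),
               "poisson_log")
})

test_that("model enumeration respects marginality and counts 18 candidates", {
  specs <- enumerate_model_specs()
  expect_length(specs, 18)
  for (sp in specs) {
    for (ia in sp$interactions) {
      expect_true(all(strsplit(ia, ":")[[1]] %in% sp$fixed))
    }
  }
})

test_that("WAIC selection finds a strong interaction and is seed-stable", {
  dat <- simulate_lmm_data(seed = 52)
  sel <- select_by_waic(dat, "y", n_draws = 300, seed = 52)
  expect_true(grepl("depth:group", sel$ranking$model[1]))
  sel2 <- select_by_waic(dat, "y", n_draws = 300, seed = 52)
  expect_identical(sel$ranking$model, sel2$ranking$model)
  expect_identical(sel$ranking$waic, sel2$ranking$waic)
})

test_that("WAIC ranking is invariant to affine predictor rescaling", {
  dat <- simulate_lmm_data(seed = 53)
  sel_cm <- select_by_waic(dat, "y", mains = c("depth", "hydro"),
                           n_draws = 400, seed = 6)
  dat_m <- dplyr::mutate(dat, depth = depth / 100 + 1)
  sel_m <- select_by_waic(dat_m, "y", mains = c("depth", "hydro"),
                          n_draws = 400, seed = 6)
  expect_identical(sel_cm$ranking$model[1], sel_m$ranking$model[1])
})

test_that("tidy and glance return well-formed tibbles", {
  dat <- simulate_lmm_data(seed = 54)
  fit <- fit_assemblage_model(dat, "y")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_true(gl$r2.conditional >= 0 && gl$r2.conditional <= 1)
})
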