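#' Simulate the joint posterior of model coefficients
#'
#' Analytical direct simulation with flat priors: draws from the multivariate
#' normal approximation centred at the fixed-effect estimates with the fitted
#' coefficient covariance. For Gaussian fits the residual scale is drawn per
#' sample from its scaled inverse-chi-square distribution
#' (\eqn{\hat\sigma\sqrt{df/\chi^2_{df}}}, df = n - p), so the posterior
#' spread reflects scale uncertainty too. Summaries report the draw mean, the
#' 2.5% and 97.5% quantiles as a 95% credible interval, and the posterior
#' sign probability P(beta < 0). A non-positive-definite covariance is
#' repaired to the nearest positive-definite matrix (eigenvalue clipping)
#' with a warning.
#'
#' @param object An `assemblage_fit`.
#' @param n Number of posterior draws (default 5000).
#' @param seed Integer seed.
#' @return An object of class `assemblage_posterior`: list with `draws`
#'   (n x p matrix), `sigma_draws` (Gaussian only), `summary` tibble
#'   (`term`, `estimate`, `conf.low`, `conf.high`, `prob.negative`), `n`,
#'   `seed`.
#' @examples
#' fit <- fit_assemblage_model(simulate_lmm_data(seed = 5), "y")
#' simulate_posterior(fit, n = 500, seed = 5)$summary
#' @export
simulate_posterior <- function(object, n = 5000, seed = NULL) {
  if (!inherits(object, "assemblage_fit")) abort("`object` must be an assemblage_fit.")
  beta <- lme4::fixef(object$fit)
  v <- as.matrix(stats::vcov(object$fit))
  ev <- eigen(v, symmetric = TRUE)
  if (min(ev$values) < -1e-10 * max(abs(ev$values))) {
    warn("coefficient covariance not positive definite; clipping eigenvalues.")
    ev$values <- pmax(ev$values, 1e-12 * max(ev$values))
    v <- ev$vectors %*% diag(ev$values, nrow = length(ev$values)) %*% t(ev$vectors)
  }
  with_seed(seed, {
    draws <- MASS::mvrnorm(n, mu = beta, Sigma = v)
    if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1,
                                             dimnames = list(NULL, names(beta)))
    sigma_draws <- NULL
    if (object$family == "gaussian") {
      df <- object$n_obs - length(beta)
      sigma_draws <- stats::sigma(object$fit) * sqrt(df / rchisq(n, df))
    }
    qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975))
    summ <- tibble::tibble(
      term = colnames(draws),
      estimate = unname(colMeans(draws)),
      conf.low = unname(qs[1, ]),
      conf.high = unname(qs[2, ]),
      prob.negative = unname(colMeans(draws < 0))
    )
    structure(
      list(draws = draws, sigma_draws = sigma_draws, summary = summ,
           n = n, seed = seed, fit = object),
      class = "assemblage_posterior"
    )
  })
}

#' @export
print.assemblage_posterior <- function(x, ...) {
  cat("<assemblage_posterior>", x$n, "draws\n")
  print(x$summary)
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.assemblage_posterior <- function(x, ...) x$summary

# pointwise log-likelihood matrix (n_obs x n_draws), conditional on the
# estimated random-effect modes
pointwise_loglik <- function(object, posterior) {
  fit <- object$fit
  x_mat <- lme4::getME(fit, "X")
  zb <- as.numeric(lme4::getME(fit, "Z") %*% lme4::getME(fit, "b"))
  y <- lme4::getME(fit, "y")
  eta <- x_mat %*% t(posterior$draws) + zb
  if (object$family == "gaussian") {
    sig <- posterior$sigma_draws %||% rep(stats::sigma(fit), posterior$n)
    matrix(dnorm(y, mean = eta, sd = rep(sig, each = length(y)), log = TRUE),
           nrow = length(y))
  } else {
    lambda <- exp(eta)
    # continuous-response Poisson quasi-likelihood: y log(l) - l - lgamma(y+1)
    y * log(lambda) - lambda - lgamma(y + 1)
  }
}

#' Widely applicable information criterion
#'
#' WAIC computed from the direct-simulation posterior:
#' \deqn{\mathrm{WAIC} = -2\,(\mathrm{lppd} - p_{waic}),}
#' with \eqn{\mathrm{lppd} = \sum_i \log \frac{1}{D}\sum_d \exp \ell_{id}}
#' and \eqn{p_{waic} = \sum_i \mathrm{Var}_d(\ell_{id})} over the pointwise
#' log-likelihoods of the posterior draws (conditional on the estimated
#' random-effect modes). A warning is raised when many pointwise variance
#' terms exceed 0.4, the usual instability diagnostic.
#'
#' @param object An `assemblage_fit`.
#' @param posterior An `assemblage_posterior` for the same fit; generated
#'   (with `n_draws`, `seed`) when absent.
#' @param n_draws,seed Used only when `posterior` is NULL.
#' @return A list: `waic`, `lppd`, `p_waic`, `n_unstable`.
#' @export
waic <- function(object, posterior = NULL, n_draws = 1000, seed = NULL) {
  if (is.null(posterior)) {
    posterior <- simulate_posterior(object, n = n_draws, seed = seed)
  }
  ll <- pointwise_loglik(object, posterior)
  lppd <- sum(row_log_mean_exp(ll))
  pw <- row_vars(ll)
  n_unstable <- sum(pw > 0.4)
  if (n_unstable > 0.1 * length(pw)) {
    warn(sprintf("WAIC may be unstable: %d pointwise variance terms > 0.4.",
                 n_unstable))
  }
  p_waic <- sum(pw)
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
       n_unstable = n_unstable)
}

#' Conditional R-squared of a mixed model
#'
#' Variance-partition fit measure: the proportion of total variance
#' attributable to fixed plus random effects,
#' \deqn{R^2_c = \frac{\sigma^2_f + \sigma^2_\alpha}{\sigma^2_f + \sigma^2_\alpha + \sigma^2_\varepsilon},}
#' where \eqn{\sigma^2_f} is the variance of the fixed-effect predictor.
#' For the Poisson-log family the residual variance on the link scale uses
#' the lognormal approximation \eqn{\ln(1 + 1/\bar\lambda)} with
#' \eqn{\bar\lambda = \exp(\beta_0 + \sigma^2_\alpha/2)}.
#'
#' @param object An `assemblage_fit`.
#' @return Conditional R-squared in `[0, 1]`.
#' @export
conditional_r2 <- function(object) {
  fit <- object$fit
  x_mat <- lme4::getME(fit, "X")
  var_f <- var(as.numeric(x_mat %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_a <- sum(vapply(vc, function(m) sum(diag(m)), numeric(1)))
  var_e <- if (object$family == "gaussian") {
    stats::sigma(fit)^2
  } else {
    lambda_bar <- exp(lme4::fixef(fit)[1] + var_a / 2)
    log1p(1 / lambda_bar)
  }
  unname((var_f + var_a) / (var_f + var_a + var_e))
}

#' Pearson dispersion check for Poisson mixed models
#'
#' Sum of squared Pearson residuals divided by the residual degrees of
#' freedom; values near 1 indicate equidispersion, values far below 1
#' underdispersion (the regime expected when a Poisson family is applied to
#' a bounded continuous index).
#'
#' @param object An `assemblage_fit` with `family = "poisson_log"`.
#' @return The dispersion statistic (>= 0).
#' @export
dispersion_check <- function(object) {
  if (object$family != "poisson_log") {
    abort("dispersion check applies to the poisson_log family.")
  }
  fit <- object$fit
  pr <- stats::residuals(fit, type = "pearson")
  df <- length(pr) - length(lme4::fixef(fit)) - length(lme4::getME(fit, "theta"))
  sum(pr^2) / df
}
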