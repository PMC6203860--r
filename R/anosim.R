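#' Analysis of similarities (ANOSIM) by label permutation
#'
#' Rank-based test contrasting between-group and within-group
#' dissimilarities. All defined off-diagonal dissimilarities are ranked
#' (average ranks on ties) and
#' \deqn{R = \frac{\bar r_{between} - \bar r_{within}}{n(n-1)/4},}
#' with `n` the number of samples. Significance comes from permuting group
#' membership: the one-sided p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{R^{perm} \ge R^{obs}\}) / (1 + n_{perm})}, which can
#' never return exactly zero. Pairs with undefined dissimilarity (both-zero
#' samples under Bray-Curtis) are excluded from the ranking and from every
#' permutation alike.
#'
#' @param d Symmetric dissimilarity matrix (possibly with `NA` pairs) or a
#'   `dist` object.
#' @param groups Group membership vector, length = number of samples; at
#'   least two groups with >= 2 members each.
#' @param n_perm Number of label permutations (1000 by default).
#' @param seed Integer seed for the permutation stream.
#' @param alpha Significance level recorded in the result.
#' @return An object of class `anosim_result`: list with `statistic` (R),
#'   `p_value`, `n_perm`, `alpha`, `significant`, `perm_stats`, `n_samples`,
#'   `seed`.
#' @examples
#' m <- rbind(a1 = c(10, 0, 0), a2 = c(9, 1, 0),
#'            b1 = c(0, 0, 10), b2 = c(1, 0, 9))
#' anosim(bray_curtis_matrix(m), c("a", "a", "b", "b"), n_perm = 99, seed = 1)
#' @export
anosim <- function(d, groups, n_perm = 1000, seed = NULL, alpha = 0.05) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (length(groups) != n) abort("`groups` must have one label per sample.")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("ANOSIM needs >= 2 groups with >= 2 members each.")
  }
  pr <- which(upper.tri(d), arr.ind = TRUE)
  dv <- d[upper.tri(d)]
  keep <- !is.na(dv)
  if (sum(keep) < 3) abort("too few defined dissimilarities.")
  pr <- pr[keep, , drop = FALSE]
  rk <- rank(dv[keep])
  denom <- n * (n - 1) / 4

  r_of <- function(g) {
    within <- g[pr[, 1]] == g[pr[, 2]]
    if (!any(within) || all(within)) return(NA_real_)
    (mean(rk[!within]) - mean(rk[within])) / denom
  }
  r_obs <- r_of(groups)

  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) r_of(sample(groups)), numeric(1))
  })
  p <- (1 + sum(perm_stats >= r_obs, na.rm = TRUE)) / (1 + n_perm)
  structure(
    list(statistic = r_obs, p_value = p, n_perm = n_perm, alpha = alpha,
         significant = p < alpha, perm_stats = perm_stats,
         n_samples = n, seed = seed),
    class = "anosim_result"
  )
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("ANOSIM: R =", format(x$statistic, digits = 4),
      " p =", format(x$p_value, digits = 4),
      sprintf("(%d permutations, n = %d)\n", x$n_perm, x$n_samples))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.anosim_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 n.perm = x$n_perm, n.samples = x$n_samples)
}
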