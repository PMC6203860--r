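#' Enumerate candidate model specifications
#'
#' All subsets of the main terms combined with all first-order interactions
#' whose two main effects are present (marginality is respected: no
#' interaction without its main effects).
#'
#' @param mains Character vector of main terms.
#' @param interactions Candidate interactions ("a:b" form); defaults to all
#'   pairs of `mains`.
#' @return A list of specs, each `list(fixed = ..., interactions = ...)`.
#' @export
enumerate_model_specs <- function(mains = c("depth", "hydro", "group"),
                                  interactions = NULL) {
  if (is.null(interactions)) {
    interactions <- if (length(mains) >= 2) {
      cmb <- utils::combn(mains, 2)
      apply(cmb, 2, paste, collapse = ":")
    } else {
      character()
    }
  }
  specs <- list()
  for (mi in 0:(2^length(mains) - 1)) {
    fx <- mains[bitwAnd(mi, 2^(seq_along(mains) - 1)) > 0]
    ok_ia <- interactions[vapply(interactions, function(ia) {
      all(strsplit(ia, ":", fixed = TRUE)[[1]] %in% fx)
    }, logical(1))]
    for (ii in 0:(2^length(ok_ia) - 1)) {
      ia <- ok_ia[bitwAnd(ii, 2^(seq_along(ok_ia) - 1)) > 0]
      specs[[length(specs) + 1L]] <- list(fixed = fx, interactions = ia)
    }
  }
  specs
}

#' Select the optimal mixed model by WAIC
#'
#' Fits every candidate specification from [enumerate_model_specs()] (always
#' with the site random intercept), computes WAIC from the direct-simulation
#' posterior of each converged fit, and returns the full ranking and the
#' minimum-WAIC specification. Candidates whose fit fails are excluded with
#' a warning.
#'
#' @inheritParams fit_assemblage_model
#' @param mains Main terms to combine.
#' @param interactions Candidate interactions; default all pairs.
#' @param n_draws Posterior draws per candidate used for WAIC.
#' @param seed Integer seed (per-candidate child seeds are derived).
#' @return An object of class `waic_selection`: list with `ranking` (tibble,
#'   one row per candidate, sorted by WAIC), `best` (spec list), `best_fit`
#'   (the refitted best model).
#' @examples
#' dat <- simulate_lmm_data(seed = 11)
#' sel <- select_by_waic(dat, "y", n_draws = 200, seed = 11)
#' sel$ranking[1:3, c("model", "waic")]
#' @export
select_by_waic <- function(data, response,
                           mains = c("depth", "hydro", "group"),
                           interactions = NULL,
                           family = c("gaussian", "poisson_log"),
                           log10_transform = FALSE,
                           n_draws = 1000, seed = NULL) {
  family <- match.arg(family)
  specs <- enumerate_model_specs(mains, interactions)
  rows <- list()
  fits <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    label <- paste(c(sp$fixed, sp$interactions), collapse = " + ")
    if (label == "") label <- "1"
    fit <- tryCatch(
      fit_assemblage_model(data, response, fixed = sp$fixed,
                           interactions = sp$interactions, family = family,
                           log10_transform = log10_transform),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      warn(sprintf("candidate '%s' failed to fit; excluded.", label))
      next
    }
    w <- waic(fit, n_draws = n_draws, seed = child_seed(seed, i))
    fits[[length(fits) + 1L]] <- fit
    rows[[length(rows) + 1L]] <- tibble::tibble(
      model = label, n_terms = length(sp$fixed) + length(sp$interactions),
      waic = w$waic, lppd = w$lppd, p_waic = w$p_waic,
      spec = list(sp)
    )
  }
  if (length(rows) == 0) abort("no candidate model converged.")
  ranking <- dplyr::arrange(dplyr::bind_rows(rows), .data$waic)
  best <- ranking$spec[[1]]
  structure(
    list(ranking = ranking, best = best,
         best_fit = fits[[which(vapply(rows, function(r) r$waic, 1) ==
                                  ranking$waic[1])[1]]]),
    class = "waic_selection"
  )
}

#' @export
print.waic_selection <- function(x, ...) {
  cat("<waic_selection>", nrow(x$ranking), "candidates\n")
  print(x$ranking[, c("model", "n_terms", "waic", "p_waic")], n = 10)
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.waic_selection <- function(x, ...) {
  x$ranking[, c("model", "n_terms", "waic", "lppd", "p_waic")]
}
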