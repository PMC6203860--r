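#' Plot a vertical flux profile
#'
#' Mean velocity per sensor pair (midpoint depth) and site, with the UW/DW
#' sign convention: positive = downward flux.
#'
#' @param flux Tibble from [flux_profile()].
#' @return A ggplot object.
#' @export
plot_flux_profile <- function(flux) {
  conv <- dplyr::filter(flux, .data$converged)
  prof <- dplyr::summarise(
    dplyr::group_by(conv, .data$site_id, .data$upper_z, .data$lower_z),
    velocity = mean(.data$velocity), .groups = "drop"
  )
  prof$mid_z <- (prof$upper_z + prof$lower_z) / 2
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$velocity, y = .data$mid_z)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_path(ggplot2::aes(group = .data$site_id)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(ggplot2::vars(.data$site_id)) +
    ggplot2::labs(x = "vertical flux (m/day, + = downward)",
                  y = "depth (cm)")
}

#' Plot depth profiles of a per-layer response
#'
#' @param data Tibble with `depth_mid_cm`, a response column, `condition`
#'   and optionally `group`.
#' @param response Column name to plot on the x axis.
#' @param log10 Use a log10 x scale.
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(data, response, log10 = FALSE) {
  aes <- if ("group" %in% names(data)) {
    ggplot2::aes(x = .data[[response]], y = .data$depth_mid_cm,
                 colour = .data$group)
  } else {
    ggplot2::aes(x = .data[[response]], y = .data$depth_mid_cm)
  }
  p <- ggplot2::ggplot(data, aes) +
    ggplot2::stat_summary(fun = mean, geom = "path",
                          ggplot2::aes(group = if ("group" %in% names(data))
                            .data$group else 1)) +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(y = "depth (cm)")
  if (log10) p <- p + ggplot2::scale_x_log10()
  p
}

#' @describeIn anosim ggplot of the permutation null distribution with the
#'   observed R marked.
#' @export
autoplot.anosim_result <- function(object, ...) {
  df <- tibble::tibble(r = object$perm_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "red") +
    ggplot2::labs(x = "permuted ANOSIM R", y = "count",
                  subtitle = sprintf("observed R = %.3f, p = %.4f",
                                     object$statistic, object$p_value))
}

#' @describeIn delineate_boundary ggplot of per-pair ANOSIM p-values along
#'   depth with the detected boundary highlighted.
#' @export
autoplot.boundary_result <- function(object, ...) {
  df <- object$pairs
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$p_value,
                                        y = .data$interface_depth_cm)) +
    ggplot2::geom_vline(xintercept = object$alpha, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::geom_path() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ANOSIM p-value", y = "interface depth (cm)",
                  subtitle = paste("condition", object$condition))
  if (!is.null(object$boundary)) {
    p <- p + ggplot2::geom_hline(yintercept = object$boundary$interface_depth_cm,
                                 colour = "red", linetype = 3)
  }
  p
}

#' @describeIn simulate_posterior ggplot of coefficient posterior means and
#'   95% credible intervals.
#' @export
autoplot.assemblage_posterior <- function(object, ...) {
  df <- object$summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "posterior mean and 95% CrI", y = NULL)
}
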