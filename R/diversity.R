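#' Shannon-Wiener diversity
#'
#' \deqn{H' = -\sum_{i=1}^{S} Pr_i \ln(Pr_i),}
#' with \eqn{Pr_i} the proportion of individuals belonging to taxon *i*;
#' zero-abundance taxa contribute nothing (the \eqn{0\ln 0 \equiv 0}
#' convention). An all-zero assemblage has undefined diversity and returns
#' `NA`; such layers are excluded from downstream models.
#'
#' @param abundance Numeric vector of taxon abundances (any common unit;
#'   H' is invariant to rescaling).
#' @return H' (natural-log units), or `NA_real_` for an empty assemblage.
#' @examples
#' shannon(rep(1, 10))   # ln 10
#' shannon(c(2, 1, 1))   # 1.039721
#' @export
shannon <- function(abundance) {
  if (any(abundance < 0, na.rm = TRUE)) abort("abundances must be >= 0.")
  tot <- sum(abundance, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  p <- abundance[abundance > 0] / tot
  -sum(p * log(p))
}

#' Diversity depth profile
#'
#' Computes H' for every (site, date, layer) assemblage of a count table.
#'
#' @param counts Organism-measurement tibble (see [simulate_community()]);
#'   abundances are `count / sample_volume_l` summed per taxon.
#' @return A tibble (`site`, `condition`, `date`, `layer`, `depth_mid_cm`,
#'   `n_taxa`, `diversity`). All-zero layers carry `NA` diversity.
#' @export
diversity_profile <- function(counts) {
  tx <- dplyr::summarise(
    dplyr::group_by(counts, .data$site, .data$condition, .data$date,
                    .data$layer, .data$depth_mid_cm, .data$taxon),
    abundance_l = sum(.data$count / .data$sample_volume_l),
    .groups = "drop_last"
  )
  dplyr::ungroup(dplyr::summarise(
    tx,
    n_taxa = sum(.data$abundance_l > 0),
    diversity = shannon(.data$abundance_l),
    .groups = "drop"
  ))
}
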