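#' Geometric biovolume from body dimensions
#'
#' Converts body length and width (micrometres) to biovolume (cubic
#' micrometres) using a shape catalogue: sphere \eqn{(\pi/6)L^3}, prolate
#' spheroid \eqn{(\pi/6)LW^2}, cylinder \eqn{(\pi/4)W^2L}, or a custom
#' user-supplied factor times \eqn{LW^2}. The default per-group mapping
#' (flagellates sphere or prolate spheroid, ciliates prolate spheroid,
#' worm-like invertebrates cylinder) reflects standard practice for
#' size-structured freshwater assemblages.
#'
#' @param length_um,width_um Body length and width, micrometres (vectorised;
#'   `width_um <= length_um` expected).
#' @param shape_class One of "sphere", "prolate_spheroid", "cylinder",
#'   "custom" (vectorised).
#' @param custom_factor Multiplier for the custom shape (`V = f * L * W^2`).
#' @return Biovolume, cubic micrometres.
#' @examples
#' biovolume(10, 10, "sphere")            # (pi/6) * 1000
#' biovolume(50, 20, "prolate_spheroid")  # (pi/6) * 50 * 400
#' @export
biovolume <- function(length_um, width_um, shape_class, custom_factor = NULL) {
  known <- c("sphere", "prolate_spheroid", "cylinder", "custom")
  bad <- setdiff(unique(shape_class), known)
  if (length(bad) > 0) {
    abort(paste0("unknown shape_class: ", paste(bad, collapse = ", ")))
  }
  if (any(shape_class == "custom") && is.null(custom_factor)) {
    abort("`custom_factor` is required for shape_class = \"custom\".")
  }
  out <- rep(NA_real_, length(length_um))
  s <- shape_class == "sphere"
  out[s] <- (pi / 6) * length_um[s]^3
  s <- shape_class == "prolate_spheroid"
  out[s] <- (pi / 6) * length_um[s] * width_um[s]^2
  s <- shape_class == "cylinder"
  out[s] <- (pi / 4) * width_um[s]^2 * length_um[s]
  s <- shape_class == "custom"
  if (any(s)) out[s] <- custom_factor * length_um[s] * width_um[s]^2
  out
}

#' Carbon conversion parameters
#'
#' Defaults follow standard conversions for freshwater micro- and meiofauna:
#' protozoan biovolume maps directly to carbon at 0.14 pg C per cubic
#' micrometre; invertebrate biovolume is first converted to fresh mass with a
#' specific gravity (default 1.05 pg/um^3, a standard literature value,
#' configurable), then to dry mass (ratio 0.25) and to carbon (ratio 0.4).
#'
#' @param protozoa_c_per_vol pg C per um^3 for ciliates and flagellates.
#' @param invert_specific_gravity pg fresh mass per um^3 for invertebrates.
#' @param dry_wet_ratio Dry mass / wet mass.
#' @param carbon_dry_ratio Carbon / dry mass.
#' @return A list of class `carbon_params`.
#' @export
carbon_params <- function(protozoa_c_per_vol = 0.14,
                          invert_specific_gravity = 1.05,
                          dry_wet_ratio = 0.25,
                          carbon_dry_ratio = 0.4) {
  vals <- c(protozoa_c_per_vol, invert_specific_gravity, dry_wet_ratio,
            carbon_dry_ratio)
  if (any(vals <= 0 | vals > 2)) abort("carbon parameters must lie in (0, 2].")
  structure(list(protozoa_c_per_vol = protozoa_c_per_vol,
                 invert_specific_gravity = invert_specific_gravity,
                 dry_wet_ratio = dry_wet_ratio,
                 carbon_dry_ratio = carbon_dry_ratio),
            class = "carbon_params")
}

#' Individual carbon content from biovolume
#'
#' @param volume_um3 Biovolume, cubic micrometres (vectorised).
#' @param group "invertebrate", "ciliate" or "flagellate" (vectorised).
#' @param params A [carbon_params()] list.
#' @return Carbon content per individual, pg C.
#' @examples
#' carbon_content(1000, "ciliate")                 # 140 pg C
#' carbon_content(1e6, "invertebrate")             # 1e6 * 1.05 * 0.25 * 0.4
#' @export
carbon_content <- function(volume_um3, group, params = carbon_params()) {
  if (any(volume_um3 < 0)) abort("`volume_um3` must be >= 0.")
  bad <- setdiff(unique(group), c("invertebrate", "ciliate", "flagellate"))
  if (length(bad) > 0) abort(paste("unknown group:", paste(bad, collapse = ", ")))
  ifelse(group == "invertebrate",
         volume_um3 * params$invert_specific_gravity * params$dry_wet_ratio *
           params$carbon_dry_ratio,
         volume_um3 * params$protozoa_c_per_vol)
}

#' Biomass concentration per taxon and layer
#'
#' Multiplies individual carbon content by individual density (count divided
#' by examined sample volume) and converts pg C/L to mg C/L (1 mg = 1e9 pg).
#' Returns one row per (site, condition, date, layer, group, taxon) with the
#' biomass concentration and the mean individual carbon content, which the
#' turnover allometry consumes as body mass.
#'
#' @param measurements Organism-measurement tibble as produced by
#'   [simulate_community()] or [read_count_table()]: columns `site`,
#'   `condition`, `date`, `layer`, `depth_mid_cm`, `taxon`, `group`,
#'   `shape_class`, `length_um`, `width_um`, `count`, `sample_volume_l`.
#' @param params A [carbon_params()] list.
#' @param custom_factor Passed to [biovolume()] for custom shapes.
#' @return A tibble with `biomass_mg_l` (mg C/L), `abundance_l` (ind/L) and
#'   `ind_carbon_pg` (pg C per individual) per taxon-layer record.
#' @export
biomass_concentration <- function(measurements, params = carbon_params(),
                                  custom_factor = NULL) {
  m <- measurements
  if (any(m$sample_volume_l <= 0)) abort("sample volumes must be > 0.")
  vol <- biovolume(m$length_um, m$width_um, m$shape_class, custom_factor)
  cpg <- carbon_content(vol, m$group, params)
  dens <- m$count / m$sample_volume_l
  out <- tibble::tibble(
    site = m$site, condition = m$condition, date = m$date, layer = m$layer,
    depth_mid_cm = m$depth_mid_cm, group = m$group, taxon = m$taxon,
    abundance_l = dens,
    ind_carbon_pg = cpg,
    biomass_mg_l = cpg * dens / 1e9
  )
  dplyr::summarise(
    dplyr::group_by(out, .data$site, .data$condition, .data$date, .data$layer,
                    .data$depth_mid_cm, .data$group, .data$taxon),
    ind_carbon_pg = ifelse(sum(.data$abundance_l) > 0,
                           sum(.data$ind_carbon_pg * .data$abundance_l) /
                             sum(.data$abundance_l),
                           mean(.data$ind_carbon_pg)),
    biomass_mg_l = sum(.data$biomass_mg_l),
    abundance_l = sum(.data$abundance_l),
    .groups = "drop"
  )
}
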