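#' Assemble a pipeline configuration
#'
#' Collects paths and stage parameters for [run_pipeline()]. Can be built
#' from arguments or loaded from a YAML file with the same keys
#' (`pipeline_config_from_yaml()`).
#'
#' @param sensor_log Path to the sensor-log CSV.
#' @param count_table Path to the organism count CSV.
#' @param output_dir Directory for the report bundle.
#' @param thermal List: `kappa_e`, `period_p`, `gamma`, `amp_threshold`,
#'   `classify_tol`.
#' @param carbon A [carbon_params()] list.
#' @param turnover A [turnover_params()] list.
#' @param boundary List: `alpha`, `n_perm`, `mode`, `correction`.
#' @param models List: `n_draws`, `diversity_family`.
#' @param seed Mandatory integer seed for all stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sensor_log, count_table, output_dir,
                            thermal = list(), carbon = carbon_params(),
                            turnover = turnover_params(),
                            boundary = list(), models = list(),
                            seed = 1L) {
  if (is.null(seed)) abort("`seed` is mandatory for stochastic stages.")
  thermal <- utils::modifyList(
    list(kappa_e = 0.05, period_p = 1, gamma = 1, amp_threshold = 0.04,
         classify_tol = 0.01), thermal)
  boundary <- utils::modifyList(
    list(alpha = 0.05, n_perm = 1000, mode = "adjacent",
         correction = "none"), boundary)
  models <- utils::modifyList(
    list(n_draws = 5000, diversity_family = "poisson_log"), models)
  structure(
    list(sensor_log = sensor_log, count_table = count_table,
         output_dir = output_dir, thermal = thermal, carbon = carbon,
         turnover = turnover, boundary = boundary, models = models,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path YAML file with the configuration keys.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    sensor_log = y$sensor_log, count_table = y$count_table,
    output_dir = y$output_dir, thermal = y$thermal %||% list(),
    boundary = y$boundary %||% list(), models = y$models %||% list(),
    seed = y$seed
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full streambed analysis pipeline
#'
#' Executes the stages in field order: harmonic amplitude fitting and
#' flux inversion -> site UW/DW classification -> biomass, secondary
#' production and diversity -> community boundary delineation per condition
#' (with layer clustering) -> mixed models (biomass, production, diversity).
#' Every output is a delimited table under `config$output_dir`, plus a
#' Newick dendrogram per condition and a YAML run log recording package
#' version, configuration hash and seed, which suffices to reproduce the
#' run. Reruns with the same configuration and seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main result objects (`flux`,
#'   `classification`, `biomass`, `production`, `diversity`, `boundaries`,
#'   `models`) and `paths` of everything written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a pipeline_config.")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  paths <- character()

  th <- config$thermal
  sensor <- stage("flux", {
    if (!file.exists(config$sensor_log)) {
      abort(sprintf("sensor log not found: %s", config$sensor_log))
    }
    read_sensor_log(config$sensor_log)
  })
  fits <- stage("flux", fit_diurnal_harmonic(sensor))
  flux <- stage("flux", flux_profile(fits, kappa_e = th$kappa_e,
                                     period_p = th$period_p, gamma = th$gamma,
                                     amp_threshold = th$amp_threshold))
  extinction <- stage("flux", thermal_extinction_depth(fits, th$amp_threshold))
  classification <- stage("classification",
                          classify_sites(flux, tol = th$classify_tol))
  classification <- dplyr::left_join(classification, extinction, by = "site_id")
  readr::write_csv(flux, out("flux.csv"), progress = FALSE)
  readr::write_csv(classification, out("classification.csv"), progress = FALSE)
  paths <- c(paths, out("flux.csv"), out("classification.csv"))

  counts <- stage("community", {
    if (!file.exists(config$count_table)) {
      abort(sprintf("count table not found: %s", config$count_table))
    }
    read_count_table(config$count_table)
  })
  # use measured hydrodynamic condition for downstream grouping
  cond_map <- setNames(classification$condition, classification$site_id)
  meas_cond <- cond_map[as.character(counts$site)]
  counts$condition <- ifelse(is.na(meas_cond), counts$condition, meas_cond)

  biomass <- stage("production", biomass_concentration(counts, config$carbon))
  temps <- stage("production", {
    tl <- layer_temperatures(fits, n_layers = max(counts$layer) + 1L)
    tl$site <- tl$site  # site ids shared between logs and counts
    tl
  })
  prod <- stage("production", production(biomass, temperatures = temps,
                                         params = config$turnover))
  divr <- stage("diversity", diversity_profile(counts))
  readr::write_csv(biomass, out("biomass.csv"), progress = FALSE)
  readr::write_csv(prod, out("production.csv"), progress = FALSE)
  readr::write_csv(divr, out("diversity.csv"), progress = FALSE)
  paths <- c(paths, out("biomass.csv"), out("production.csv"), out("diversity.csv"))

  bd <- config$boundary
  boundaries <- list()
  for (cond in intersect(c("UW", "DW"), unique(counts$condition))) {
    res <- stage("delineate", delineate_boundary(
      counts, cond, alpha = bd$alpha, n_perm = bd$n_perm,
      seed = child_seed(config$seed, match(cond, c("UW", "DW"))),
      mode = bd$mode, correction = bd$correction))
    boundaries[[cond]] <- res
    readr::write_csv(tidy(res), out(sprintf("boundary_%s.csv", cond)),
                     progress = FALSE)
    paths <- c(paths, out(sprintf("boundary_%s.csv", cond)))
    # layer clustering on averaged dissimilarities between strata
    lay <- stage("delineate", layer_mean_dissimilarity(counts, cond))
    if (!any(is.na(lay)) && nrow(lay) >= 3) {
      hc <- cluster_layers(lay)
      cluster_to_newick(hc, out(sprintf("dendrogram_%s.nwk", cond)))
      paths <- c(paths, out(sprintf("dendrogram_%s.nwk", cond)))
    }
  }

  md <- config$models
  analysis <- stage("model", build_analysis_table(biomass, prod, divr))
  models <- stage("model", {
    list(
      biomass = fit_assemblage_model(analysis, "biomass_mg_l",
                                     log10_transform = TRUE),
      production = fit_assemblage_model(analysis, "p_total",
                                        log10_transform = TRUE),
      diversity = fit_assemblage_model(
        dplyr::distinct(analysis, .data$site, .data$condition, .data$depth,
                        .data$date, .data$diversity),
        "diversity", fixed = c("depth", "hydro"),
        family = md$diversity_family)
    )
  })
  for (nm in names(models)) {
    post <- simulate_posterior(models[[nm]], n = md$n_draws,
                               seed = child_seed(config$seed, 10 + match(nm, names(models))))
    tab <- post$summary
    tab$response <- nm
    readr::write_csv(tab, out(sprintf("model_%s.csv", nm)), progress = FALSE)
    paths <- c(paths, out(sprintf("model_%s.csv", nm)))
  }

  log <- list(
    package = "hyporheos",
    version = as.character(utils::packageVersion("hyporheos")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    inputs = list(sensor_log = config$sensor_log,
                  count_table = config$count_table),
    outputs = basename(paths)
  )
  yaml::write_yaml(log, out("run_log.yml"))
  paths <- c(paths, out("run_log.yml"))

  invisible(list(flux = flux, classification = classification,
                 biomass = biomass, production = prod, diversity = divr,
                 boundaries = boundaries, models = models, paths = paths))
}

# averaged Bray-Curtis dissimilarity between strata (labels = layer index),
# averaging over all replicate cross-pairs
layer_mean_dissimilarity <- function(counts, condition) {
  cc <- dplyr::filter(counts, .data$condition == !!condition)
  ab <- dplyr::summarise(
    dplyr::group_by(cc, .data$layer, .data$site, .data$date, .data$taxon),
    abundance_l = sum(.data$count / .data$sample_volume_l),
    .groups = "drop"
  )
  taxa <- sort(unique(ab$taxon))
  layers <- sort(unique(ab$layer))
  mats <- lapply(layers, function(k) {
    sub <- dplyr::filter(ab, .data$layer == k)
    sub$rep_id <- paste(sub$site, sub$date, sep = "|")
    wide <- tidyr::pivot_wider(sub[, c("rep_id", "taxon", "abundance_l")],
                               names_from = "taxon", values_from = "abundance_l",
                               values_fill = 0)
    m <- as.matrix(wide[, -1, drop = FALSE])
    miss <- setdiff(taxa, colnames(m))
    if (length(miss) > 0) m <- cbind(m, matrix(0, nrow(m), length(miss),
                                               dimnames = list(NULL, miss)))
    m[, taxa, drop = FALSE]
  })
  n <- length(layers)
  d <- matrix(0, n, n, dimnames = list(paste0("L", layers), paste0("L", layers)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- bc_between_mean(mats[[i]], mats[[j]])
    }
  }
  d
}

# tidy analysis table joining biomass, production and diversity per
# (site, condition, depth midpoint, group, date)
build_analysis_table <- function(biomass, prod, divr) {
  b <- dplyr::summarise(
    dplyr::group_by(biomass, .data$site, .data$condition, .data$date,
                    .data$layer, .data$depth_mid_cm, .data$group),
    biomass_mg_l = sum(.data$biomass_mg_l), .groups = "drop"
  )
  p <- dplyr::distinct(prod, .data$site, .data$condition, .data$layer,
                       .data$group, .data$p_total)
  d <- divr[, c("site", "condition", "date", "layer", "diversity")]
  out <- dplyr::left_join(b, p, by = c("site", "condition", "layer", "group"))
  out <- dplyr::left_join(out, d, by = c("site", "condition", "date", "layer"))
  out$depth <- out$depth_mid_cm
  out
}
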