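#' Read a temperature sensor log
#'
#' Reads the delimited sensor-log format: comma-separated, UTF-8, header
#' `site_id, depth_cm, timestamp_iso, temp_c`, ISO-8601 timestamps (UTC),
#' signed depths in cm (positive downward). Each (site, depth) series is
#' validated: timestamps must parse, (site, depth, timestamp) must be
#' unique, and irregular spacing is flagged in the `gap` column (TRUE on
#' observations whose spacing from the previous one differs from the series'
#' modal cadence).
#'
#' @param path CSV file path.
#' @return A tibble `site_id`, `depth_cm`, `timestamp` (POSIXct UTC),
#'   `temp_c`, `gap`.
#' @export
read_sensor_log <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(),
    depth_cm = readr::col_double(),
    timestamp_iso = readr::col_character(),
    temp_c = readr::col_double()
  ), progress = FALSE)
  req <- c("site_id", "depth_cm", "timestamp_iso", "temp_c")
  if (!all(req %in% names(raw))) {
    abort(paste("sensor log must have columns:", paste(req, collapse = ", ")))
  }
  ts <- as.POSIXct(strptime(raw$timestamp_iso, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- is.na(ts)
  if (any(alt)) {
    ts[alt] <- as.POSIXct(strptime(raw$timestamp_iso[alt],
                                   "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  }
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    abort(sprintf("unparseable timestamp at data line %d: '%s'",
                  bad[1], raw$timestamp_iso[bad[1]]))
  }
  key <- paste(raw$site_id, raw$depth_cm, raw$timestamp_iso)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(sprintf("duplicate (site, depth, timestamp) at data line %d.", dup[1]))
  }
  out <- tibble::tibble(site_id = raw$site_id, depth_cm = raw$depth_cm,
                        timestamp = ts, temp_c = raw$temp_c)
  out <- dplyr::arrange(out, .data$site_id, .data$depth_cm, .data$timestamp)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$site_id, .data$depth_cm),
    gap = {
      dt <- diff(as.numeric(.data$timestamp))
      if (length(dt) == 0) FALSE else {
        cadence <- as.numeric(names(sort(table(dt), decreasing = TRUE))[1])
        c(FALSE, abs(dt - cadence) > 1e-6)
      }
    }
  )
  dplyr::ungroup(out)
}

#' Write a temperature sensor log
#'
#' @param data Tibble with `site_id`, `depth_cm`, `timestamp`, `temp_c`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensor_log <- function(data, path) {
  out <- tibble::tibble(
    site_id = data$site_id,
    depth_cm = data$depth_cm,
    timestamp_iso = format(data$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    temp_c = data$temp_c
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an organism count table
#'
#' Reads the delimited organism-measurement format with columns `site`,
#' `condition`, `date`, `layer` (stratum index 0-6 or a depth range such as
#' "5-10"), `taxon`, `group`, `shape_class`, `length_um`, `width_um`,
#' `count`, `sample_volume_l`. Unknown taxa are allowed; unknown groups,
#' negative counts and width exceeding length are hard errors.
#'
#' @param path CSV file path.
#' @return A validated tibble in the layout of [simulate_community()].
#' @export
read_count_table <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    site = readr::col_character(), condition = readr::col_character(),
    date = readr::col_date(), layer = readr::col_character(),
    taxon = readr::col_character(), group = readr::col_character(),
    shape_class = readr::col_character(), length_um = readr::col_double(),
    width_um = readr::col_double(), count = readr::col_double(),
    sample_volume_l = readr::col_double()
  ), progress = FALSE)
  layer <- ifelse(grepl("-", raw$layer),
                  as.integer(vapply(strsplit(raw$layer, "-"),
                                    function(p) as.numeric(p[1]), 1)) %/% 5L,
                  suppressWarnings(as.integer(raw$layer)))
  if (anyNA(layer)) {
    abort(sprintf("unparseable layer at data line %d: '%s'",
                  which(is.na(layer))[1], raw$layer[which(is.na(layer))[1]]))
  }
  bad_g <- which(!raw$group %in% c("invertebrate", "ciliate", "flagellate"))
  if (length(bad_g) > 0) {
    abort(sprintf("unknown group at data line %d: '%s'",
                  bad_g[1], raw$group[bad_g[1]]))
  }
  if (any(raw$count < 0)) {
    abort(sprintf("negative count at data line %d.", which(raw$count < 0)[1]))
  }
  if (any(raw$width_um > raw$length_um)) {
    abort(sprintf("width exceeds length at data line %d.",
                  which(raw$width_um > raw$length_um)[1]))
  }
  if (any(raw$sample_volume_l <= 0)) {
    abort("sample volumes must be > 0.")
  }
  tibble::tibble(
    site = raw$site, condition = raw$condition, date = raw$date,
    layer = layer, depth_mid_cm = layer * 5 + 2.5,
    taxon = raw$taxon, group = raw$group, shape_class = raw$shape_class,
    length_um = raw$length_um, width_um = raw$width_um, count = raw$count,
    sample_volume_l = raw$sample_volume_l,
    abundance_l = raw$count / raw$sample_volume_l
  )
}

#' Write an organism count table
#'
#' @param counts Tibble in the layout of [simulate_community()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  out <- tibble::tibble(
    site = as.character(counts$site), condition = counts$condition,
    date = counts$date, layer = counts$layer, taxon = counts$taxon,
    group = counts$group, shape_class = counts$shape_class,
    length_um = counts$length_um, width_um = counts$width_um,
    count = counts$count, sample_volume_l = counts$sample_volume_l
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a complete synthetic fixture to disk
#'
#' Materialises a demo study: one sensor log per thermal scenario, one count
#' table from the community scenario, a ground-truth sidecar (site, true
#' velocity, condition, true boundary depth, group decay rates) and a YAML
#' manifest. The default arguments reproduce the standard campaign: six
#' sites, alternating UW/DW, four weekly sampling dates, seven 5-cm layers.
#'
#' @param dir Output directory (created if needed).
#' @param thermal_scenarios List of [thermal_scenario()] objects (one per
#'   site); `NULL` builds the default six-site set.
#' @param community A [community_scenario()]; `NULL` uses the default.
#' @param seed Integer seed used to derive per-site scenario seeds when the
#'   defaults are built.
#' @return Invisibly, a list of written paths.
#' @export
write_fixture <- function(dir, thermal_scenarios = NULL, community = NULL,
                          seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(thermal_scenarios) && is.null(community)) {
    def <- default_study(seed)
    thermal_scenarios <- def$thermal
    community <- def$community
  }
  paths <- list()
  if (!is.null(thermal_scenarios) && length(thermal_scenarios) > 0) {
    sensor <- dplyr::bind_rows(lapply(thermal_scenarios, simulate_temperature))
    paths$sensor_log <- file.path(dir, "sensor_log.csv")
    write_sensor_log(sensor, paths$sensor_log)
    truth <- tibble::tibble(
      site = vapply(thermal_scenarios, function(s) s$site_id, ""),
      true_velocity = vapply(thermal_scenarios, function(s) s$velocity_v, 1),
      condition = ifelse(vapply(thermal_scenarios,
                                function(s) s$velocity_v, 1) >= 0, "DW", "UW")
    )
  } else {
    truth <- tibble::tibble(site = character(), true_velocity = numeric(),
                            condition = character())
  }
  if (!is.null(community)) {
    counts <- simulate_community(community)
    paths$counts <- file.path(dir, "counts.csv")
    write_count_table(counts, paths$counts)
    bt <- community$boundary_depth
    truth$true_boundary_cm <- if (nrow(truth) > 0) {
      bt[truth$condition]
    } else {
      numeric()
    }
  }
  paths$ground_truth <- file.path(dir, "ground_truth.csv")
  readr::write_csv(truth, paths$ground_truth, progress = FALSE)
  manifest <- list(
    files = lapply(paths, basename),
    n_thermal_scenarios = length(thermal_scenarios),
    has_community = !is.null(community),
    seed = seed
  )
  paths$manifest <- file.path(dir, "manifest.yml")
  yaml::write_yaml(manifest, paths$manifest)
  invisible(paths)
}

#' Default six-site demo study
#'
#' Standard campaign used by [write_fixture()] and [run_pipeline()] demos:
#' sites 1, 3, 5 upwelling (negative velocities) and 2, 4, 6 downwelling
#' (positive), moderate flux magnitudes (0.2-0.4 m/day), four weekly
#' sampling dates, seven 5-cm layers, boundaries at 10 cm (UW) and 15 cm
#' (DW).
#'
#' @param seed Integer seed.
#' @return A list with `thermal` (list of six [thermal_scenario()]) and
#'   `community` (a [community_scenario()]).
#' @export
default_study <- function(seed = 1L) {
  v <- c(-0.3, 0.3, -0.2, 0.4, -0.4, 0.2)  # sites 1..6, UW negative
  thermal <- lapply(seq_along(v), function(i) {
    thermal_scenario(velocity_v = v[i], site_id = as.character(i),
                     seed = child_seed(seed, i))
  })
  community <- community_scenario(
    n_sites = 6,
    conditions = ifelse(v >= 0, "DW", "UW"),
    seed = child_seed(seed, 100)
  )
  list(thermal = thermal, community = community)
}
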