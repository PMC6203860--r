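#' Delineate the benthic/hyporheic community boundary
#'
#' Scans adjacent 5-cm stratum pairs from the surface downward and tests, per
#' pair, whether the assemblages of the upper and lower stratum differ by
#' ANOSIM on Bray-Curtis dissimilarities. Replicates are the (site, date)
#' samples within the focal hydrodynamic condition. The community boundary is
#' placed at the shallowest pair whose test is significant; the averaged
#' Bray-Curtis similarity (1 - mean between-stratum dissimilarity) at that
#' pair is reported. In `mode = "cumulative"` the upper group pools all
#' strata above the candidate interface instead of only the one adjacent
#' stratum.
#'
#' Strata in which every replicate is empty terminate the scan (with a
#' warning): below the colonised zone the comparison is undefined.
#'
#' @param counts Organism-measurement tibble (one condition or more; rows
#'   are filtered to `condition`).
#' @param condition "UW" or "DW".
#' @param alpha Significance level.
#' @param n_perm Permutations per pair test.
#' @param seed Integer seed; pair tests use derived child seeds.
#' @param mode "adjacent" (default) or "cumulative" upper group.
#' @param correction "none" (default, mirrors the uncorrected scan) or
#'   "holm" across the scanned pairs.
#' @return An object of class `boundary_result`: list with `condition`,
#'   `boundary` (tibble row of the detected pair, or NULL), `pairs` (per-pair
#'   tibble: strata, depths, R, p, significant), `alpha`, `mode`.
#' @examples
#' sc <- community_scenario(n_sites = 4, conditions = rep("UW", 4),
#'                          n_dates = 3, turnover_sharpness = 3, seed = 2)
#' comm <- simulate_community(sc)
#' delineate_boundary(comm, "UW", n_perm = 199, seed = 9)
#' @export
delineate_boundary <- function(counts, condition, alpha = 0.05,
                               n_perm = 1000, seed = NULL,
                               mode = c("adjacent", "cumulative"),
                               correction = c("none", "holm")) {
  mode <- match.arg(mode)
  correction <- match.arg(correction)
  cc <- dplyr::filter(counts, .data$condition == !!condition)
  if (nrow(cc) == 0) abort(sprintf("no rows for condition '%s'.", condition))

  # replicate (site x date) by taxon abundance matrix per stratum
  ab <- dplyr::summarise(
    dplyr::group_by(cc, .data$layer, .data$site, .data$date, .data$taxon),
    abundance_l = sum(.data$count / .data$sample_volume_l),
    .groups = "drop"
  )
  taxa <- sort(unique(ab$taxon))
  layers <- sort(unique(ab$layer))
  strat_mat <- lapply(layers, function(k) {
    sub <- dplyr::filter(ab, .data$layer == k)
    sub$rep_id <- paste(sub$site, sub$date, sep = "|")
    wide <- tidyr::pivot_wider(sub[, c("rep_id", "taxon", "abundance_l")],
                               names_from = "taxon",
                               values_from = "abundance_l",
                               values_fill = 0)
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$rep_id
    miss <- setdiff(taxa, colnames(m))
    if (length(miss) > 0) {
      m <- cbind(m, matrix(0, nrow(m), length(miss),
                           dimnames = list(NULL, miss)))
    }
    m[, taxa, drop = FALSE]
  })
  names(strat_mat) <- layers

  # truncate the scan at the first stratum where all replicates are empty
  occupied <- vapply(strat_mat, function(m) any(rowSums(m) > 0), logical(1))
  if (!all(occupied)) {
    first_empty <- which(!occupied)[1]
    if (first_empty <= 2) abort("the two shallowest strata are empty; nothing to scan.")
    warn(sprintf("strata below index %d are empty; scan truncated.",
                 layers[first_empty - 1]))
    layers <- layers[seq_len(first_empty - 1)]
    strat_mat <- strat_mat[seq_len(first_empty - 1)]
  }
  n_rep <- vapply(strat_mat, nrow, 1L)
  if (any(n_rep < 2)) abort("need >= 2 replicate samples per stratum.")

  rows <- list()
  for (k in seq_len(length(layers) - 1L)) {
    upper_idx <- if (mode == "adjacent") k else seq_len(k)
    upper <- do.call(rbind, strat_mat[upper_idx])
    lower <- strat_mat[[k + 1]]
    m <- rbind(upper, lower)
    g <- c(rep("upper", nrow(upper)), rep("lower", nrow(lower)))
    res <- anosim(bray_curtis_matrix(m), g, n_perm = n_perm,
                  seed = child_seed(seed, k), alpha = alpha)
    between <- bc_between_mean(strat_mat[[k]], lower)
    rows[[k]] <- tibble::tibble(
      pair = k,
      upper_stratum = layers[k],
      lower_stratum = layers[k + 1],
      interface_depth_cm = 5 * layers[k + 1],
      statistic = res$statistic,
      p_value = res$p_value,
      mean_similarity = 1 - between
    )
  }
  pairs <- dplyr::bind_rows(rows)
  p_adj <- if (correction == "holm") stats::p.adjust(pairs$p_value, "holm") else pairs$p_value
  pairs$significant <- p_adj < alpha
  hit <- which(pairs$significant)
  boundary <- if (length(hit) > 0) pairs[hit[1], ] else NULL
  structure(
    list(condition = condition, boundary = boundary, pairs = pairs,
         alpha = alpha, mode = mode, n_perm = n_perm, seed = seed),
    class = "boundary_result"
  )
}

# mean defined Bray-Curtis dissimilarity between all cross-stratum pairs
bc_between_mean <- function(a, b) {
  vals <- c(outer(seq_len(nrow(a)), seq_len(nrow(b)),
                  Vectorize(function(i, j) bray_curtis(a[i, ], b[j, ]))))
  mean(vals, na.rm = TRUE)
}

#' @export
print.boundary_result <- function(x, ...) {
  cat("<boundary_result>", x$condition, "mode =", x$mode, "\n")
  if (is.null(x$boundary)) {
    cat("  no significant boundary detected at alpha =", x$alpha, "\n")
  } else {
    cat(sprintf("  boundary at the %d-cm interface (strata %d | %d), R = %.3f, p = %.4f\n",
                x$boundary$interface_depth_cm, x$boundary$upper_stratum,
                x$boundary$lower_stratum, x$boundary$statistic,
                x$boundary$p_value))
    cat(sprintf("  mean Bray-Curtis similarity across the boundary pair: %.2f\n",
                x$boundary$mean_similarity))
  }
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.boundary_result <- function(x, ...) {
  out <- x$pairs
  out$condition <- x$condition
  out[, c("condition", setdiff(names(out), "condition"))]
}

#' Agglomerative clustering of layers by average Bray-Curtis similarity
#'
#' UPGMA (average-linkage) clustering of a dissimilarity matrix, used to
#' group depth strata by their averaged Bray-Curtis similarity. Undefined
#' entries are refused rather than imputed.
#'
#' @param d Symmetric dissimilarity matrix with labels.
#' @return An `hclust` tree.
#' @export
cluster_layers <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) abort("need >= 3 labels to cluster.")
  if (any(is.na(d))) abort("dissimilarity matrix contains undefined entries; not imputing.")
  hclust(as.dist(d), method = "average")
}

#' Serialise an hclust tree as Newick
#'
#' @param hc An `hclust` object (e.g. from [cluster_layers()]).
#' @param file Optional path; when given the string is also written there.
#' @return The Newick string, invisibly when writing to file.
#' @export
cluster_to_newick <- function(hc, file = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("the 'ape' package is required for Newick export.")
  }
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
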