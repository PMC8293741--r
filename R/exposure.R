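#' Species-richness overlay map
#'
#' Cellwise sum of the individual binary suitability maps: each cell counts
#' the species for which it is suitable. A cell is missing only where every
#' input is missing; a species' missing cells contribute 0 elsewhere.
#'
#' @param binaries Non-empty list of `binary_suitability_map`s (or binary
#'   `raster_layer`s) on one grid.
#' @return A `raster_layer` of counts `0..n_species`.
#' @export
richness_map <- function(binaries) {
  if (!length(binaries)) stop("richness_map needs at least one binary map")
  layers <- lapply(binaries, function(b)
    if (inherits(b, "binary_suitability_map")) b$map else b)
  g <- layers[[1]]$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  any_ok <- matrix(FALSE, g$n_rows, g$n_cols)
  for (l in layers) {
    check_same_grid(g, l$grid)
    ok <- !is.na(l$values)
    acc[ok] <- acc[ok] + l$values[ok]
    any_ok <- any_ok | ok
  }
  acc[!any_ok] <- NA_real_
  raster_layer(g, acc, "richness")
}

#' Per-species exposure and protection summary
#'
#' Overlays one species' binary suitable range with the classified threat
#' map and the protected-area polygons: area (km^2) of the range in each
#' threat class, the class fractions, and the protected fraction (by
#' cell-centre membership). Suitable cells whose threat class is missing
#' (e.g. urban-masked) are reported under `Unclassified` so areas always
#' partition the total.
#'
#' @param binary A `binary_suitability_map` (or binary `raster_layer`).
#' @param classes Classified threat `raster_layer` (codes 1-4, from
#'   [classify_index()]).
#' @param pas Protected areas as a [polygon_set()], or a precomputed
#'   membership `raster_layer`.
#' @return An `exposure_summary`: `species`, `total_suitable_km2`,
#'   `area_by_class`, `fraction_by_class`, `protected_km2`,
#'   `protected_fraction`.
#' @export
exposure_summary <- function(binary, classes, pas) {
  species <- if (inherits(binary, "binary_suitability_map")) binary$species else "species"
  bmap <- if (inherits(binary, "binary_suitability_map")) binary$map else binary
  g <- bmap$grid
  check_same_grid(g, classes$grid)
  pa_layer <- if (inherits(pas, "polygon_set")) rasterize(pas, g) else pas
  check_same_grid(g, pa_layer$grid)
  suit <- !is.na(bmap$values) & bmap$values == 1
  if (!any(suit)) stop("species has no suitable cells")
  cell_km2 <- (g$cell_size / 1000)^2
  cls <- classes$values[suit]
  buckets <- c(threat_class_levels, "Unclassified")
  counts <- stats::setNames(numeric(5), buckets)
  for (k in 1:4) counts[k] <- sum(cls == k, na.rm = TRUE)
  counts["Unclassified"] <- sum(is.na(cls))
  total <- sum(suit)
  prot <- sum(pa_layer$values[suit] == 1, na.rm = TRUE)
  out <- list(species = species,
              total_suitable_km2 = total * cell_km2,
              area_by_class = counts * cell_km2,
              fraction_by_class = counts / total,
              protected_km2 = prot * cell_km2,
              protected_fraction = prot / total)
  stopifnot(abs(sum(out$area_by_class) - out$total_suitable_km2) < 1e-9,
            abs(sum(out$fraction_by_class) - 1) < 1e-9,
            out$protected_fraction >= 0, out$protected_fraction <= 1)
  structure(out, class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("<exposure_summary> %s: %.0f km2 suitable, %.1f%% protected\n",
              x$species, x$total_suitable_km2, 100 * x$protected_fraction))
  pct <- 100 * x$fraction_by_class
  cat(paste(sprintf("  %s: %.1f%%", names(pct), pct), collapse = "\n"), "\n")
  invisible(x)
}

#' Threat-class profile of the protected-area network
#'
#' Distribution of threat classes over protected-area cells (cell-centre
#' membership); fractions sum to 1 over classified PA cells.
#'
#' @param classes Classified threat `raster_layer` (codes 1-4).
#' @param pas A [polygon_set()] or membership `raster_layer`.
#' @return Named numeric vector of fractions per class.
#' @export
pa_class_profile <- function(classes, pas) {
  g <- classes$grid
  pa_layer <- if (inherits(pas, "polygon_set")) rasterize(pas, g) else pas
  check_same_grid(g, pa_layer$grid)
  inside <- pa_layer$values == 1 & !is.na(pa_layer$values)
  cls <- classes$values[inside]
  cls <- cls[!is.na(cls)]
  if (!length(cls)) stop("no classified protected-area cells")
  frac <- stats::setNames(numeric(4), threat_class_levels)
  for (k in 1:4) frac[k] <- mean(cls == k)
  frac
}

#' Tabulate exposure summaries for several species
#'
#' @param summaries List of `exposure_summary` objects.
#' @return Data frame with one row per species (areas in km^2, protection in
#'   percent).
#' @export
exposure_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) data.frame(
    species = s$species,
    total_km2 = s$total_suitable_km2,
    km2_low = s$area_by_class[["Low"]],
    km2_moderate = s$area_by_class[["Moderate"]],
    km2_high = s$area_by_class[["High"]],
    km2_veryhigh = s$area_by_class[["VeryHigh"]],
    km2_unclassified = s$area_by_class[["Unclassified"]],
    pct_protected = 100 * s$protected_fraction)))
}
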