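#' Threat-index scenario parameter bundles
#'
#' The eight threat factors are scored on a 0-10 scale under a named
#' scenario. `reference` holds the literature-based thresholds; `highest`
#' makes every threshold stricter (more area at maximum threat) and
#' `lowest` looser, bounding the sensitivity of the index to those choices:
#'
#' | parameter               | reference | highest | lowest |
#' |-------------------------|-----------|---------|--------|
#' | pop_saturation (p/km^2) | 1000      | 800     | 1200   |
#' | crop_cutoff (fraction)  | 0.20      | 0.15    | 0.25   |
#' | road_buffer_km          | 20        | 25      | 15     |
#' | overexploit_margin      | 0         | -0.10   | +0.10  |
#' | treeloss_cutoff         | 0.20      | 0.15    | 0.25   |
#' | burn_buffer_km          | 5         | 10      | 0      |
#' | temp_saturation_C       | 2.0       | 1.5     | 2.5    |
#' | precip_saturation_mm    | 200       | 150     | 250    |
#'
#' @param name `"reference"`, `"highest"` or `"lowest"`.
#' @return A `threat_scenario` (named list of the eight parameters).
#' @export
threat_scenario <- function(name = c("reference", "highest", "lowest")) {
  name <- match.arg(name)
  p <- switch(name,
    reference = list(pop_saturation = 1000, crop_cutoff = 0.20,
                     road_buffer_km = 20, overexploit_margin = 0,
                     treeloss_cutoff = 0.20, burn_buffer_km = 5,
                     temp_saturation_C = 2.0, precip_saturation_mm = 200),
    highest   = list(pop_saturation = 800, crop_cutoff = 0.15,
                     road_buffer_km = 25, overexploit_margin = -0.10,
                     treeloss_cutoff = 0.15, burn_buffer_km = 10,
                     temp_saturation_C = 1.5, precip_saturation_mm = 150),
    lowest    = list(pop_saturation = 1200, crop_cutoff = 0.25,
                     road_buffer_km = 15, overexploit_margin = 0.10,
                     treeloss_cutoff = 0.25, burn_buffer_km = 0,
                     temp_saturation_C = 2.5, precip_saturation_mm = 250))
  structure(c(list(name = name), p), class = "threat_scenario")
}

#' Population-pressure score
#'
#' Human pressure grows logarithmically with population density and
#' saturates at `saturation` persons/km^2:
#' `score = min(10, 10 / log10(saturation + 1) * log10(density + 1))`.
#' The coefficient is derived from the saturation level so the score reaches
#' exactly 10 at saturation under every scenario (at the reference
#' saturation of 1,000 the coefficient is 10/log10(1001) = 3.333). Density 0
#' scores 0.
#'
#' @param density `raster_layer` of population density (persons/km^2, >= 0).
#' @param saturation Saturation density (persons/km^2).
#' @return A `raster_layer` of scores in `[0, 10]`.
#' @export
score_population <- function(density, saturation = 1000) {
  stopifnot(inherits(density, "raster_layer"), saturation > 0)
  v <- density$values
  if (any(v < 0, na.rm = TRUE)) stop("population density must be >= 0")
  coef <- 10 / log10(saturation + 1)
  out <- pmin(coef * log10(v + 1), 10)   # matrix first: pmin keeps its dims
  raster_layer(density$grid, out, "population_score")
}

#' Threshold score for fractional-cover layers
#'
#' Scores cropland-cover and tree-cover-loss factors: cells whose fraction
#' meets or exceeds the cutoff score 10, all others 0.
#'
#' @param fraction `raster_layer` with values in `[0, 1]`.
#' @param cutoff Fraction cutoff, strictly inside `(0, 1)`.
#' @return A `raster_layer` with values `{0, 10}`.
#' @export
score_threshold_layer <- function(fraction, cutoff) {
  stopifnot(inherits(fraction, "raster_layer"))
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie strictly inside (0, 1)")
  v <- fraction$values
  if (any(v < 0 | v > 1, na.rm = TRUE)) stop("fractions must lie in [0, 1]")
  raster_layer(fraction$grid, ifelse(is.na(v), NA_real_, 10 * (v >= cutoff)),
               "threshold_score")
}

#' Road-proximity score
#'
#' Habitat conversion concentrates near roads: cells within `buffer_km` of a
#' primary/secondary road score 10 (roads rasterised to their cell trace,
#' then centre-to-centre buffered), all others 0. `buffer_km = 0` scores
#' only the road-intersecting cells.
#'
#' @param roads A [polyline_set()] in the grid CRS.
#' @param grid A [grid_spec()].
#' @param buffer_km Buffer distance in km.
#' @return A `raster_layer` with values `{0, 10}`.
#' @export
score_roads <- function(roads, grid, buffer_km = 20) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!length(roads$lines)) {
    warning("empty road set: road score is zero everywhere")
    return(raster_layer(grid, 0, "road_score"))
  }
  r <- rasterize_lines(roads, grid)
  b <- buffer_mask(r, buffer_km * 1000)
  raster_layer(grid, b$values * 10, "road_score")
}

#' Overexploitation score by province
#'
#' A province where the licensed timber-extraction volume exceeds the
#' adequate harvesting volume scores 10 for all its cells:
#' `licensed > adequate * (1 + margin)`. The sensitivity margins shift the
#' adequate volume by -10% (`highest`) or +10% (`lowest`).
#'
#' @param provinces A [polygon_set()] whose features carry numeric
#'   `licensed` and `adequate` attributes (volumes >= 0).
#' @param grid A [grid_spec()].
#' @param margin Overexploitation margin (fraction; 0, -0.10 or +0.10).
#' @return A `raster_layer` with values `{0, 10}` (missing outside all
#'   provinces).
#' @export
score_overexploitation <- function(provinces, grid, margin = 0) {
  stopifnot(inherits(provinces, "polygon_set"), inherits(grid, "grid_spec"))
  feats <- lapply(provinces$features, function(f) {
    lic <- f$attributes$licensed; ade <- f$attributes$adequate
    if (is.null(lic) || is.null(ade))
      stop("province '", f$id, "' lacks licensed/adequate volumes")
    if (lic < 0 || ade < 0) stop("volumes must be >= 0")
    f$attributes$overexploited <- 10 * (lic > ade * (1 + margin))
    f
  })
  out <- rasterize(polygon_set(feats), grid, attribute = "overexploited")
  raster_layer(grid, out$values, "overexploitation_score")
}

#' Burned-area-trend score
#'
#' Cells with a significant increasing trend of annual burned area, plus a
#' buffer (default 5 km; the lowest-threat scenario uses no buffer), score
#' 10.
#'
#' @param trend Binary `raster_layer` (`{0, 1, NA}`) of significant
#'   increasing-trend cells.
#' @param buffer_km Buffer distance in km (0 disables buffering).
#' @return A `raster_layer` with values `{0, 10}`.
#' @export
score_burn_trend <- function(trend, buffer_km = 5) {
  stopifnot(inherits(trend, "raster_layer"))
  if (!all(trend$values %in% c(0, 1) | is.na(trend$values)))
    stop("trend layer must be binary {0, 1}")
  b <- if (buffer_km > 0) buffer_mask(trend, buffer_km * 1000) else trend
  raster_layer(trend$grid, b$values * 10, "burn_trend_score")
}

#' Climate-change pressure score
#'
#' Pressure rises linearly with the absolute amplitude of projected change
#' (future mean minus current), reaching 10 at the saturation amplitude:
#' `score = min(10, |future - current| / saturation * 10)`. Saturation is
#' 2 deg C for temperature and 200 mm for precipitation in the reference
#' scenario.
#'
#' @param current,future_mean Aligned `raster_layer`s.
#' @param saturation Amplitude at which the score saturates (> 0), in the
#'   layer's units.
#' @return A `raster_layer` of scores in `[0, 10]`.
#' @export
score_climate_delta <- function(current, future_mean, saturation) {
  stopifnot(inherits(current, "raster_layer"),
            inherits(future_mean, "raster_layer"), saturation > 0)
  check_same_grid(current$grid, future_mean$grid)
  amp <- abs(future_mean$values - current$values)
  raster_layer(current$grid, pmin(amp / saturation * 10, 10), "climate_score")
}

#' Cellwise mean of future-climate model layers
#'
#' The future climate surface is the multi-model mean of the supplied
#' projection layers.
#'
#' @param layers Non-empty list of aligned `raster_layer`s.
#' @return A `raster_layer`.
#' @export
mean_future <- function(layers) {
  if (!length(layers)) stop("mean_future needs at least one layer")
  g <- layers[[1]]$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  for (l in layers) { check_same_grid(g, l$grid); acc <- acc + l$values }
  raster_layer(g, acc / length(layers), "future_mean")
}

#' Sum the eight factor scores into the threat index
#'
#' The standardised 0-10 factor scores are summed cellwise into the 0-80
#' threat index. A factor missing in a cell contributes 0 there (factors are
#' only assembled where coverage exists), with a per-layer missing-cell
#' count reported; urban cells are masked to missing afterwards.
#'
#' @param layer_scores Named list of exactly 8 `raster_layer`s, each in
#'   `[0, 10]`.
#' @param urban Binary urban mask `raster_layer` on the same grid.
#' @return A `raster_layer` (the index, `[0, 80]`).
#' @export
sum_index <- function(layer_scores, urban) {
  if (length(layer_scores) != 8L)
    stop("the threat index sums exactly 8 factor scores, got ", length(layer_scores))
  g <- layer_scores[[1]]$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  for (nm in names(layer_scores)) {
    l <- layer_scores[[nm]]
    check_same_grid(g, l$grid)
    v <- l$values
    if (any(v < 0 | v > 10, na.rm = TRUE))
      stop("factor '", nm, "' has scores outside [0, 10]")
    n_miss <- sum(is.na(v))
    if (n_miss > 0) {
      message("sum_index: factor '", nm, "' missing in ", n_miss,
              " cell(s); contributing 0 there")
      v[is.na(v)] <- 0
    }
    acc <- acc + v
  }
  apply_urban_mask(raster_layer(g, acc, "threat_index"), urban)
}

threat_class_levels <- c("Low", "Moderate", "High", "VeryHigh")

#' Classify the threat index into four classes
#'
#' Fixed equal-width bands of the 0-80 index: Low `[0, 20)`, Moderate
#' `[20, 40)`, High `[40, 60]`, Very high `(60, 80]`. (The boundary at 60
#' belongs to High so that both printed class labels "40-60" and ">60" are
#' honoured.)
#'
#' @param index `raster_layer` with values in `[0, 80]`.
#' @return A `raster_layer` of class codes 1-4 with a `"levels"` attribute
#'   (`Low`, `Moderate`, `High`, `VeryHigh`).
#' @export
classify_index <- function(index) {
  stopifnot(inherits(index, "raster_layer"))
  v <- index$values
  if (any(v < 0 | v > 80, na.rm = TRUE)) stop("index values must lie in [0, 80]")
  code <- ifelse(is.na(v), NA_real_,
                 ifelse(v < 20, 1, ifelse(v < 40, 2, ifelse(v <= 60, 3, 4))))
  out <- raster_layer(index$grid, code, "threat_class")
  attr(out, "levels") <- threat_class_levels
  out
}

#' Compare two classified threat maps
#'
#' Sensitivity summary over cells non-missing in both maps: the percentage
#' of cells that changed class, split into increases and decreases
#' (`changed = increased + decreased`).
#'
#' @param reference,alternate Classified `raster_layer`s (codes 1-4) on one
#'   grid with one category order.
#' @return List with `changed`, `increased`, `decreased` (percent).
#' @export
sensitivity_compare <- function(reference, alternate) {
  stopifnot(inherits(reference, "raster_layer"), inherits(alternate, "raster_layer"))
  check_same_grid(reference$grid, alternate$grid)
  a <- reference$values; b <- alternate$values
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0) stop("no cells are non-missing in both maps")
  inc <- sum(b[ok] > a[ok]); dec <- sum(b[ok] < a[ok])
  list(changed = 100 * (inc + dec) / n,
       increased = 100 * inc / n,
       decreased = 100 * dec / n)
}

#' Build the full threat-index map for a scenario
#'
#' Scores all eight factors under the given scenario, sums them, classifies
#' the result, and returns everything.
#'
#' @param factors Named list of factor inputs: `population` (density
#'   raster), `cropland`, `treeloss` (fraction rasters), `roads`
#'   ([polyline_set()]), `provinces` ([polygon_set()] with
#'   `licensed`/`adequate`), `burn_trend` (binary raster), `temp_current`,
#'   `precip_current` (rasters), `temp_future`, `precip_future` (lists of
#'   projection rasters), `urban` (binary raster).
#' @param scenario A [threat_scenario()] or scenario name.
#' @return A `threat_index_map`: `scenario`, `layer_scores` (8 rasters),
#'   `index` (0-80 raster), `classes` (coded raster).
#' @export
threat_index_map <- function(factors, scenario = "reference") {
  if (is.character(scenario)) scenario <- threat_scenario(scenario)
  g <- factors$population$grid
  scores <- list(
    population = score_population(factors$population, scenario$pop_saturation),
    cropland = score_threshold_layer(factors$cropland, scenario$crop_cutoff),
    roads = score_roads(factors$roads, g, scenario$road_buffer_km),
    overexploitation = score_overexploitation(factors$provinces, g,
                                              scenario$overexploit_margin),
    treeloss = score_threshold_layer(factors$treeloss, scenario$treeloss_cutoff),
    burn_trend = score_burn_trend(factors$burn_trend, scenario$burn_buffer_km),
    temperature = score_climate_delta(factors$temp_current,
                                      mean_future(factors$temp_future),
                                      scenario$temp_saturation_C),
    precipitation = score_climate_delta(factors$precip_current,
                                        mean_future(factors$precip_future),
                                        scenario$precip_saturation_mm))
  index <- sum_index(scores, factors$urban)
  structure(list(scenario = scenario, layer_scores = scores,
                 index = index, classes = classify_index(index)),
            class = "threat_index_map")
}

#' @export
print.threat_index_map <- function(x, ...) {
  rng <- range(x$index$values, na.rm = TRUE)
  cat(sprintf("<threat_index_map> scenario '%s', index range [%.1f, %.1f]\n",
              x$scenario$name, rng[1], rng[2]))
  invisible(x)
}
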