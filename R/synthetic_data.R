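#' Configuration for the synthetic study system
#'
#' The generator emulates the structure of a national-scale threat
#' assessment on a planar toy geography: spatially autocorrelated
#' environmental predictors, a species with a known Gaussian (in predictor
#' space) niche sampled in proportion to its true occurrence probability,
#' clustered population density, random road polylines, fractional
#' cropland / tree-loss covers, a burned-area-trend mask, provinces with
#' harvest volumes, climate-change amplitude fields and urban blobs. Because
#' the truth (niche parameters, probability surface, factor parameters) is
#' recorded, every pipeline stage can be tested by recovery rather than by
#' eye.
#'
#' @param n_rows,n_cols,cell_size Analysis grid (default 100 x 100 cells of
#'   5 km).
#' @param seed Master seed; every generated object derives from it.
#' @param n_env_layers Number of environmental layers (named `env1`...).
#' @param autocorr_range_cells Smoothing range of the random fields, in
#'   cells.
#' @param niche Named list `variable -> c(optimum, breadth)` on the
#'   standardised layer scale; defaults to a strong two-variable niche on
#'   `env1` and `env2`.
#' @param prevalence Target mean occurrence probability (intercept is
#'   calibrated to it by bisection).
#' @param n_presences Number of presence records to draw.
#' @param sampling_bias `"none"` or `"road-biased"` (collection effort
#'   concentrated near roads, as in herbarium data).
#' @param collinear_pair Add a layer nearly collinear with `env1` (to
#'   exercise VIF elimination)?
#' @param town_count,road_count Numbers of population centres and roads.
#' @param climate_delta_scale Length-2 vector: maximum temperature (deg C)
#'   and precipitation (mm) change amplitudes.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_rows = 100, n_cols = 100, cell_size = 5000,
                             seed = 1, n_env_layers = 6,
                             autocorr_range_cells = 8,
                             niche = list(env1 = c(optimum = 0.5, breadth = 0.6),
                                          env2 = c(optimum = -0.3, breadth = 0.6)),
                             prevalence = 0.15, n_presences = 150,
                             sampling_bias = c("none", "road-biased"),
                             collinear_pair = FALSE,
                             town_count = 5, road_count = 5,
                             climate_delta_scale = c(2.0, 200)) {
  stopifnot(n_presences >= 1, all(vapply(niche, function(p) p[2] > 0, TRUE)))
  structure(list(grid = grid_spec(n_rows, n_cols, cell_size),
                 seed = seed, n_env_layers = n_env_layers,
                 autocorr_range_cells = autocorr_range_cells, niche = niche,
                 prevalence = prevalence, n_presences = n_presences,
                 sampling_bias = match.arg(sampling_bias),
                 collinear_pair = collinear_pair,
                 town_count = town_count, road_count = road_count,
                 climate_delta_scale = climate_delta_scale),
            class = "synthetic_config")
}

# Edge-truncated running mean along both dimensions (box blur via cumsum).
box_blur <- function(m, r) {
  if (r < 1) return(m)
  blur1 <- function(x) {
    n <- length(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - r, 1); hi <- pmin(seq_len(n) + r, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  m <- apply(m, 2, blur1)
  t(apply(m, 1, blur1))
}

# Standardised smoothed Gaussian random field on a grid.
smooth_field <- function(grid, range_cells) {
  m <- matrix(stats::rnorm(grid$n_rows * grid$n_cols), grid$n_rows, grid$n_cols)
  r <- round(range_cells / 2)
  m <- box_blur(box_blur(m, r), r)   # two passes approximate a Gaussian kernel
  (m - mean(m)) / stats::sd(m)
}

rescale01 <- function(m) (m - min(m)) / (max(m) - min(m))

#' Generate autocorrelated environmental layers
#'
#' Each layer is a standardised spatial moving average of white noise
#' (two box-blur passes at half the configured range), so neighbouring
#' cells are correlated at ranges up to `autocorr_range_cells`. With
#' `collinear_pair = TRUE` the last layer is `env1` plus a small amount of
#' noise, giving a pair with VIF far above 10.
#'
#' @param cfg A [synthetic_config()].
#' @return Named list of `raster_layer`s (`env1`, `env2`, ...).
#' @export
gen_env_layers <- function(cfg) {
  set.seed(derive_seeds(cfg$seed, 1))
  layers <- list()
  for (i in seq_len(cfg$n_env_layers)) {
    v <- if (cfg$collinear_pair && i == cfg$n_env_layers && i > 1) {
      w <- layers[["env1"]]$values + 0.05 * matrix(
        stats::rnorm(cfg$grid$n_rows * cfg$grid$n_cols),
        cfg$grid$n_rows, cfg$grid$n_cols)
      (w - mean(w)) / stats::sd(w)
    } else smooth_field(cfg$grid, cfg$autocorr_range_cells)
    layers[[paste0("env", i)]] <- raster_layer(cfg$grid, v, paste0("env", i))
  }
  layers
}

#' Generate a species with a known niche
#'
#' The true occurrence probability is a logistic Gaussian niche response,
#' `logit(p) = intercept - sum_v (x_v - optimum_v)^2 / (2 * breadth_v^2)`,
#' with the intercept calibrated by bisection so the grid-mean probability
#' equals the target prevalence. Presence cells are sampled without
#' replacement with probability proportional to `p`; records sit at cell
#' centres. `road-biased` sampling additionally weights collection effort
#' toward cells near roads.
#'
#' @param cfg A [synthetic_config()].
#' @param env Layers from [gen_env_layers()].
#' @param roads Optional [polyline_set()] (required for road-biased
#'   sampling).
#' @param species Species label.
#' @return List with `occurrences` (an [occurrence_set()]) and `truth`
#'   (`probability_map` raster, `niche`, `intercept`).
#' @export
gen_species <- function(cfg, env, roads = NULL, species = "Synthspecies exemplaris") {
  for (v in names(cfg$niche))
    if (!v %in% names(env)) stop("niche variable ", v, " not among layers")
  g <- cfg$grid
  eta <- matrix(0, g$n_rows, g$n_cols)
  for (v in names(cfg$niche)) {
    p <- cfg$niche[[v]]
    eta <- eta - (env[[v]]$values - p[1])^2 / (2 * p[2]^2)
  }
  calib <- function(c0) mean(stats::plogis(eta + c0)) - cfg$prevalence
  lo <- -50; hi <- 50
  if (calib(lo) > 0 || calib(hi) < 0) stop("target prevalence unreachable")
  intercept <- stats::uniroot(calib, c(lo, hi), tol = 1e-10)$root
  prob <- stats::plogis(eta + intercept)
  wt <- as.vector(prob)
  if (cfg$sampling_bias == "road-biased") {
    if (is.null(roads)) stop("road-biased sampling needs a road set")
    near <- buffer_mask(rasterize_lines(roads, g), 4 * g$cell_size)$values
    wt <- wt * ifelse(as.vector(near) == 1, 1, 0.2)
  }
  set.seed(derive_seeds(cfg$seed, 2)[2])
  cells <- sample(length(wt), cfg$n_presences, prob = wt)
  ctr <- cell_centers(g, cells)
  rec <- data.frame(species = species, x = ctr[, "x"], y = ctr[, "y"],
                    collector = "synth", collection_number = as.character(seq_along(cells)),
                    uncertainty_m = 0, source_id = "synthetic")
  list(occurrences = occurrence_set(rec, g),
       truth = list(probability_map = raster_layer(g, prob, "true_probability"),
                    niche = cfg$niche, intercept = intercept))
}

# Jittered rectangular partition of the grid into province polygons.
make_provinces <- function(grid, n_bands_r = 2, n_bands_c = 3) {
  rb <- round(seq(0, grid$n_rows, length.out = n_bands_r + 1))
  cb <- round(seq(0, grid$n_cols, length.out = n_bands_c + 1))
  jitter_breaks <- function(b, nmax) {
    if (length(b) > 2)
      b[2:(length(b) - 1)] <- pmin(nmax - 1, pmax(
        1, b[2:(length(b) - 1)] + sample(-3:3, length(b) - 2, replace = TRUE)))
    b
  }
  rb <- jitter_breaks(rb, grid$n_rows); cb <- jitter_breaks(cb, grid$n_cols)
  feats <- list(); k <- 0
  for (i in seq_len(n_bands_r)) for (j in seq_len(n_bands_c)) {
    k <- k + 1
    x0 <- grid$origin_x + cb[j] * grid$cell_size
    x1 <- grid$origin_x + cb[j + 1] * grid$cell_size
    y0 <- grid$origin_y - rb[i] * grid$cell_size
    y1 <- grid$origin_y - rb[i + 1] * grid$cell_size
    feats[[k]] <- list(id = sprintf("province_%02d", k),
                       geometry = list(rbind(c(x0, y0), c(x1, y0),
                                             c(x1, y1), c(x0, y1))),
                       attributes = list())
  }
  feats
}

#' Generate the eight threat-factor inputs
#'
#' Population density is a sum of exponential-decay kernels around random
#' town centres (peaks above the reference saturation, so scores span
#' 0-10); roads are random polylines; cropland and tree-loss are smoothed
#' fields squashed to `[0, 1]`; the burned-area trend is the top decile of
#' a smoothed field (a blob mask); provinces are a jittered rectangular
#' partition with licensed volumes drawn between 70% and 130% of the
#' adequate volume (so some provinces break the overexploitation rule under
#' every scenario margin); temperature and precipitation changes are smooth
#' amplitude fields reaching 125% of `climate_delta_scale` (so some cells
#' saturate); urban areas are one-cell-radius blobs at the town centres.
#'
#' @param cfg A [synthetic_config()].
#' @return Named list of factor inputs as [threat_index_map()] expects
#'   (`population`, `cropland`, `roads`, `provinces`, `treeloss`,
#'   `burn_trend`, `temp_current`, `temp_future`, `precip_current`,
#'   `precip_future`, `urban`), plus `harvest` (the province harvest table).
#' @export
gen_threat_factors <- function(cfg) {
  g <- cfg$grid
  set.seed(derive_seeds(cfg$seed, 3)[3])
  n <- g$n_rows * g$n_cols
  ctr <- cell_centers(g)

  # population: exponential kernels at town centres
  dens <- matrix(0, g$n_rows, g$n_cols)
  towns <- if (cfg$town_count > 0) sample(n, cfg$town_count) else integer()
  for (tc in towns) {
    peak <- stats::runif(1, 1200, 3000)
    d <- sqrt((ctr[, "x"] - ctr[tc, "x"])^2 + (ctr[, "y"] - ctr[tc, "y"])^2)
    dens <- dens + peak * exp(-d / 15000)
  }
  population <- raster_layer(g, dens, "population_density")

  # roads: random 3-waypoint polylines across the extent
  ext_x <- g$origin_x + c(0, g$n_cols) * g$cell_size
  ext_y <- g$origin_y - c(g$n_rows, 0) * g$cell_size
  roads <- polyline_set(lapply(seq_len(cfg$road_count), function(i)
    cbind(stats::runif(3, ext_x[1], ext_x[2]),
          stats::runif(3, ext_y[1], ext_y[2]))))

  cropland <- raster_layer(g, rescale01(smooth_field(g, cfg$autocorr_range_cells)),
                           "cropland_fraction")
  treeloss <- raster_layer(g, rescale01(smooth_field(g, cfg$autocorr_range_cells)),
                           "treeloss_fraction")

  burn_f <- smooth_field(g, cfg$autocorr_range_cells)
  burn_trend <- raster_layer(g, (burn_f >= stats::quantile(burn_f, 0.9)) + 0,
                             "burn_trend")

  feats <- make_provinces(g)
  harvest <- data.frame(province = vapply(feats, `[[`, "", "id"),
                        adequate_volume = round(stats::runif(length(feats), 50, 150), 1))
  harvest$licensed_volume <- round(harvest$adequate_volume *
                                     stats::runif(length(feats), 0.7, 1.3), 1)
  for (i in seq_along(feats))
    feats[[i]]$attributes <- list(licensed = harvest$licensed_volume[i],
                                  adequate = harvest$adequate_volume[i])
  provinces <- polygon_set(feats)

  temp_current <- raster_layer(g, 20 + 2 * smooth_field(g, cfg$autocorr_range_cells),
                               "temp_current")
  temp_amp <- cfg$climate_delta_scale[1] * 1.25 *
    rescale01(smooth_field(g, cfg$autocorr_range_cells))
  temp_future <- lapply(1:3, function(i)
    raster_layer(g, temp_current$values + temp_amp +
                   0.1 * smooth_field(g, cfg$autocorr_range_cells),
                 paste0("temp_gcm", i)))
  precip_current <- raster_layer(g, 1000 + 200 * smooth_field(g, cfg$autocorr_range_cells),
                                 "precip_current")
  precip_amp <- cfg$climate_delta_scale[2] * 1.25 *
    rescale01(smooth_field(g, cfg$autocorr_range_cells))
  precip_future <- lapply(1:3, function(i)
    raster_layer(g, precip_current$values - precip_amp +
                   10 * smooth_field(g, cfg$autocorr_range_cells),
                 paste0("precip_gcm", i)))

  urban <- matrix(0, g$n_rows, g$n_cols)
  if (length(towns)) {
    seed_layer <- raster_layer(g, {m <- matrix(0, g$n_rows, g$n_cols); m[towns] <- 1; m})
    urban <- buffer_mask(seed_layer, g$cell_size)$values
  }
  list(population = population, cropland = cropland, roads = roads,
       provinces = provinces, treeloss = treeloss, burn_trend = burn_trend,
       temp_current = temp_current, temp_future = temp_future,
       precip_current = precip_current, precip_future = precip_future,
       urban = raster_layer(g, urban, "urban"), harvest = harvest)
}

#' Generate protected-area polygons
#'
#' A few random rectangles, together covering roughly `target_fraction` of
#' the grid extent.
#'
#' @param cfg A [synthetic_config()].
#' @param n_pas Number of protected areas.
#' @param target_fraction Approximate total covered fraction.
#' @return A [polygon_set()].
#' @export
gen_protected_areas <- function(cfg, n_pas = 4, target_fraction = 0.12) {
  g <- cfg$grid
  set.seed(derive_seeds(cfg$seed, 4)[4])
  w_cells <- sqrt(target_fraction / n_pas * g$n_rows * g$n_cols)
  feats <- lapply(seq_len(n_pas), function(i) {
    w <- max(2, round(w_cells * stats::runif(1, 0.7, 1.3)))
    h <- max(2, round(w_cells * stats::runif(1, 0.7, 1.3)))
    r0 <- sample(g$n_rows - h, 1); c0 <- sample(g$n_cols - w, 1)
    x0 <- g$origin_x + c0 * g$cell_size; x1 <- x0 + w * g$cell_size
    y0 <- g$origin_y - r0 * g$cell_size; y1 <- y0 - h * g$cell_size
    list(id = sprintf("pa_%02d", i),
         geometry = list(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))),
         attributes = list(name = sprintf("Reserve %d", i)))
  })
  polygon_set(feats)
}

#' Write a complete synthetic fixture set to disk
#'
#' Writes every file format the pipeline consumes: predictor and factor
#' rasters as ESRI ASCII grids, occurrences as CSV, roads / provinces /
#' protected areas as GeoJSON, the harvest table as CSV, and the generating
#' truth as JSON.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
write_synthetic_fixtures <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  env <- gen_env_layers(cfg)
  factors <- gen_threat_factors(cfg)
  sp <- gen_species(cfg, env, roads = factors$roads)
  pas <- gen_protected_areas(cfg)
  paths <- list()
  p <- function(f) file.path(dir, f)
  for (nm in names(env))
    paths[[nm]] <- write_ascii_grid(env[[nm]], p(paste0(nm, ".asc")))
  for (nm in c("population", "cropland", "treeloss", "burn_trend",
               "temp_current", "precip_current", "urban"))
    paths[[nm]] <- write_ascii_grid(factors[[nm]], p(paste0(nm, ".asc")))
  for (i in seq_along(factors$temp_future))
    paths[[paste0("temp_future", i)]] <-
      write_ascii_grid(factors$temp_future[[i]], p(sprintf("temp_future_%d.asc", i)))
  for (i in seq_along(factors$precip_future))
    paths[[paste0("precip_future", i)]] <-
      write_ascii_grid(factors$precip_future[[i]], p(sprintf("precip_future_%d.asc", i)))
  paths$occurrences <- write_occurrences(sp$occurrences$records, p("occurrences.csv"))
  paths$roads <- write_lines_geojson(factors$roads, p("roads.geojson"))
  paths$provinces <- write_polygons_geojson(factors$provinces, p("provinces.geojson"))
  paths$protected_areas <- write_polygons_geojson(pas, p("protected_areas.geojson"))
  utils::write.csv(factors$harvest, p("harvest.csv"), row.names = FALSE)
  paths$harvest <- p("harvest.csv")
  jsonlite::write_json(list(niche = cfg$niche, intercept = sp$truth$intercept,
                            seed = cfg$seed, prevalence = cfg$prevalence),
                       p("truth.json"), auto_unbox = TRUE, digits = NA)
  paths$truth <- p("truth.json")
  paths$probability_map <- write_ascii_grid(sp$truth$probability_map,
                                            p("true_probability.asc"))
  invisible(paths)
}
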