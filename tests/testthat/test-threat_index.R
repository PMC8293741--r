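test_that("scenario bundles carry the published parameter values", {
  ref <- threat_scenario("reference")
  expect_equal(unlist(ref[-1]),
               c(pop_saturation = 1000, crop_cutoff = 0.20, road_buffer_km = 20,
                 overexploit_margin = 0, treeloss_cutoff = 0.20,
                 burn_buffer_km = 5, temp_saturation_C = 2.0,
                 precip_saturation_mm = 200))
  hi <- threat_scenario("highest"); lo <- threat_scenario("lowest")
  expect_equal(hi$pop_saturation, 800); expect_equal(lo$pop_saturation, 1200)
  expect_equal(hi$overexploit_margin, -0.10); expect_equal(lo$overexploit_margin, 0.10)
  expect_equal(hi$burn_buffer_km, 10); expect_equal(lo$burn_buffer_km, 0)
  expect_error(threat_scenario("median"))
})

test_that("population score is logarithmic, saturating exactly at 10", {
  g <- tiny_grid(1, 4)
  dens <- raster_layer(g, matrix(c(0, 99, 1000, 5000), 1, 4))
  s <- score_population(dens, 1000)
  expect_equal(s$values[1, 1], 0)
  expect_equal(s$values[1, 2], 10 / log10(1001) * 2)   # = 6.666...
  expect_equal(s$values[1, 3], 10)
  expect_equal(s$values[1, 4], 10)
  # exact saturation under every scenario's level
  for (sat in c(800, 1000, 1200))
    expect_equal(score_population(raster_layer(g, sat), sat)$values[1, 1], 10)
  # strictly increasing below saturation
  below <- raster_layer(grid_spec(1, 3), matrix(c(10, 100, 999), 1, 3))
  sv <- score_population(below, 1000)$values
  expect_true(all(diff(as.vector(sv)) > 0))
  expect_error(score_population(raster_layer(g, -1)), ">= 0")
})

test_that("fraction-threshold scoring is inclusive at the cutoff", {
  g <- tiny_grid(1, 3)
  frac <- raster_layer(g, matrix(c(0.19, 0.20, 0.0), 1, 3))
  s <- score_threshold_layer(frac, 0.20)
  expect_equal(as.vector(s$values), c(0, 10, 0))
  expect_equal(score_threshold_layer(raster_layer(g, 0), 0.2)$values,
               matrix(0, 1, 3))
  expect_error(score_threshold_layer(frac, 1.5), "cutoff")
})

test_that("road scoring buffers the rasterised network, nested across scenarios", {
  g <- tiny_grid(11, 11)   # 55 km x 55 km
  # straight horizontal road along the centre row of cell centres
  y_mid <- g$origin_y - 5.5 * g$cell_size
  road <- polyline_set(list(cbind(c(0, 11 * g$cell_size), c(y_mid, y_mid))))

  s20 <- score_roads(road, g, 20)
  # distance-to-segment oracle on cell centres
  ctr <- cell_centers(g)
  d <- abs(ctr[, "y"] - y_mid)
  expect_equal(as.vector(s20$values), ifelse(d <= 20000, 10, 0))

  s0 <- score_roads(road, g, 0)
  expect_equal(which(s0$values == 10), which(d <= g$cell_size / 2))

  s15 <- score_roads(road, g, 15); s25 <- score_roads(road, g, 25)
  expect_true(all(s25$values >= s20$values) && all(s20$values >= s15$values))

  expect_warning(empty <- score_roads(polyline_set(), g, 20), "empty road set")
  expect_true(all(empty$values == 0))
})

test_that("overexploitation rule compares licensed volume to the margin-adjusted quota", {
  g <- tiny_grid(4, 4)
  mk <- function(lic, ade) polygon_set(list(
    cell_rect(g, 1, 4, 1, 4, id = "p", attributes = list(licensed = lic, adequate = ade))))
  expect_equal(unique(as.vector(score_overexploitation(mk(110, 100), g, 0)$values)), 10)
  expect_equal(unique(as.vector(score_overexploitation(mk(100, 100), g, 0)$values)), 0)
  expect_equal(unique(as.vector(score_overexploitation(mk(95, 100), g, -0.10)$values)), 10)
  expect_equal(unique(as.vector(score_overexploitation(mk(105, 100), g, 0.10)$values)), 0)
  broken <- polygon_set(list(cell_rect(g, 1, 4, 1, 4, id = "p",
                                       attributes = list(licensed = 10))))
  expect_error(score_overexploitation(broken, g), "lacks")
})

test_that("burn-trend scoring buffers by one ring per 5 km on a 5-km grid", {
  g <- tiny_grid(7, 7)
  v <- matrix(0, 7, 7); v[4, 4] <- 1
  trend <- raster_layer(g, v)
  s0 <- score_burn_trend(trend, 0)
  expect_equal(s0$values, v * 10)
  s5 <- score_burn_trend(trend, 5)
  expect_equal(s5$values, buffer_oracle(trend, 5000) * 10)
  expect_equal(sum(s5$values == 10), 5)
  expect_equal(score_burn_trend(raster_layer(g, 0), 5)$values, matrix(0, 7, 7))
  expect_error(score_burn_trend(raster_layer(g, 0.5), 5), "binary")
})

test_that("climate-delta scoring is linear in |amplitude| and saturates", {
  g <- tiny_grid(1, 3)
  cur <- raster_layer(g, matrix(c(20, 20, 20), 1, 3))
  fut <- raster_layer(g, matrix(c(22, 20, 23.5), 1, 3))
  s <- score_climate_delta(cur, fut, 2)
  expect_equal(as.vector(s$values), c(10, 0, 10))
  # a 100 mm decrease at 200 mm saturation scores 5
  p_cur <- raster_layer(g, 1000); p_fut <- raster_layer(g, 900)
  expect_equal(unique(as.vector(score_climate_delta(p_cur, p_fut, 200)$values)), 5)
  expect_error(score_climate_delta(cur, raster_layer(tiny_grid(2, 2), 1), 2),
               "same grid")

  expect_equal(mean_future(list(cur))$values, cur$values)
  expect_equal(mean_future(list(raster_layer(g, 1), raster_layer(g, 3)))$values,
               matrix(2, 1, 3))
  set.seed(6)
  ls <- lapply(1:8, function(i) raster_layer(g, matrix(rnorm(3), 1, 3)))
  expect_equal(mean_future(ls)$values,
               Reduce(`+`, lapply(ls, `[[`, "values")) / 8)
  expect_error(mean_future(list()), "at least one")
})

test_that("the index sums eight factors, treats missing as 0, masks urban cells", {
  g <- tiny_grid(3, 3)
  no_urban <- raster_layer(g, 0)
  mk8 <- function(vals) setNames(lapply(vals, function(v) raster_layer(g, v)),
                                 paste0("f", 1:8))
  expect_equal(unique(as.vector(
    sum_index(mk8(rep(10, 8)), no_urban)$values)), 80)
  expect_equal(unique(as.vector(
    sum_index(mk8(rep(0, 8)), no_urban)$values)), 0)
  expect_equal(unique(as.vector(
    sum_index(mk8(c(10, 10, 10, 10, 0, 0, 0, 0)), no_urban)$values)), 40)

  # permutation invariance of the sum
  set.seed(10)
  layers <- mk8(runif(8, 0, 10))
  expect_equal(sum_index(layers, no_urban)$values,
               sum_index(rev(layers), no_urban)$values)

  # a missing score contributes 0, with a message
  layers$f1$values[2, 2] <- NA
  expect_message(out <- sum_index(layers, no_urban), "missing in 1 cell")
  full <- sum(vapply(layers, function(l) l$values[1, 1], numeric(1)))
  expect_equal(out$values[2, 2], full - layers$f1$values[1, 1])

  u <- matrix(0, 3, 3); u[1, 1] <- 1
  masked <- sum_index(mk8(rep(1, 8)), raster_layer(g, u))
  expect_true(is.na(masked$values[1, 1]))

  expect_error(sum_index(mk8(rep(1, 8))[1:7], no_urban), "exactly 8")
  expect_error(sum_index(mk8(c(rep(1, 7), 11)), no_urban), "outside")
})

test_that("index classification uses the fixed 20/40/60 breakpoints", {
  g <- tiny_grid(1, 8)
  idx <- raster_layer(g, matrix(c(0, 7.2, 19.99, 20, 39.99, 40, 60, 73.6), 1, 8))
  cls <- classify_index(idx)
  expect_equal(as.vector(cls$values), c(1, 1, 1, 2, 2, 3, 3, 4))
  expect_equal(attr(cls, "levels"), c("Low", "Moderate", "High", "VeryHigh"))
  expect_error(classify_index(raster_layer(g, 81)), "\\[0, 80\\]")
  # every non-missing cell gets exactly one class (partition)
  set.seed(12)
  idx2 <- raster_layer(tiny_grid(6, 6), matrix(runif(36, 0, 80), 6, 6))
  expect_false(anyNA(classify_index(idx2)$values))
})

test_that("sensitivity comparison partitions changes into increases and decreases", {
  g <- tiny_grid(4, 4)
  ref <- classify_index(raster_layer(g, matrix(rep(c(10, 30, 50, 70), 4), 4, 4)))
  expect_equal(unlist(sensitivity_compare(ref, ref)),
               c(changed = 0, increased = 0, decreased = 0))

  # every Low cell bumped to Moderate: changed = share of Low, all increases
  alt_vals <- ref$values
  alt_vals[ref$values == 1] <- 2
  alt <- raster_layer(g, alt_vals)
  out <- sensitivity_compare(ref, alt)
  expect_equal(out$changed, 100 * mean(ref$values == 1))
  expect_equal(out$increased, out$changed)
  expect_equal(out$decreased, 0)

  set.seed(19)
  for (i in 1:5) {
    a <- raster_layer(g, matrix(sample(1:4, 16, TRUE), 4, 4))
    b <- raster_layer(g, matrix(sample(1:4, 16, TRUE), 4, 4))
    s <- sensitivity_compare(a, b)
    expect_equal(s$changed, s$increased + s$decreased)
  }
  expect_error(sensitivity_compare(ref, raster_layer(tiny_grid(2, 2), 1)),
               "same grid")
})

test_that("factor scores are monotone across the three scenarios", {
  cfg <- synthetic_config(seed = 23, n_rows = 40, n_cols = 40)
  f <- gen_threat_factors(cfg)
  maps <- lapply(c("highest", "reference", "lowest"), function(s)
    suppressMessages(threat_index_map(f, s)))
  for (nm in names(maps[[1]]$layer_scores)) {
    hi <- maps[[1]]$layer_scores[[nm]]$values
    re <- maps[[2]]$layer_scores[[nm]]$values
    lo <- maps[[3]]$layer_scores[[nm]]$values
    expect_true(all(hi >= re - 1e-9, na.rm = TRUE), label = paste(nm, "hi>=ref"))
    expect_true(all(re >= lo - 1e-9, na.rm = TRUE), label = paste(nm, "ref>=lo"))
  }
  idx <- maps[[2]]$index$values
  expect_true(all(idx >= 0 & idx <= 80, na.rm = TRUE))
})
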