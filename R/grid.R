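#' Define the common analysis grid
#'
#' A `grid_spec` describes the regular, axis-aligned analysis grid that every
#' raster layer in a threatscape analysis lives on: cell-centre registered,
#' row-major from the north-west corner, in a projected equal-area coordinate
#' system so that distances and areas are planar. The default cell size of
#' 5,000 m matches the 5-km resolution at which all inputs are harmonised.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size Cell edge length in metres (> 0). Cell area is
#'   `cell_size^2`, used for all km^2 reporting.
#' @param origin_x,origin_y Projected coordinates (m) of the north-west
#'   corner of the grid (the outer corner of cell `[1, 1]`).
#' @param crs_id Text identifier of the projected, equal-area CRS. Layers
#'   only combine when their `crs_id` matches.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 5000,
                      origin_x = 0, origin_y = n_rows * cell_size,
                      crs_id = "local-equal-area") {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("grid dimensions must be >= 1")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 origin_x = origin_x, origin_y = origin_y, crs_id = crs_id),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m (%s), NW corner (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$crs_id, x$origin_x, x$origin_y))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("n_rows", "n_cols", "cell_size", "origin_x", "origin_y")],
                   b[c("n_rows", "n_cols", "cell_size", "origin_x", "origin_y")])) &&
    identical(a$crs_id, b$crs_id)
}

check_same_grid <- function(a, b, what = "layers") {
  if (!same_grid(a, b)) stop(what, " are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

#' Create a single-band raster layer on a grid
#'
#' Values are stored as a numeric matrix of shape `(n_rows, n_cols)`; missing
#' cells are explicit `NA`s (no nodata sentinels take part in arithmetic).
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix `(n_rows, n_cols)`, or a single number to
#'   fill the grid.
#' @param name Layer name.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values, name = "layer") {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(dim(values) == c(grid$n_rows, grid$n_cols)))
    stop("values shape must be (n_rows, n_cols)")
  structure(list(grid = grid, values = values, name = name),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_layer '%s'> %d x %d, %d missing, range [%s, %s]\n",
              x$name, nrow(v), ncol(v), sum(is.na(v)),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @param cells Optional vector of linear cell indices (column-major, as used
#'   by R matrices). Default: all cells.
#' @return A two-column matrix `(x, y)` of cell-centre coordinates.
#' @export
cell_centers <- function(grid, cells = NULL) {
  if (is.null(cells)) cells <- seq_len(grid$n_rows * grid$n_cols)
  row <- (cells - 1L) %% grid$n_rows + 1L
  col <- (cells - 1L) %/% grid$n_rows + 1L
  cbind(x = grid$origin_x + (col - 0.5) * grid$cell_size,
        y = grid$origin_y - (row - 0.5) * grid$cell_size)
}

#' Locate points on a grid
#'
#' @param grid A [grid_spec()].
#' @param x,y Point coordinates in the grid CRS.
#' @return Linear cell indices; `NA` for points outside the grid extent.
#' @export
cell_from_xy <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  # points exactly on the S/E outer edge belong to the last row/col
  col[x == grid$origin_x + grid$n_cols * grid$cell_size] <- grid$n_cols
  row[y == grid$origin_y - grid$n_rows * grid$cell_size] <- grid$n_rows
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- rep(NA_integer_, length(x))
  out[ok] <- (as.integer(col[ok]) - 1L) * grid$n_rows + as.integer(row[ok])
  out
}

# 1-D overlap lengths between target intervals and source intervals.
# Both described by ascending break vectors; returns |targets| x |sources|.
interval_overlap <- function(t_breaks, s_breaks) {
  nt <- length(t_breaks) - 1L; ns <- length(s_breaks) - 1L
  m <- matrix(0, nt, ns)
  for (i in seq_len(nt)) {
    lo <- pmax(t_breaks[i], s_breaks[-length(s_breaks)])
    hi <- pmin(t_breaks[i + 1L], s_breaks[-1L])
    m[i, ] <- pmax(hi - lo, 0)
  }
  m
}

#' Resample a raster onto a target grid
#'
#' `area_weighted_mean` computes, for each target cell, the mean of
#' intersecting non-missing source cells weighted by overlap area (the
#' "Mean Value - cell area weighted" rule); target cells with no non-missing
#' overlap become missing. `nearest` takes the source cell containing the
#' target cell centre. Both grids must share a CRS.
#'
#' @param src A `raster_layer`.
#' @param target A [grid_spec()].
#' @param method `"area_weighted_mean"` or `"nearest"`.
#' @return A `raster_layer` on `target`.
#' @export
resample_to_grid <- function(src, target, method = "area_weighted_mean") {
  stopifnot(inherits(src, "raster_layer"), inherits(target, "grid_spec"))
  if (!identical(src$grid$crs_id, target$crs_id))
    stop("source and target grids must share a CRS")
  if (all(is.na(src$values))) stop("source raster is entirely missing")
  if (same_grid(src$grid, target)) return(raster_layer(target, src$values, src$name))
  g <- src$grid
  if (method == "area_weighted_mean") {
    # x breaks west->east, y breaks north->south (descending y made ascending
    # by negation so interval_overlap sees ascending vectors)
    sx <- g$origin_x + (0:g$n_cols) * g$cell_size
    tx <- target$origin_x + (0:target$n_cols) * target$cell_size
    sy <- -(g$origin_y - (0:g$n_rows) * g$cell_size)
    ty <- -(target$origin_y - (0:target$n_rows) * target$cell_size)
    w_col <- interval_overlap(tx, sx)          # n_tc x n_sc
    w_row <- interval_overlap(ty, sy)          # n_tr x n_sr
    v <- src$values
    ok <- !is.na(v)
    v0 <- ifelse(ok, v, 0)
    num <- w_row %*% v0 %*% t(w_col)
    den <- w_row %*% (ok + 0) %*% t(w_col)
    out <- ifelse(den > 0, num / den, NA_real_)
  } else if (method == "nearest") {
    ctr <- cell_centers(target)
    idx <- cell_from_xy(g, ctr[, "x"], ctr[, "y"])
    out <- matrix(NA_real_, target$n_rows, target$n_cols)
    out[!is.na(idx)] <- src$values[idx[!is.na(idx)]]
  } else stop("unknown resampling method: ", method)
  raster_layer(target, out, src$name)
}

#' Grow the 1-set of a binary layer by a buffer distance
#'
#' A cell becomes 1 when its centre lies within `distance` (Euclidean, in the
#' grid CRS) of the centre of any 1-cell; other cells keep their original
#' value. Buffers are computed on cell centres, consistent with a raster
#' pipeline; vector-buffer edge conventions do not apply.
#'
#' @param binary A `raster_layer` with values in `{0, 1, NA}`.
#' @param distance Buffer distance in metres (>= 0); 0 leaves the layer
#'   unchanged.
#' @return A `raster_layer`.
#' @export
buffer_mask <- function(binary, distance) {
  stopifnot(inherits(binary, "raster_layer"))
  if (!is.numeric(distance) || length(distance) != 1L || distance < 0)
    stop("distance must be a single non-negative number")
  v <- binary$values
  if (!all(v %in% c(0, 1) | is.na(v))) stop("buffer_mask needs a {0,1,NA} layer")
  if (distance == 0 || !any(v == 1, na.rm = TRUE)) return(binary)
  g <- binary$grid
  r <- distance / g$cell_size
  k <- floor(r)
  off <- expand.grid(dr = -k:k, dc = -k:k)
  off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
  ones <- which(v == 1, arr.ind = TRUE)
  out <- v
  for (i in seq_len(nrow(off))) {
    rr <- ones[, 1] + off$dr[i]; cc <- ones[, 2] + off$dc[i]
    ok <- rr >= 1 & rr <= g$n_rows & cc >= 1 & cc <= g$n_cols
    out[cbind(rr[ok], cc[ok])] <- 1
  }
  raster_layer(g, out, binary$name)
}

#' Build a set of polygon features
#'
#' Each feature is a polygon or multipolygon given as a list of rings (the
#' first ring of each polygon is the shell, subsequent rings are holes; the
#' even-odd rule resolves containment), with a unique id and a named
#' attribute list.
#'
#' @param features A list; each element has `id` (text), `geometry` (list of
#'   rings, each a two-column x/y matrix with >= 3 vertices) and `attributes`
#'   (named list).
#' @return An object of class `polygon_set`.
#' @export
polygon_set <- function(features = list()) {
  ids <- vapply(features, function(f) as.character(f$id), "")
  if (anyDuplicated(ids)) stop("feature ids must be unique")
  for (f in features) {
    for (ring in f$geometry) {
      ring <- as.matrix(ring)
      if (ncol(ring) != 2L || nrow(ring) < 3L)
        stop("each ring needs >= 3 vertices and 2 columns")
    }
  }
  structure(list(features = features), class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set> %d feature(s)\n", length(x$features)))
  invisible(x)
}

# Even-odd (ray casting) point-in-rings test; rings may include holes.
points_in_rings <- function(px, py, rings) {
  inside <- rep(FALSE, length(px))
  for (ring in rings) {
    ring <- as.matrix(ring)
    n <- nrow(ring)
    # drop an explicit closing vertex
    if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1L }
    j <- n
    for (i in seq_len(n)) {
      xi <- ring[i, 1]; yi <- ring[i, 2]; xj <- ring[j, 1]; yj <- ring[j, 2]
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
      j <- i
    }
  }
  inside
}

#' Rasterize polygons onto a grid by cell-centre containment
#'
#' Each cell takes the value of the polygon containing its centre: either the
#' requested numeric attribute, or 1 for plain membership. Cells in no
#' polygon are 0 (membership) or missing (attribute). When features overlap,
#' the last-listed feature wins and a message reports the overlap.
#'
#' @param polys A [polygon_set()] in the grid CRS.
#' @param grid A [grid_spec()].
#' @param attribute Name of a numeric attribute to burn in, or `NULL` for
#'   membership.
#' @return A `raster_layer`.
#' @export
rasterize <- function(polys, grid, attribute = NULL) {
  stopifnot(inherits(polys, "polygon_set"), inherits(grid, "grid_spec"))
  ctr <- cell_centers(grid)
  out <- matrix(if (is.null(attribute)) 0 else NA_real_, grid$n_rows, grid$n_cols)
  claimed <- matrix(FALSE, grid$n_rows, grid$n_cols)
  overlapped <- FALSE
  for (f in polys$features) {
    if (!is.null(attribute)) {
      if (is.null(f$attributes[[attribute]]))
        stop("feature '", f$id, "' lacks attribute '", attribute, "'")
      val <- as.numeric(f$attributes[[attribute]])
    } else val <- 1
    inside <- points_in_rings(ctr[, "x"], ctr[, "y"], f$geometry)
    if (any(inside & claimed)) overlapped <- TRUE
    out[inside] <- val
    claimed[inside] <- TRUE
  }
  if (overlapped) message("rasterize: overlapping polygons; last-listed feature wins")
  raster_layer(grid, out, if (is.null(attribute)) "membership" else attribute)
}

#' Build a set of polyline features (e.g. roads)
#'
#' @param lines A list of two-column x/y matrices, each a polyline with >= 2
#'   vertices, in the grid CRS.
#' @return An object of class `polyline_set`.
#' @export
polyline_set <- function(lines = list()) {
  for (l in lines) {
    l <- as.matrix(l)
    if (ncol(l) != 2L || nrow(l) < 2L) stop("each polyline needs >= 2 vertices")
  }
  structure(list(lines = lines), class = "polyline_set")
}

# Minimum distance from points to a segment (vectorised over points).
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

#' Rasterize polylines onto a grid
#'
#' A cell is marked 1 when any polyline passes within half a cell width of
#' its centre (the raster trace of the line).
#'
#' @param lines A [polyline_set()].
#' @param grid A [grid_spec()].
#' @return A binary `raster_layer`.
#' @export
rasterize_lines <- function(lines, grid) {
  stopifnot(inherits(lines, "polyline_set"), inherits(grid, "grid_spec"))
  ctr <- cell_centers(grid)
  hit <- rep(FALSE, nrow(ctr))
  tol <- grid$cell_size / 2
  for (l in lines$lines) {
    l <- as.matrix(l)
    for (i in seq_len(nrow(l) - 1L)) {
      # only test centres near the segment's bounding box
      xlo <- min(l[i, 1], l[i + 1, 1]) - tol; xhi <- max(l[i, 1], l[i + 1, 1]) + tol
      ylo <- min(l[i, 2], l[i + 1, 2]) - tol; yhi <- max(l[i, 2], l[i + 1, 2]) + tol
      cand <- which(ctr[, "x"] >= xlo & ctr[, "x"] <= xhi &
                      ctr[, "y"] >= ylo & ctr[, "y"] <= yhi & !hit)
      if (!length(cand)) next
      d <- dist_point_segment(ctr[cand, "x"], ctr[cand, "y"],
                              l[i, 1], l[i, 2], l[i + 1, 1], l[i + 1, 2])
      hit[cand[d <= tol]] <- TRUE
    }
  }
  out <- matrix(0, grid$n_rows, grid$n_cols)
  out[hit] <- 1
  raster_layer(grid, out, "lines")
}

#' Mask urban cells out of a layer
#'
#' Urban areas completely prevent the growth of natural vegetation and are
#' excluded from suitability and threat maps: cells where `urban == 1`
#' become missing; all other cells pass through unchanged.
#'
#' @param layer A `raster_layer`.
#' @param urban A `{0,1}` `raster_layer` on the same grid.
#' @return A `raster_layer`.
#' @export
apply_urban_mask <- function(layer, urban) {
  stopifnot(inherits(layer, "raster_layer"), inherits(urban, "raster_layer"))
  check_same_grid(layer$grid, urban$grid)
  if (!all(urban$values %in% c(0, 1) | is.na(urban$values)))
    stop("urban mask must be a {0,1} layer")
  out <- layer$values
  out[urban$values == 1] <- NA_real_
  raster_layer(layer$grid, out, layer$name)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster exchange format (`ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value` header followed by north-to-south rows).
#'
#' @param layer A `raster_layer`.
#' @param path File path.
#' @param nodata Value written for missing cells.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `raster_layer`.
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  hdr <- c(sprintf("ncols %d", g$n_cols), sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$origin_x),
           sprintf("yllcorner %.10g", g$origin_y - g$n_rows * g$cell_size),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  v <- layer$values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(format(r, trim = TRUE, digits = 10), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param crs_id CRS identifier to stamp on the grid (not stored in the file).
#' @param name Layer name for the result.
#' @export
read_ascii_grid <- function(path, crs_id = "local-equal-area", name = NULL) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^", key, "\\b"), hdr, ignore.case = TRUE)]
    if (!length(ln)) stop("corrupt ASCII grid (missing ", key, "): ", path)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]][2])
  }
  n_cols <- val("ncols"); n_rows <- val("nrows")
  cs <- val("cellsize"); nodata <- val("NODATA_value")
  g <- grid_spec(n_rows, n_cols, cs,
                 origin_x = val("xllcorner"),
                 origin_y = val("yllcorner") + n_rows * cs, crs_id = crs_id)
  body <- strsplit(trimws(lines[-(1:6)]), "\\s+")
  v <- t(vapply(body, as.numeric, numeric(n_cols)))
  if (!all(dim(v) == c(n_rows, n_cols))) stop("corrupt ASCII grid body: ", path)
  v[v == nodata] <- NA_real_
  raster_layer(g, v, name %||% sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read polygon features as GeoJSON
#'
#' Coordinates are written in the grid CRS (GeoJSON is used purely as a
#' container format here; no datum transformation is implied).
#'
#' @param polys A [polygon_set()].
#' @param path File path.
#' @return `write_polygons_geojson` returns `path` invisibly;
#'   `read_polygons_geojson` returns a [polygon_set()].
#' @export
write_polygons_geojson <- function(polys, path) {
  feats <- lapply(polys$features, function(f) {
    coords <- lapply(f$geometry, function(ring) {
      ring <- as.matrix(ring)
      if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
      unname(lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2])))
    })
    list(type = "Feature", id = f$id,
         properties = c(list(id = f$id), f$attributes),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_polygons_geojson
#' @export
read_polygons_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  feats <- lapply(seq_along(j$features), function(k) {
    f <- j$features[[k]]
    geom <- f$geometry
    ringify <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    rings <- switch(geom$type,
      Polygon = lapply(geom$coordinates, ringify),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(poly) lapply(poly, ringify)),
                            recursive = FALSE),
      stop("unsupported geometry type: ", geom$type))
    props <- f$properties %||% list()
    id <- props$id %||% f$id %||% as.character(k)
    props$id <- NULL
    list(id = as.character(id), geometry = rings, attributes = props)
  })
  polygon_set(feats)
}

#' Write / read polylines as GeoJSON LineStrings
#'
#' @param lines A [polyline_set()].
#' @param path File path.
#' @return `write_lines_geojson` returns `path` invisibly;
#'   `read_lines_geojson` returns a [polyline_set()].
#' @export
write_lines_geojson <- function(lines, path) {
  feats <- lapply(seq_along(lines$lines), function(i) {
    l <- as.matrix(lines$lines[[i]])
    list(type = "Feature", properties = list(id = i),
         geometry = list(
           type = "LineString",
           coordinates = unname(lapply(seq_len(nrow(l)),
                                       function(k) c(l[k, 1], l[k, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lines_geojson
#' @export
read_lines_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  lines <- lapply(j$features, function(f) {
    do.call(rbind, lapply(f$geometry$coordinates,
                          function(pt) c(pt[[1]], pt[[2]])))
  })
  polyline_set(lines)
}
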