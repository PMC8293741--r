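#' Occurrence records and cleaned occurrence sets
#'
#' Occurrence records are held in a plain data frame with columns `species`,
#' `x`, `y` (grid-CRS coordinates), and optionally `collector`,
#' `collection_number`, `uncertainty_m` and `source_id`. An `occurrence_set`
#' binds the records of a single species to the analysis grid; after
#' [spatial_thin()] no two records share a grid cell.
#'
#' @param records Data frame of occurrence records for one species.
#' @param grid A [grid_spec()].
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(records, grid) {
  stopifnot(is.data.frame(records), inherits(grid, "grid_spec"))
  needed <- c("species", "x", "y")
  if (!all(needed %in% names(records)))
    stop("records need columns: ", paste(needed, collapse = ", "))
  if (nrow(records) && length(unique(records$species)) != 1L)
    stop("an occurrence_set holds a single species")
  if (nrow(records) && !all(is.finite(records$x) & is.finite(records$y)))
    stop("record coordinates must be finite")
  structure(list(species = if (nrow(records)) records$species[[1]] else NA_character_,
                 records = records, grid = grid),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s: %d record(s)\n", x$species, nrow(x$records)))
  invisible(x)
}

#' Remove duplicate collection events
#'
#' Herbarium datasets commonly hold the same collection event several times
#' (one database row per institution). Records sharing a collector and a
#' collection number are the same event: only the first in input order is
#' kept. Records lacking either field are never merged.
#'
#' @param records Data frame with optional `collector` and
#'   `collection_number` columns.
#' @return The data frame with duplicated collection events dropped,
#'   original order preserved.
#' @export
deduplicate <- function(records) {
  stopifnot(is.data.frame(records))
  if (!nrow(records) || !all(c("collector", "collection_number") %in% names(records)))
    return(records)
  coll <- as.character(records$collector)
  num <- as.character(records$collection_number)
  keyed <- !is.na(coll) & coll != "" & !is.na(num) & num != ""
  key <- paste(coll, num, sep = "\r")
  dup <- keyed & duplicated(ifelse(keyed, key, paste0("\r#", seq_along(key))))
  records[!dup, , drop = FALSE]
}

#' Drop records with large georeferencing uncertainty
#'
#' Only records with less than `max_uncertainty_m` of spatial uncertainty are
#' kept (strict inequality: a record whose uncertainty equals the grid
#' resolution cannot be pinned to one cell). Records with no recorded
#' uncertainty are retained, with a warning giving their count.
#'
#' @param records Data frame with an optional `uncertainty_m` column.
#' @param max_uncertainty_m Gate in metres (default 5,000, one grid cell).
#' @return The filtered data frame.
#' @export
filter_uncertainty <- function(records, max_uncertainty_m = 5000) {
  stopifnot(is.data.frame(records))
  if (!nrow(records) || !"uncertainty_m" %in% names(records)) {
    if (nrow(records))
      warning(nrow(records), " record(s) lack uncertainty metadata; retained")
    return(records)
  }
  u <- records$uncertainty_m
  n_missing <- sum(is.na(u))
  if (n_missing > 0)
    warning(n_missing, " record(s) lack uncertainty metadata; retained")
  records[is.na(u) | u < max_uncertainty_m, , drop = FALSE]
}

#' Spatially thin occurrences to one record per grid cell
#'
#' Sampling-bias control: at most one presence is retained per analysis grid
#' cell, keeping as many distinct localities as possible. Within a cell the
#' record nearest the cell centre wins; exact ties go to the earliest record
#' in input order. Records falling outside the grid extent are excluded with
#' a warning.
#'
#' @param set An [occurrence_set()].
#' @return A thinned `occurrence_set` (one record per occupied cell).
#' @export
spatial_thin <- function(set) {
  stopifnot(inherits(set, "occurrence_set"))
  rec <- set$records
  if (!nrow(rec)) return(set)
  cells <- cell_from_xy(set$grid, rec$x, rec$y)
  if (anyNA(cells)) {
    warning(sum(is.na(cells)), " record(s) outside the grid extent; excluded")
    rec <- rec[!is.na(cells), , drop = FALSE]
    cells <- cells[!is.na(cells)]
  }
  if (!nrow(rec)) return(occurrence_set(rec, set$grid))
  ctr <- cell_centers(set$grid, cells)
  d2 <- (rec$x - ctr[, "x"])^2 + (rec$y - ctr[, "y"])^2
  ord <- order(cells, d2, seq_len(nrow(rec)))
  keep <- ord[!duplicated(cells[ord])]
  occurrence_set(rec[sort(keep), , drop = FALSE], set$grid)
}

#' Grid cells occupied by an occurrence set
#'
#' @param set An [occurrence_set()].
#' @return Sorted unique linear cell indices.
#' @export
occupied_cells <- function(set) {
  stopifnot(inherits(set, "occurrence_set"))
  if (!nrow(set$records)) return(integer())
  cells <- cell_from_xy(set$grid, set$records$x, set$records$y)
  sort(unique(cells[!is.na(cells)]))
}

#' Read / write occurrence CSV files
#'
#' Column layout: `species,x,y,collector,collection_number,uncertainty_m,
#' source_id` (extra columns pass through).
#'
#' @param path CSV file path.
#' @return `read_occurrences` returns a data frame.
#' @export
read_occurrences <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_occurrences
#' @param records Data frame of occurrence records.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Full occurrence-cleaning pipeline for one species
#'
#' Convenience wrapper: [deduplicate()] then [filter_uncertainty()] then
#' [spatial_thin()].
#'
#' @param records Data frame of raw records for one species.
#' @param grid A [grid_spec()].
#' @param max_uncertainty_m Uncertainty gate in metres.
#' @return A thinned [occurrence_set()].
#' @export
prepare_occurrences <- function(records, grid, max_uncertainty_m = 5000) {
  rec <- deduplicate(records)
  rec <- filter_uncertainty(rec, max_uncertainty_m)
  spatial_thin(occurrence_set(rec, grid))
}
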