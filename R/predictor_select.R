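#' Classify bioclimatic variable names
#'
#' BIO1-BIO11 are temperature-derived, BIO12-BIO19 precipitation-derived;
#' anything else is "other" (soil, elevation, radiation, ...).
#'
#' @param names Character vector of variable names.
#' @return Character vector in `{"temperature", "precipitation", "other"}`.
#' @export
bioclim_class <- function(names) {
  num <- suppressWarnings(as.integer(sub("^BIO", "", names, ignore.case = TRUE)))
  is_bio <- grepl("^BIO[0-9]+$", names, ignore.case = TRUE) & !is.na(num)
  out <- rep("other", length(names))
  out[is_bio & num <= 11] <- "temperature"
  out[is_bio & num >= 12 & num <= 19] <- "precipitation"
  out
}

bio_order <- function(names) {
  num <- suppressWarnings(as.integer(sub("^BIO", "", names, ignore.case = TRUE)))
  order(ifelse(is.na(num), Inf, num), names)
}

#' Pre-screen bioclimatic variables by model importance
#'
#' To avoid overweighting the candidate set with the 19 bioclimatic
#' variables, only the `k_temp` temperature-derived and `k_precip`
#' precipitation-derived variables with the highest importance are kept.
#' Non-bioclim variables pass through untouched. Ties break by BIO number
#' order (BIO1 before BIO19).
#'
#' @param importances Named numeric vector of variable importances.
#' @param k_temp,k_precip Number of variables to keep per class (default 3).
#' @param var_class Optional class per variable (as [bioclim_class()]);
#'   derived from names when omitted.
#' @return Character vector of retained variable names, in input order.
#' @export
prescreen_bioclim <- function(importances, k_temp = 3, k_precip = 3,
                              var_class = NULL) {
  stopifnot(is.numeric(importances), !is.null(names(importances)))
  nm <- names(importances)
  cls <- var_class %||% bioclim_class(nm)
  pick <- function(class_name, k) {
    cand <- nm[cls == class_name]
    if (length(cand) < k) {
      warning("only ", length(cand), " ", class_name,
              " variable(s) available; keeping all")
      return(cand)
    }
    cand_sorted <- cand[bio_order(cand)]
    cand_sorted[order(-importances[cand_sorted])][seq_len(k)]
  }
  keep <- c(pick("temperature", k_temp), pick("precipitation", k_precip),
            nm[cls == "other"])
  nm[nm %in% keep]
}

#' Variance inflation factor of one predictor
#'
#' `VIF = 1 / (1 - R^2)` where `R^2` comes from the ordinary least-squares
#' regression (with intercept) of `target` on all other columns. Returns
#' `Inf` under perfect collinearity.
#'
#' @param table Data frame or named list of equal-length numeric columns
#'   (the combined presence + pseudo-absence sample).
#' @param target Column name.
#' @return The VIF (>= 1).
#' @export
vif <- function(table, target) {
  tab <- as.data.frame(table)
  if (!target %in% names(tab)) stop("unknown column: ", target)
  if (ncol(tab) < 2L) stop("vif needs at least 2 columns")
  if (nrow(tab) < ncol(tab) + 1L) stop("vif needs more samples than columns")
  y <- tab[[target]]
  if (stats::var(y) == 0) stop("constant target column: R^2 undefined")
  x <- as.matrix(tab[setdiff(names(tab), target)])
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  if (r2 >= 1 - 1e-12) return(Inf)
  max(1, 1 / (1 - r2))
}

#' Iterative VIF elimination
#'
#' Repeatedly removes the variable with the highest VIF (ties broken by BIO
#' number, then name order) and recomputes, until every remaining variable
#' scores below `threshold`. The report records each removal with the VIF at
#' removal time and the final VIFs of the retained set.
#'
#' @param table Data frame or named list of numeric columns.
#' @param threshold VIF threshold (default 10).
#' @return A `vif_report`: list with `steps` (data frame of
#'   `removed_variable`, `vif_at_removal`), `retained` and `final_vifs`.
#' @export
vif_select <- function(table, threshold = 10) {
  tab <- as.data.frame(table)
  steps <- data.frame(removed_variable = character(), vif_at_removal = numeric())
  repeat {
    if (ncol(tab) < 2L) break
    vifs <- vapply(names(tab), function(v) vif(tab, v), numeric(1))
    if (all(vifs < threshold)) break
    cand <- names(tab)[vifs == max(vifs)]
    drop <- cand[bio_order(cand)][1]
    steps <- rbind(steps, data.frame(removed_variable = drop,
                                     vif_at_removal = unname(vifs[drop])))
    tab[[drop]] <- NULL
  }
  final <- if (ncol(tab) >= 2L)
    vapply(names(tab), function(v) vif(tab, v), numeric(1))
  else stats::setNames(rep(1, ncol(tab)), names(tab))
  stopifnot(all(final < threshold))
  structure(list(steps = steps, retained = names(tab), final_vifs = final),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("<vif_report> removed %d, retained %d: %s\n",
              nrow(x$steps), length(x$retained),
              paste(x$retained, collapse = ", ")))
  invisible(x)
}

#' Extract layer values at point locations
#'
#' Builds the sample table the models see: one row per point, one column per
#' layer. Rows touching any missing cell are dropped, with a message giving
#' the count.
#'
#' @param layers List of `raster_layer`s on one grid (names become columns).
#' @param points An [occurrence_set()], a vector of linear cell indices, or
#'   a two-column x/y matrix.
#' @return Data frame of predictor values with attribute `"cells"` (the
#'   linear cell index of each retained row).
#' @export
extract_at_points <- function(layers, points) {
  stopifnot(length(layers) >= 1L)
  g <- layers[[1]]$grid
  for (l in layers) check_same_grid(g, l$grid)
  cells <- if (inherits(points, "occurrence_set")) {
    check_same_grid(g, points$grid)
    cell_from_xy(g, points$records$x, points$records$y)
  } else if (is.matrix(points)) {
    cell_from_xy(g, points[, 1], points[, 2])
  } else as.integer(points)
  if (anyNA(cells) || any(cells < 1 | cells > g$n_rows * g$n_cols))
    stop("points outside the grid extent")
  nm <- names(layers) %||% vapply(layers, `[[`, "", "name")
  tab <- as.data.frame(lapply(layers, function(l) l$values[cells]))
  names(tab) <- nm
  ok <- stats::complete.cases(tab)
  if (any(!ok)) message("extract_at_points: dropped ", sum(!ok),
                        " row(s) falling in missing cells")
  if (!any(ok)) stop("all rows fall in missing cells")
  tab <- tab[ok, , drop = FALSE]
  attr(tab, "cells") <- cells[ok]
  tab
}
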