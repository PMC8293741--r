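# Shared fixtures: tiny grids and layers built in code.

tiny_grid <- function(n_rows = 5, n_cols = 5, cell_size = 5000)
  grid_spec(n_rows, n_cols, cell_size)

const_layer <- function(grid, value, name = "const")
  raster_layer(grid, value, name)

# a rectangle polygon covering grid cells rows r0..r1, cols c0..c1 (1-based)
cell_rect <- function(grid, r0, r1, c0, c1, id = "rect", attributes = list()) {
  x0 <- grid$origin_x + (c0 - 1) * grid$cell_size
  x1 <- grid$origin_x + c1 * grid$cell_size
  y0 <- grid$origin_y - (r0 - 1) * grid$cell_size
  y1 <- grid$origin_y - r1 * grid$cell_size
  list(id = id, geometry = list(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1))),
       attributes = attributes)
}

# brute-force centre-to-centre buffer oracle
buffer_oracle <- function(binary, distance) {
  g <- binary$grid
  ctr <- cell_centers(g)
  ones <- which(binary$values == 1)
  out <- binary$values
  if (length(ones)) {
    for (i in seq_len(nrow(ctr))) {
      d <- sqrt((ctr[ones, "x"] - ctr[i, "x"])^2 + (ctr[ones, "y"] - ctr[i, "y"])^2)
      if (any(d <= distance)) out[i] <- 1
    }
  }
  out
}

# O(n^2) pairwise AUC oracle
auc_oracle <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# exhaustive TSS scan oracle over all candidate thresholds
tss_oracle <- function(pos, neg) {
  u <- sort(unique(c(pos, neg)))
  if (length(u) == 1L) return(list(threshold = u, tss = 0))
  cand <- (u[-1] + u[-length(u)]) / 2
  best_t <- NA_real_; best <- -Inf
  for (th in cand) {
    val <- mean(pos >= th) + mean(neg < th) - 1
    if (val > best + 1e-9) { best <- val; best_t <- th }
  }
  list(threshold = best_t, tss = best)
}

# fake model_run for ensemble tests
fake_run <- function(grid, value, auc = 0.8, scores = NULL, labels = NULL) {
  structure(list(learner = "fake", pa_set = 1L, replicate = 1L, seed = 1L,
                 auc = auc, tss = 0.5, tss_threshold = 0.5,
                 importance = c(x = 0.5),
                 prediction = raster_layer(grid, value, "fake"),
                 test_scores = scores %||% c(0.9, 0.1),
                 test_labels = labels %||% c(1, 0), failed = FALSE),
            class = "model_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
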