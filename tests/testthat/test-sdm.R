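occ_at_cells <- function(grid, cells, species = "sp") {
  ctr <- cell_centers(grid, cells)
  occurrence_set(data.frame(species = species, x = ctr[, "x"], y = ctr[, "y"]),
                 grid)
}

test_that("pseudo-absence sets sample one-third of the eligible background", {
  g <- tiny_grid(18, 18)              # 324 cells
  occ <- occ_at_cells(g, 1:24)        # 300 eligible background cells
  sets <- draw_pseudo_absences(g, occ, n_sets = 3, seed = 42)
  expect_length(sets, 3)
  for (s in sets) {
    expect_length(s$cell_ids, 100)
    expect_length(intersect(s$cell_ids, 1:24), 0)
    expect_false(anyDuplicated(s$cell_ids) > 0)
  }

  # fraction 1 exhausts the background; any two sets identical as sets
  full <- draw_pseudo_absences(g, occ, n_sets = 2, fraction = 1, seed = 1)
  expect_setequal(full[[1]]$cell_ids, full[[2]]$cell_ids)
  expect_length(full[[1]]$cell_ids, 300)

  # two seeds: overlap close to the hypergeometric expectation (1/3 of 100)
  s1 <- draw_pseudo_absences(g, occ, n_sets = 1, seed = 7)[[1]]
  s2 <- draw_pseudo_absences(g, occ, n_sets = 1, seed = 8)[[1]]
  ov <- length(intersect(s1$cell_ids, s2$cell_ids))
  expect_gt(ov, 100 / 3 - 20); expect_lt(ov, 100 / 3 + 20)

  expect_error(draw_pseudo_absences(g, occ, fraction = 1.5, seed = 1), "eligible")
})

test_that("rank-based AUC equals the pairwise-comparison oracle", {
  expect_equal(auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(auc(c(0.7, 0.3), c(0.5)), 0.5)   # one win, one loss
  set.seed(13)
  for (i in 1:20) {
    pos <- round(runif(sample(1:50, 1)), 2)   # rounding forces ties
    neg <- round(runif(sample(1:50, 1)), 2)
    expect_equal(auc(pos, neg), auc_oracle(pos, neg))
  }
  expect_error(auc(numeric(), 1), "non-empty")
})

test_that("TSS arithmetic and range checks", {
  expect_equal(tss(1, 1), 1)
  expect_equal(tss(0.5, 0.5), 0)
  expect_equal(tss(0, 0), -1)
  expect_error(tss(1.2, 0.5), "\\[0, 1\\]")
})

test_that("best TSS threshold equals exhaustive brute force", {
  # perfect separation: lowest midpoint in the gap, TSS = 1
  out <- best_tss_threshold(c(0.8, 0.9), c(0.1, 0.2))
  expect_equal(out$tss, 1)
  expect_equal(out$threshold, 0.5)

  # identical constant scores: no split, TSS 0
  expect_equal(best_tss_threshold(rep(0.4, 5), rep(0.4, 5))$tss, 0)

  set.seed(17)
  for (i in 1:20) {
    pos <- round(runif(10), 1); neg <- round(runif(10), 1)
    got <- best_tss_threshold(pos, neg)
    want <- tss_oracle(pos, neg)
    expect_equal(got$tss, want$tss)
    expect_equal(got$threshold, want$threshold)
  }
})

test_that("permutation importance separates used from ignored variables", {
  # adapter whose predictions depend on x1 only
  oracle_learner <- structure(list(
    name = "oracle",
    fit = function(features, labels, weights, seed) NULL,
    predict = function(fitted, features) plogis(features$x1)), class = "learner")
  set.seed(2)
  feats <- data.frame(x1 = rnorm(400), x2 = rnorm(400))
  expect_equal(permutation_importance(oracle_learner, NULL, feats, "x2",
                                      n_perm = 5, seed = 1), 0)
  imp1 <- permutation_importance(oracle_learner, NULL, feats, "x1",
                                 n_perm = 5, seed = 1)
  expect_gt(imp1, 0.8); expect_lte(imp1, 1)

  const_learner <- structure(list(
    name = "const", fit = function(...) NULL,
    predict = function(fitted, features) rep(0.5, nrow(features))),
    class = "learner")
  expect_warning(
    expect_equal(permutation_importance(const_learner, NULL, feats, "x1"), 0),
    "constant")
})

test_that("fit_all produces learners x sets x replicates runs, deterministically", {
  cfg <- synthetic_config(n_rows = 30, n_cols = 30, seed = 5,
                          n_env_layers = 3, n_presences = 40)
  env <- gen_env_layers(cfg)
  sp <- gen_species(cfg, env)
  occ <- prepare_occurrences(sp$occurrences$records, cfg$grid)
  pa <- draw_pseudo_absences(cfg$grid, occ, seed = 5)
  learners <- list(learner_glmnet(), learner_ranger(num_trees = 30))
  runs <- fit_all(occ, env, pa, learners, n_replicates = 2, seed = 5,
                  min_presences = 10, n_perm_importance = 2)
  expect_length(runs, 2 * 3 * 2)
  tab <- runs_table(runs)
  expect_false(any(tab$failed))
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(tab$tss >= -1 & tab$tss <= 1))
  imp <- mean_importance(runs)
  expect_true(all(imp >= 0 & imp <= 1))

  # bit-identical rerun under the same master seed
  runs2 <- fit_all(occ, env, pa, learners, n_replicates = 2, seed = 5,
                   min_presences = 10, n_perm_importance = 2)
  expect_equal(runs_table(runs2), tab)
  expect_equal(runs2[[1]]$prediction$values, runs[[1]]$prediction$values)

  expect_error(fit_all(occ, env, pa, learners, min_presences = 1e4),
               "presence cells")
})

test_that("ensemble is the gated unweighted mean of its members", {
  g <- tiny_grid()
  r1 <- fake_run(g, 0.2, auc = 0.75)
  r2 <- fake_run(g, 0.8, auc = 0.90)
  ens <- build_ensemble(structure(list(r1, r2), class = "model_run_set"))
  expect_equal(unique(as.vector(ens$mean_map$values)), 0.5)

  # all-identical members: mean equals any member
  same <- build_ensemble(structure(list(r1, r1, r1), class = "model_run_set"))
  expect_equal(same$mean_map$values, r1$prediction$values)

  # the 0.7 gate is inclusive: 0.70 in, 0.69 out
  gated <- build_ensemble(structure(list(fake_run(g, 1, auc = 0.70),
                                         fake_run(g, 0, auc = 0.69)),
                                    class = "model_run_set"))
  expect_equal(gated$n_members, 1)
  expect_equal(unique(as.vector(gated$mean_map$values)), 1)

  expect_error(build_ensemble(structure(list(fake_run(g, 1, auc = 0.5)),
                                        class = "model_run_set")),
               "gate")

  # mean lies within the member envelope cellwise
  set.seed(4)
  rs <- lapply(1:4, function(i) fake_run(g, matrix(runif(25), 5, 5)))
  e <- build_ensemble(structure(rs, class = "model_run_set"))
  lo <- Reduce(pmin, lapply(rs, function(r) r$prediction$values))
  hi <- Reduce(pmax, lapply(rs, function(r) r$prediction$values))
  expect_true(all(e$mean_map$values >= lo - 1e-12 & e$mean_map$values <= hi + 1e-12))
})

test_that("10th-percentile binarisation uses linear interpolation", {
  g <- tiny_grid(2, 5)
  vals <- matrix(seq(0.1, 1.0, by = 0.1), 2, 5)   # presence cells hold 0.1..1.0
  ens <- structure(list(species = "sp",
                        mean_map = raster_layer(g, vals, "m"),
                        member_runs = list(), ensemble_auc = 1,
                        ensemble_tss = 1, n_members = 1),
                   class = "ensemble_prediction")
  occ <- occ_at_cells(g, 1:10)
  bin <- binarize_p10(ens, occ)
  expect_equal(bin$threshold, 0.19)               # quantile type 7 on 0.1..1.0
  expect_equal(sum(bin$map$values), sum(vals >= 0.19))
  # at least 90% of presence cells fall inside the range
  expect_gte(mean(bin$map$values[1:10]), 0.9)

  # constant suitability: threshold c, everything suitable
  ens$mean_map <- raster_layer(g, 0.37, "m")
  bin2 <- binarize_p10(ens, occ)
  expect_equal(bin2$threshold, 0.37)
  expect_true(all(bin2$map$values == 1))

  occ_small <- occ_at_cells(g, 1:3)
  expect_warning(binarize_p10(ens, occ_small), "fewer than 10")
})

test_that("models recover a strong synthetic niche almost perfectly", {
  # narrow niche, low prevalence: the generator's truth gives near-perfect
  # separability, so single-model AUCs should be high
  cfg <- synthetic_config(n_rows = 40, n_cols = 40, seed = 11,
                          n_env_layers = 3, n_presences = 100,
                          prevalence = 0.05,
                          niche = list(env1 = c(optimum = 0.5, breadth = 0.15)))
  env <- gen_env_layers(cfg)
  sp <- gen_species(cfg, env)
  occ <- prepare_occurrences(sp$occurrences$records, cfg$grid)
  # Bayes-level AUC from the generating truth: presence cells vs background
  truth <- as.vector(sp$truth$probability_map$values)
  pres <- occupied_cells(occ)
  bayes <- auc(truth[pres], truth[-pres])
  expect_gt(bayes, 0.9)
  pa <- draw_pseudo_absences(cfg$grid, occ, seed = 11)
  runs <- fit_all(occ, env, pa, list(learner_ranger(num_trees = 100)),
                  n_replicates = 2, seed = 11, min_presences = 10,
                  n_perm_importance = 0)
  med <- median(runs_table(runs)$auc)
  expect_gt(med, 0.9)
  # and the fitted models approach the Bayes-optimal separability
  expect_gt(med, bayes - 0.05)
})
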