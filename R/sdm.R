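#' Learner adapters
#'
#' The modelling engine is learner-agnostic: any adapter exposing
#' `fit(features, labels, weights, seed)` and
#' `predict(fitted, features)` (suitability in `[0, 1]`, deterministic given
#' the seed) plugs in. Two concrete adapters ship:
#'
#' * `learner_glmnet()` — ridge-regularised logistic regression on linear +
#'   quadratic terms (the regression-technique role). Quadratic terms let a
#'   linear model express unimodal niche responses.
#' * `learner_ranger()` — probability random forest (the machine-learning
#'   role), the family reported to perform best in ensemble platforms.
#'
#' @param lambda Ridge penalty for `learner_glmnet`.
#' @param num_trees,mtry Forest size and split candidates for
#'   `learner_ranger` (`mtry = NULL` uses ranger's default, sqrt(p)).
#' @return A `learner` object (list with `name`, `fit`, `predict`).
#' @export
learner_glmnet <- function(lambda = 0.01) {
  structure(list(
    name = "glmnet",
    fit = function(features, labels, weights, seed) {
      x <- as.matrix(features)
      x <- cbind(x, x^2)
      colnames(x) <- c(names(features), paste0(names(features), "_sq"))
      set.seed(seed)
      fit <- glmnet::glmnet(x, factor(labels, levels = c(0, 1)),
                            family = "binomial", alpha = 0,
                            lambda = lambda, weights = weights,
                            standardize = TRUE)
      list(fit = fit, vars = names(features))
    },
    predict = function(fitted, features) {
      x <- as.matrix(features[fitted$vars])
      x <- cbind(x, x^2)
      as.numeric(stats::predict(fitted$fit, x, type = "response"))
    }), class = "learner")
}

#' @rdname learner_glmnet
#' @export
learner_ranger <- function(num_trees = 100, mtry = NULL) {
  structure(list(
    name = "ranger",
    fit = function(features, labels, weights, seed) {
      dat <- cbind(..y.. = factor(labels, levels = c(0, 1)), features)
      ranger::ranger(dependent.variable.name = "..y..", data = dat,
                     probability = TRUE, num.trees = num_trees, mtry = mtry,
                     case.weights = weights, seed = seed,
                     num.threads = 1)
    },
    predict = function(fitted, features) {
      as.numeric(stats::predict(fitted, data = features,
                                num.threads = 1)$predictions[, "1"])
    }), class = "learner")
}

# Seeds derived from one master seed; kept below 2^31.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Draw pseudo-absence sets from the background
#'
#' Presence-only data need background "absences": each set samples, without
#' replacement, a fixed fraction (default one-third) of the eligible
#' background cells — the non-missing study-area cells that do not hold a
#' presence. Multiple independent sets (default 3) propagate the sampling
#' uncertainty into the ensemble.
#'
#' @param grid A [grid_spec()].
#' @param presences An [occurrence_set()] (already thinned).
#' @param n_sets Number of independent sets.
#' @param fraction Fraction of eligible background cells per set.
#' @param seed Master seed; per-set seeds are derived and recorded.
#' @param mask Optional `raster_layer`; cells missing in it are excluded
#'   from the background (default: all grid cells eligible).
#' @return List of `pseudo_absence_set`s (`set_id`, `cell_ids`, `seed`).
#' @export
draw_pseudo_absences <- function(grid, presences, n_sets = 3, fraction = 1 / 3,
                                 seed = 1, mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  all_cells <- seq_len(grid$n_rows * grid$n_cols)
  if (!is.null(mask)) {
    check_same_grid(grid, mask$grid)
    all_cells <- all_cells[!is.na(mask$values[all_cells])]
  }
  eligible <- setdiff(all_cells, occupied_cells(presences))
  size <- round(fraction * length(eligible))
  if (size < 1 || size > length(eligible))
    stop("eligible background (", length(eligible),
         " cells) cannot supply sets of ", size)
  seeds <- derive_seeds(seed, n_sets)
  lapply(seq_len(n_sets), function(i) {
    set.seed(seeds[i])
    structure(list(set_id = i, cell_ids = sort(sample(eligible, size)),
                   seed = seeds[i]),
              class = "pseudo_absence_set")
  })
}

#' Rank-based AUC of the ROC curve
#'
#' The probability that a randomly chosen presence scores above a randomly
#' chosen absence (ties count half): the Mann-Whitney statistic normalised
#' by `|pos| * |neg|`. Threshold-independent.
#'
#' @param scores_pos,scores_neg Scores of the positive / negative class
#'   (both non-empty).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg))
    stop("auc needs non-empty score vectors")
  np <- length(scores_pos)
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * length(scores_neg))
}

#' True skill statistic
#'
#' `TSS = sensitivity + specificity - 1`, in `[-1, 1]`; zero or less means no
#' better than random, and the statistic is independent of prevalence.
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @return The TSS.
#' @export
tss <- function(sensitivity, specificity) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1)
    stop("sensitivity and specificity must lie in [0, 1]")
  sensitivity + specificity - 1
}

#' TSS-maximising classification threshold
#'
#' Scans the midpoints of consecutive sorted unique scores (a score >=
#' threshold predicts presence) and returns the threshold with maximal TSS;
#' ties go to the lowest threshold. With a single distinct score no split
#' exists and the TSS is 0.
#'
#' @param scores_pos,scores_neg Scores of each class (non-empty).
#' @return List with `threshold` and `tss`.
#' @export
best_tss_threshold <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg))
    stop("best_tss_threshold needs non-empty score vectors")
  u <- sort(unique(c(scores_pos, scores_neg)))
  if (length(u) == 1L) return(list(threshold = u, tss = 0))
  cand <- (u[-1] + u[-length(u)]) / 2
  tss_at <- vapply(cand, function(th) {
    sens <- mean(scores_pos >= th)
    spec <- mean(scores_neg < th)
    sens + spec - 1
  }, numeric(1))
  # lowest threshold among maximisers; 1e-9 absorbs float noise between
  # mathematically tied (sens, spec) pairs
  best <- which(tss_at >= max(tss_at) - 1e-9)[1]
  list(threshold = cand[best], tss = tss_at[best])
}

#' Permutation importance of one variable
#'
#' Shuffles a single variable, re-predicts, and measures how much the
#' predictions decorrelate from the originals:
#' `1 - cor(pred_original, pred_shuffled)` (Pearson), averaged over `n_perm`
#' shuffles and clipped to `[0, 1]`. 0 means the model ignores the variable.
#'
#' @param learner A learner adapter.
#' @param fitted A model fitted by `learner$fit`.
#' @param features Data frame of predictor values.
#' @param variable Column to shuffle.
#' @param n_perm Number of shuffles (default 10).
#' @param seed Seed for the shuffles.
#' @return Importance in `[0, 1]`.
#' @export
permutation_importance <- function(learner, fitted, features, variable,
                                   n_perm = 10, seed = 1) {
  stopifnot(variable %in% names(features))
  base <- learner$predict(fitted, features)
  if (stats::sd(base) == 0) {
    warning("constant predictions: importance undefined, returning 0")
    return(0)
  }
  seeds <- derive_seeds(seed, n_perm)
  vals <- vapply(seq_len(n_perm), function(i) {
    set.seed(seeds[i])
    shuffled <- features
    shuffled[[variable]] <- sample(shuffled[[variable]])
    p <- learner$predict(fitted, shuffled)
    if (stats::sd(p) == 0) return(1)
    1 - stats::cor(base, p)
  }, numeric(1))
  min(1, max(0, mean(vals)))
}

#' Fit all replicate models for one species
#'
#' For every learner x pseudo-absence set x replicate: the presence /
#' pseudo-absence sample is split into 70% training and 30% test data
#' (stratified, so the class ratio is preserved), classes are balanced by
#' weights (total presence weight = total pseudo-absence weight), the model
#' is fitted on the training portion, AUC and the TSS-maximising threshold
#' are evaluated on the held-out portion, permutation importance is computed
#' per variable, and a suitability raster is predicted over all non-missing
#' cells. With the full-scale defaults of 5 learners x 3 sets x 100
#' replicates this bookkeeping yields 1,500 individual models per species.
#'
#' @param presences A thinned [occurrence_set()].
#' @param layers Named list of predictor `raster_layer`s on one grid.
#' @param pa_sets List from [draw_pseudo_absences()].
#' @param learners List of learner adapters.
#' @param n_replicates Replicate 70/30 splits per learner x set.
#' @param train_fraction Training fraction (default 0.7).
#' @param seed Master seed; all per-run seeds derive from it.
#' @param min_presences Minimum presence cells required (default 15).
#' @param n_perm_importance Shuffles per variable for importance (default
#'   10); 0 skips importance.
#' @return A `model_run_set`: list of `model_run`s, each with `learner`,
#'   `pa_set`, `replicate`, `seed`, `auc`, `tss`, `tss_threshold`,
#'   `importance`, `prediction` (raster), and the held-out scores. Failed
#'   fits are recorded with `failed = TRUE` and excluded downstream.
#' @export
fit_all <- function(presences, layers, pa_sets, learners,
                    n_replicates = 100, train_fraction = 0.7, seed = 1,
                    min_presences = 15, n_perm_importance = 10) {
  stopifnot(inherits(presences, "occurrence_set"), length(layers) >= 1L,
            length(pa_sets) >= 1L, length(learners) >= 1L)
  grid <- layers[[1]]$grid
  pres_cells <- occupied_cells(presences)
  if (length(pres_cells) < min_presences)
    stop("only ", length(pres_cells), " presence cells; need >= ", min_presences)
  pres_tab <- extract_at_points(layers, pres_cells)
  # full-grid table for the prediction raster
  all_cells <- which(Reduce(`&`, lapply(layers, function(l) !is.na(l$values))))
  grid_tab <- extract_at_points(layers, all_cells)
  vars <- names(grid_tab)
  n_runs <- length(learners) * length(pa_sets) * n_replicates
  seeds <- derive_seeds(seed, 3L * n_runs)
  runs <- vector("list", n_runs)
  k <- 0L
  for (ln in learners) for (pa in pa_sets) {
    abs_tab <- extract_at_points(layers, pa$cell_ids)
    for (rep_i in seq_len(n_replicates)) {
      k <- k + 1L
      split_seed <- seeds[3L * k - 2L]
      fit_seed <- seeds[3L * k - 1L]
      imp_seed <- seeds[3L * k]
      run <- tryCatch({
        set.seed(split_seed)
        n_p <- nrow(pres_tab); n_a <- nrow(abs_tab)
        p_tr <- sample(n_p, round(train_fraction * n_p))
        a_tr <- sample(n_a, round(train_fraction * n_a))
        train <- rbind(pres_tab[p_tr, , drop = FALSE],
                       abs_tab[a_tr, , drop = FALSE])
        y_tr <- c(rep(1, length(p_tr)), rep(0, length(a_tr)))
        test <- rbind(pres_tab[-p_tr, , drop = FALSE],
                      abs_tab[-a_tr, , drop = FALSE])
        y_te <- c(rep(1, n_p - length(p_tr)), rep(0, n_a - length(a_tr)))
        w <- ifelse(y_tr == 1, 1, length(p_tr) / length(a_tr))
        fitted <- ln$fit(train, y_tr, w, fit_seed)
        sc <- ln$predict(fitted, test)
        run_auc <- auc(sc[y_te == 1], sc[y_te == 0])
        bt <- best_tss_threshold(sc[y_te == 1], sc[y_te == 0])
        imp <- if (n_perm_importance > 0)
          vapply(vars, function(v)
            permutation_importance(ln, fitted, train, v,
                                   n_perm_importance, imp_seed),
            numeric(1))
        else stats::setNames(rep(NA_real_, length(vars)), vars)
        pv <- matrix(NA_real_, grid$n_rows, grid$n_cols)
        pv[all_cells] <- ln$predict(fitted, grid_tab)
        list(learner = ln$name, pa_set = pa$set_id, replicate = rep_i,
             seed = split_seed, auc = run_auc, tss = bt$tss,
             tss_threshold = bt$threshold, importance = imp,
             prediction = raster_layer(grid, pv, ln$name),
             test_scores = sc, test_labels = y_te, failed = FALSE)
      }, error = function(e) {
        warning("run ", ln$name, "/set", pa$set_id, "/rep", rep_i,
                " failed: ", conditionMessage(e))
        list(learner = ln$name, pa_set = pa$set_id, replicate = rep_i,
             seed = split_seed, failed = TRUE, message = conditionMessage(e))
      })
      runs[[k]] <- structure(run, class = "model_run")
    }
  }
  structure(runs, class = "model_run_set")
}

#' Tabulate a set of model runs
#'
#' @param runs A `model_run_set` from [fit_all()].
#' @return Data frame with one row per run (failed runs have NA metrics).
#' @export
runs_table <- function(runs) {
  do.call(rbind, lapply(runs, function(r) data.frame(
    learner = r$learner, pa_set = r$pa_set, replicate = r$replicate,
    auc = if (isTRUE(r$failed)) NA_real_ else r$auc,
    tss = if (isTRUE(r$failed)) NA_real_ else r$tss,
    tss_threshold = if (isTRUE(r$failed)) NA_real_ else r$tss_threshold,
    failed = isTRUE(r$failed))))
}

#' Mean permutation importance across runs
#'
#' @param runs A `model_run_set`.
#' @return Named numeric vector (mean importance per variable over
#'   non-failed runs).
#' @export
mean_importance <- function(runs) {
  ok <- Filter(function(r) !isTRUE(r$failed), runs)
  if (!length(ok)) stop("no successful runs")
  imps <- do.call(rbind, lapply(ok, `[[`, "importance"))
  colMeans(imps, na.rm = TRUE)
}

#' AUC-gated mean consensus ensemble
#'
#' Single models with held-out AUC below the gate (default 0.7, the lower
#' bound of a "good" model) are excluded; the ensemble suitability of each
#' cell is the unweighted mean of the passing members. Ensemble AUC / TSS
#' are evaluated against the pooled held-out predictions of the members.
#'
#' @param runs A `model_run_set` from [fit_all()].
#' @param auc_gate Inclusion gate, inclusive (default 0.7).
#' @param species Species label carried on the result.
#' @return An `ensemble_prediction`: `species`, `member_runs`, `mean_map`,
#'   `ensemble_auc`, `ensemble_tss`, `n_members`.
#' @export
build_ensemble <- function(runs, auc_gate = 0.7, species = "species") {
  ok <- Filter(function(r) !isTRUE(r$failed), runs)
  members <- Filter(function(r) r$auc >= auc_gate, ok)
  if (!length(members))
    stop("no runs pass the AUC gate of ", auc_gate)
  grid <- members[[1]]$prediction$grid
  acc <- matrix(0, grid$n_rows, grid$n_cols)
  for (m in members) acc <- acc + m$prediction$values
  mean_map <- raster_layer(grid, acc / length(members), "ensemble_mean")
  pool_sc <- unlist(lapply(members, `[[`, "test_scores"))
  pool_lab <- unlist(lapply(members, `[[`, "test_labels"))
  e_auc <- auc(pool_sc[pool_lab == 1], pool_sc[pool_lab == 0])
  e_tss <- best_tss_threshold(pool_sc[pool_lab == 1], pool_sc[pool_lab == 0])$tss
  structure(list(species = species, member_runs = members, mean_map = mean_map,
                 ensemble_auc = e_auc, ensemble_tss = e_tss,
                 n_members = length(members)),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> %s: %d member(s), AUC %.3f, TSS %.3f\n",
              x$species, x$n_members, x$ensemble_auc, x$ensemble_tss))
  invisible(x)
}

#' Binarise an ensemble at the 10th-percentile training-presence threshold
#'
#' The suitability threshold is the 10th percentile (linear interpolation
#' between order statistics, R quantile type 7) of the ensemble suitability
#' at the presence cells, so ~90% of training presences fall inside the
#' predicted range. Cells with suitability >= threshold become 1, others 0;
#' missing cells stay missing.
#'
#' @param ens An `ensemble_prediction`.
#' @param presences The [occurrence_set()] used for fitting.
#' @return A `binary_suitability_map`: `species`, `threshold`, `map`.
#' @export
binarize_p10 <- function(ens, presences) {
  stopifnot(inherits(ens, "ensemble_prediction"))
  cells <- occupied_cells(presences)
  suit <- ens$mean_map$values[cells]
  if (anyNA(suit)) stop("presences fall in missing cells")
  if (length(suit) < 10)
    warning("fewer than 10 presence cells; 10th percentile is poorly resolved")
  th <- as.numeric(stats::quantile(suit, 0.10, type = 7))
  v <- ens$mean_map$values
  out <- ifelse(is.na(v), NA_real_, as.numeric(v >= th))
  structure(list(species = ens$species, threshold = th,
                 map = raster_layer(ens$mean_map$grid, out, "binary_suitability")),
            class = "binary_suitability_map")
}
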