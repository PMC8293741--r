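#' Run the full analysis pipeline
#'
#' End-to-end orchestration of the four stages — occurrence preparation,
#' ensemble distribution modelling, threat-index mapping (all three
#' scenarios plus the sensitivity comparison), and exposure overlay — on a
#' synthetic study system generated from the config. Everything derives
#' from one master seed; reruns with an identical config reuse the cached
#' model-stage outputs (keyed by a config hash) and produce identical
#' output digests.
#'
#' @param config A config list, or the path to a YAML file holding one.
#'   Recognised sections (all optional except `out_dir`):
#'   `seed` (master seed, default 1); `grid` (`n_rows`, `n_cols`,
#'   `cell_size`); `synth` (arguments of [synthetic_config()]);
#'   `sdm` (`n_replicates`, `learners` = names among
#'   `"glmnet"`/`"ranger"`, `auc_gate`, `n_perm_importance`,
#'   `min_presences`); `threat` (`scenarios`); `out_dir`.
#' @return A `run_manifest` (also written to `out_dir/manifest.json`):
#'   `config_hash`, `master_seed`, `versions`, `stage_timings`,
#'   `output_checksums`, `stages`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  bad <- setdiff(names(config),
                 c("seed", "grid", "synth", "sdm", "threat", "out_dir"))
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  old <- read_manifest(file.path(out_dir, "manifest.json"))
  cached <- !is.null(old) && identical(old$config_hash, hash)

  timings <- list(); outputs <- character(); stages <- character()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    stages <<- c(stages, stage)
    val
  }

  g_args <- config$grid %||% list()
  cfg <- do.call(synthetic_config, c(
    list(n_rows = g_args$n_rows %||% 60, n_cols = g_args$n_cols %||% 60,
         cell_size = g_args$cell_size %||% 5000, seed = seed),
    config$synth %||% list()))

  # stage 1: synthetic inputs + occurrence preparation
  prep <- tick("prep", {
    env <- gen_env_layers(cfg)
    factors <- gen_threat_factors(cfg)
    sp <- gen_species(cfg, env, roads = factors$roads)
    pas <- gen_protected_areas(cfg)
    occ <- prepare_occurrences(sp$occurrences$records, cfg$grid)
    write_occurrences(occ$records, file.path(out_dir, "occurrences_thinned.csv"))
    list(env = env, factors = factors, truth = sp$truth, pas = pas, occ = occ)
  })
  outputs <- c(outputs, "occurrences_thinned.csv")

  # stage 2: ensemble SDM (cached when config hash matches)
  sdm_cfg <- config$sdm %||% list()
  suit_path <- file.path(out_dir, "suitability.asc")
  bin_path <- file.path(out_dir, "binary.asc")
  sdm_out <- tick("sdm", {
    if (cached && file.exists(suit_path) && file.exists(bin_path)) {
      message("run_pipeline: reusing cached sdm outputs (config hash match)")
      list(mean_map = read_ascii_grid(suit_path, cfg$grid$crs_id),
           binary = structure(
             list(species = prep$occ$species, threshold = NA_real_,
                  map = read_ascii_grid(bin_path, cfg$grid$crs_id)),
             class = "binary_suitability_map"))
    } else {
      learner_names <- sdm_cfg$learners %||% c("glmnet", "ranger")
      learners <- lapply(learner_names, function(nm)
        switch(nm, glmnet = learner_glmnet(), ranger = learner_ranger(),
               stop("unknown learner: ", nm)))
      pa_sets <- draw_pseudo_absences(cfg$grid, prep$occ, n_sets = 3,
                                      seed = seed, mask = prep$env[[1]])
      runs <- fit_all(prep$occ, prep$env, pa_sets, learners,
                      n_replicates = sdm_cfg$n_replicates %||% 5,
                      seed = seed,
                      min_presences = sdm_cfg$min_presences %||% 15,
                      n_perm_importance = sdm_cfg$n_perm_importance %||% 3)
      ens <- build_ensemble(runs, auc_gate = sdm_cfg$auc_gate %||% 0.7,
                            species = prep$occ$species)
      bin <- binarize_p10(ens, prep$occ)
      write_ascii_grid(ens$mean_map, suit_path)
      write_ascii_grid(bin$map, bin_path)
      utils::write.csv(runs_table(runs), file.path(out_dir, "runs.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(variable = names(mean_importance(runs)),
                                  importance = unname(mean_importance(runs))),
                       file.path(out_dir, "importance.csv"), row.names = FALSE)
      list(mean_map = ens$mean_map, binary = bin)
    }
  })
  outputs <- c(outputs, "suitability.asc", "binary.asc")

  # stage 3: threat index, all scenarios + sensitivity
  threat <- tick("threat", {
    scen_names <- (config$threat %||% list())$scenarios %||%
      c("reference", "highest", "lowest")
    maps <- lapply(scen_names, function(s) threat_index_map(prep$factors, s))
    names(maps) <- scen_names
    write_ascii_grid(maps[[1]]$index, file.path(out_dir, "threat_index.asc"))
    write_ascii_grid(maps[[1]]$classes, file.path(out_dir, "threat_classes.asc"))
    sens <- lapply(setdiff(scen_names, scen_names[1]), function(s)
      sensitivity_compare(maps[[scen_names[1]]]$classes, maps[[s]]$classes))
    names(sens) <- setdiff(scen_names, scen_names[1])
    jsonlite::write_json(sens, file.path(out_dir, "sensitivity.json"),
                         auto_unbox = TRUE, digits = NA)
    list(maps = maps, sensitivity = sens)
  })
  outputs <- c(outputs, "threat_index.asc", "threat_classes.asc", "sensitivity.json")

  # stage 4: exposure overlay
  tick("exposure", {
    classes <- threat$maps[[1]]$classes
    expo <- exposure_summary(sdm_out$binary, classes, prep$pas)
    rich <- richness_map(list(sdm_out$binary))
    write_ascii_grid(rich, file.path(out_dir, "richness.asc"))
    utils::write.csv(exposure_table(list(expo)),
                     file.path(out_dir, "exposure.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(species = expo$species,
           total_suitable_km2 = expo$total_suitable_km2,
           fraction_by_class = as.list(expo$fraction_by_class),
           protected_fraction = expo$protected_fraction,
           pa_profile = as.list(pa_class_profile(classes, prep$pas))),
      file.path(out_dir, "exposure_report.json"), auto_unbox = TRUE, digits = NA)
    expo
  })
  outputs <- c(outputs, "richness.asc", "exposure.csv", "exposure_report.json")

  checks <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(checks) <- outputs
  manifest <- structure(
    list(config_hash = hash, master_seed = seed,
         versions = list(r = as.character(getRversion()),
                         threatscape = as.character(utils::packageVersion("threatscape"))),
         stage_timings = timings, output_checksums = checks, stages = stages),
    class = "run_manifest")
  write_manifest(manifest, file.path(out_dir, "manifest.json"))
  manifest
}

# Stable hash of a config: md5 of its canonical serialised JSON.
config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(manifest, path) {
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(unclass(manifest), tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)   # atomic on one filesystem
  invisible(path)
}

read_manifest <- function(path) {
  if (!file.exists(path)) return(NULL)
  structure(jsonlite::read_json(path), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, hash %s\n  stages: %s\n",
              x$master_seed, substr(x$config_hash, 1, 8),
              paste(sprintf("%s (%.1fs)", names(x$stage_timings),
                            unlist(x$stage_timings)), collapse = ", ")))
  invisible(x)
}
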