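#' Default run configuration
#'
#' All settings of the per-species analysis with their defaults: 1-km
#' spatial thinning (100 runs), the five-step variable selection
#' (1 percent contribution cut, |r| >= 0.8, VIF > 5, top 5), the
#' 8 x 6 = 48-combination tuning grid, bootstrap evaluation with 10
#' replicates at a 75/25 split, 500 optimizer iterations at tolerance
#' 1e-5, and the 25/36 km2 cell area.
#'
#' @param ... named overrides, e.g. `seed = 7` or
#'   `tuning = list(n_rep = 2)`; nested lists are merged over the
#'   defaults.
#' @return nested list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    paths = list(occurrences = NULL, scenarios = NULL, outdir = "hsmax_run"),
    thinning = list(thin_par_km = 1.0, reps = 100),
    selection = list(n_runs = 3, contribution_cut = 1, r_thresh = 0.8,
                     vif_thresh = 5, k = 5, cor_data = "background"),
    tuning = list(rm_values = seq(0.5, 4, by = 0.5),
                  fc_sets = c("L", "LQ", "H", "LQH", "LQHP", "LQHPT"),
                  n_rep = 3),
    evaluation = list(n_rep = 10, train_frac = 0.75, max_iter = 500,
                      tol = 1e-5),
    features = list(hinge_knots = 15, threshold_knots = 15),
    classification = list(cell_area_km2 = 25 / 36)
  )
  over <- list(...)
  cfg <- utils::modifyList(cfg, over)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    stopifnot(thinning$thin_par_km > 0, thinning$reps >= 1,
              selection$contribution_cut > 0, selection$r_thresh > 0,
              selection$vif_thresh > 0, selection$k >= 1,
              evaluation$n_rep >= 1, evaluation$train_frac > 0,
              evaluation$train_frac < 1, evaluation$tol > 0,
              classification$cell_area_km2 > 0)
  })
  if (!is.null(cfg$paths$scenarios) &&
      anyDuplicated(names(cfg$paths$scenarios))) {
    stop("scenario labels must be unique")
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Values in the file override [default_config()]; anything omitted keeps
#' its default.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), over)
  class(cfg) <- "run_config"
  validate_config(cfg)
  cfg
}

#' The default tuning grid
#'
#' @param rm_values regularization multipliers.
#' @param fc_sets feature-class strings.
#' @return data.frame of (fc, rm) combinations, fc-major; 48 rows at the
#'   defaults.
#' @export
default_tuning_grid <- function(rm_values = seq(0.5, 4, by = 0.5),
                                fc_sets = c("L", "LQ", "H", "LQH", "LQHP",
                                            "LQHPT")) {
  if (anyDuplicated(rm_values)) stop("duplicate rm values")
  if (anyDuplicated(fc_sets)) stop("duplicate fc sets")
  g <- expand.grid(rm = rm_values, fc = fc_sets, stringsAsFactors = FALSE)
  g[order(match(g$fc, fc_sets), g$rm), c("fc", "rm")]
}

#' Reduced layer specification used by the bundled demo
#'
#' A 14-layer subset of [default_layer_spec()] (7 bioclimatic, 3 soil,
#' 2 topographic, 1 land-cover, 1 human-pressure) keeping the demo run
#' fast while still exercising the climate/static layer split.
#'
#' @return data.frame like [default_layer_spec()].
#' @export
demo_layer_spec <- function() {
  spec <- default_layer_spec()
  spec[spec$name %in% c("BIO1", "BIO4", "BIO11", "BIO14", "BIO15", "BIO18",
                        "BIO19", "SOIL1", "SOIL3", "SOIL4", "ELV", "SLP",
                        "LC1", "CHP"), ]
}

#' Generate a self-contained demo data set
#'
#' Writes a synthetic landscape (current plus four future scenario stacks:
#' 2030s/2050s x SSP245/SSP585), presence records sampled from a known
#' suitability surface driven by one climate and one soil layer, and a
#' ready-to-run YAML configuration.
#'
#' @param seed RNG seed; regeneration with the same seed reproduces the
#'   directory bit-identically.
#' @param dir output directory.
#' @param n_occurrences presence records to sample (30--60 is realistic
#'   for rare orchids at this scale).
#' @param species species label.
#' @return `dir`, invisibly.
#' @export
make_demo <- function(seed = 1, dir = "hsmax_demo", n_occurrences = 45,
                      species = "synthetic_orchid") {
  stopifnot(n_occurrences >= 1)
  seeds <- derive_seeds(seed, 6)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  current <- gen_stack(seeds[1], layer_spec = demo_layer_spec())
  # a rare, sharply defined niche (true AUC ~0.9, prevalence ~10%),
  # driven by one climate and one soil layer
  truth <- gen_true_suitability(
    current, c(BIO15 = 3, SOIL1 = -3), intercept = -6
  )
  occ <- sample_occurrences(truth, n_occurrences, seeds[2],
                            species = species)
  futures <- list(
    "2030s-SSP245" = list(shift = 0.5, seed = seeds[3]),
    "2030s-SSP585" = list(shift = 0.8, seed = seeds[4]),
    "2050s-SSP245" = list(shift = 1.0, seed = seeds[5]),
    "2050s-SSP585" = list(shift = 1.8, seed = seeds[6])
  )
  bio <- grep("^BIO", demo_layer_spec()$name, value = TRUE)
  warmish <- intersect(bio, c("BIO1", "BIO4", "BIO11"))
  dryish <- setdiff(bio, warmish)
  scen_paths <- list(current = file.path("stacks", "current", "manifest.csv"))
  write_stack(current, file.path(dir, "stacks", "current"))
  for (lab in names(futures)) {
    f <- futures[[lab]]
    deltas <- rbind(
      data.frame(name = warmish, shift = f$shift, sd = 0.25),
      data.frame(name = dryish, shift = -0.7 * f$shift, sd = 0.25)
    )
    fut <- gen_future_stack(current, deltas, seed = f$seed, label = lab)
    write_stack(fut, file.path(dir, "stacks", lab))
    scen_paths[[lab]] <- file.path("stacks", lab, "manifest.csv")
  }
  write_occurrences(occ, file.path(dir, "occurrences.csv"))
  write_ascii_grid(truth$surface, file.path(dir, "true_suitability.asc"))
  cfg <- list(
    seed = seed,
    paths = list(occurrences = "occurrences.csv",
                 scenarios = scen_paths,
                 outdir = "run")
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full per-species analysis
#'
#' Occurrence preparation (deduplicate, clip, thin), variable selection,
#' (RM, FC) tuning, final fit and 10-replicate evaluation, MTSPS
#' thresholding, current and per-future-scenario classification, and
#' range-change accounting. All artifacts (maps, tables, the serialized
#' model) are written under `outdir/species` together with a JSON run
#' manifest of settings, per-file MD5 hashes and summary metrics.
#'
#' @param config a `run_config` whose `paths` are set; relative paths are
#'   resolved against `base_dir`.
#' @param species species to analyse (must appear in the occurrence CSV).
#' @param base_dir directory against which relative config paths resolve.
#' @return The run manifest, invisibly (a list).
#' @export
run_species <- function(config, species, base_dir = ".") {
  validate_config(config)
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else
    file.path(base_dir, p)
  seeds <- derive_seeds(config$seed, 5)
  outdir <- resolve(config$paths$outdir) %||% "hsmax_run"
  sp_dir <- file.path(outdir, gsub("[^A-Za-z0-9_.-]", "_", species))
  dir.create(sp_dir, recursive = TRUE, showWarnings = FALSE)

  stacks <- stage("stack-assembly", {
    labs <- names(config$paths$scenarios)
    if (!"current" %in% labs) stop("config must name a 'current' scenario")
    stats::setNames(lapply(labs, function(l) {
      read_stack(resolve(config$paths$scenarios[[l]]), label = l)
    }), labs)
  })
  current <- stacks$current
  future_labs <- setdiff(names(stacks), "current")

  occ <- stage("occurrence-prep", {
    o <- read_occurrences(resolve(config$paths$occurrences), species)
    o <- deduplicate(o)
    o <- clip_to_boundary(o, current)
    spatial_thin(o, thin_par_km = config$thinning$thin_par_km,
                 reps = config$thinning$reps, seed = seeds[1],
                 log_path = file.path(sp_dir, "thinning_log.csv"))
  })
  write_occurrences(occ, file.path(sp_dir, "occurrences_thinned.csv"))

  pres <- stage("data-matrix", extract_matrix(occ, current))
  bg <- stack_matrix(current)

  sel <- stage("variable-selection", {
    run_variable_selection(
      pres, bg, n_runs = config$selection$n_runs, seed = seeds[2],
      contribution_cut = config$selection$contribution_cut,
      r_thresh = config$selection$r_thresh,
      vif_thresh = config$selection$vif_thresh, k = config$selection$k,
      cor_data = config$selection$cor_data,
      max_iter = config$evaluation$max_iter, tol = config$evaluation$tol
    )
  })
  write_selection_report(sel, file.path(sp_dir, "selection"))
  pres_f <- pres[, sel$final_set, drop = FALSE]
  bg_f <- bg[, sel$final_set, drop = FALSE]

  tuning <- stage("tuning", {
    tune_grid(pres_f, bg_f, rm_values = config$tuning$rm_values,
              fc_sets = config$tuning$fc_sets, seed = seeds[3],
              n_rep = config$tuning$n_rep,
              hinge_knots = config$features$hinge_knots,
              threshold_knots = config$features$threshold_knots,
              max_iter = config$evaluation$max_iter,
              tol = config$evaluation$tol)
  })
  utils::write.csv(tuning, file.path(sp_dir, "tuning.csv"),
                   row.names = FALSE)
  best <- select_best(tuning)
  best_cfg <- feature_config(best$fc, best$rm,
                             config$features$hinge_knots,
                             config$features$threshold_knots)

  evaluation <- stage("evaluation", {
    evaluate_replicates(pres_f, bg_f, best_cfg,
                        n_rep = config$evaluation$n_rep,
                        train_frac = config$evaluation$train_frac,
                        seed = seeds[4],
                        max_iter = config$evaluation$max_iter,
                        tol = config$evaluation$tol)
  })
  utils::write.csv(evaluation$replicates,
                   file.path(sp_dir, "evaluation_replicates.csv"),
                   row.names = FALSE)

  model <- stage("final-fit", {
    fd <- build_features(pres_f, bg_f, best_cfg)
    suppressWarnings(fit_maxent(fd, max_iter = config$evaluation$max_iter,
                                tol = config$evaluation$tol))
  })
  write_maxent_model(model, file.path(sp_dir, "model.json"))

  t_mtsps <- stage("threshold", {
    mtsps_threshold(evaluation$test_scores, evaluation$background_scores)
  })

  cell_area <- config$classification$cell_area_km2
  classified <- list()
  binaries <- list()
  rc_rows <- list()
  stage("classification", {
    for (lab in names(stacks)) {
      key <- if (lab == "current") "present" else lab
      suit <- predict_cloglog(model, stacks[[lab]])
      cm <- classify(suit, t_mtsps, cell_area)
      bm <- binary_map(suit, t_mtsps)
      classified[[key]] <- cm
      binaries[[key]] <- bm
      pref <- file.path(sp_dir, gsub("[^A-Za-z0-9_.-]", "_", lab))
      write_ascii_grid(suit, paste0(pref, "_cloglog.asc"))
      write_ascii_grid(cm$grid, paste0(pref, "_class.asc"), digits = 0)
      write_ascii_grid(bm, paste0(pref, "_binary.asc"), digits = 0)
    }
  })
  stage("range-change", {
    for (lab in future_labs) {
      rc <- range_change(binaries$present, binaries[[lab]], cell_area)
      rc_rows[[lab]] <- data.frame(
        scenario = lab, loss = rc$loss, stable = rc$stable, gain = rc$gain,
        crs = rc$crs, pct_loss = rc$pct_loss, pct_gain = rc$pct_gain,
        src = rc$src, loss_km2 = rc$loss_km2, stable_km2 = rc$stable_km2,
        gain_km2 = rc$gain_km2, crs_km2 = rc$crs_km2
      )
    }
  })
  rc_tab <- do.call(rbind, rc_rows)
  if (!is.null(rc_tab)) {
    utils::write.csv(rc_tab, file.path(sp_dir, "range_change.csv"),
                     row.names = FALSE)
  }
  areas <- area_summary(classified, cell_area)
  utils::write.csv(areas, file.path(sp_dir, "area_summary.csv"),
                   row.names = FALSE)

  files <- list.files(sp_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("hsmax")),
    species = species,
    config = config[setdiff(names(config), "paths")],
    paths = config$paths,
    n_occurrences_used = n_points(occ),
    selected_variables = sel$final_set,
    best_fc = best$fc, best_rm = best$rm,
    mtsps_threshold = t_mtsps,
    auc_train_mean = evaluation$auc_train_mean,
    auc_train_sd = evaluation$auc_train_sd,
    auc_diff_mean = evaluation$auc_diff_mean,
    or10_mean = evaluation$or10_mean,
    auc_grade = evaluation$grade,
    artifact_hashes = as.list(tools::md5sum(files))
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"),
             file.path(sp_dir, "manifest.json"))
  invisible(manifest)
}
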