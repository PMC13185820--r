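#' Assemble a full-run configuration
#'
#' One config drives the whole pipeline; a single top-level seed expands
#' deterministically into per-stage seeds (recorded in the manifest), so a
#' rerun with the same config reproduces every output byte for byte.
#' Configs round-trip through YAML unchanged.
#'
#' @param seed top-level integer seed (mandatory).
#' @param world named list of [world_config()] overrides.
#' @param sites named list: `n_sites`, `max_years_per_site`,
#'   `missing_frac`, `outlier_frac`, `obs_noise_sd`, `site_effect_sd`.
#' @param filter named list: `year_min`, `year_max`, `sd_k`.
#' @param split named list: `train_frac`, `per_ecosystem`.
#' @param selection named list: `criterion`, `direction`.
#' @param window moving-window length (years).
#' @param alpha significance level for the coupling test.
#' @param percentiles bivariate low/high percentile thresholds.
#' @param aridity_edges aridity class bin edges.
#' @param rf named list: `n_trees`, `cv_folds` (vegetation-free forest).
#' @param drivers named list: `block`, `min_frac`, `n_perm`, `n_trees`.
#' @return a `run_config` list.
#' @export
run_config <- function(seed,
                       world = list(),
                       sites = list(n_sites = 150, max_years_per_site = 10,
                                    missing_frac = 0.02, outlier_frac = 0.01),
                       filter = list(year_min = 1985, year_max = 2018, sd_k = 3),
                       split = list(train_frac = 0.8, per_ecosystem = TRUE),
                       selection = list(criterion = "bic", direction = "both"),
                       window = 10, alpha = 0.05,
                       percentiles = c(10, 90),
                       aridity_edges = c(0.05, 0.20, 0.50, 0.65),
                       rf = list(n_trees = 500, cv_folds = 10),
                       drivers = list(block = 5, min_frac = 0.25,
                                      n_perm = 99, n_trees = 300)) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  defaults <- list(n_sites = 150, max_years_per_site = 10,
                   missing_frac = 0.02, outlier_frac = 0.01,
                   obs_noise_sd = 0, site_effect_sd = 0)
  sites <- utils::modifyList(defaults, sites)
  structure(list(seed = as.integer(seed), world = world, sites = sites,
                 filter = filter, split = split, selection = selection,
                 window = window, alpha = alpha, percentiles = percentiles,
                 aridity_edges = aridity_edges, rf = rf, drivers = drivers),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must carry a seed", call. = FALSE)
  do.call(run_config, cfg)
}

write_json_out <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Run the full stability-coupling pipeline
#'
#' Executes the stages in dependency order: synthetic world, site sampling,
#' record ingest/filtering, composite indices, design extraction,
#' site-blocked split, per-ecosystem regression with validation, gridded
#' prediction, moving-window stability, above-belowground coupling with
#' stratified summaries, and driver attribution (random-forest importance,
#' partial correlations, variance partitioning, SEM). All outputs are
#' plain-text (CSV/JSON) in `out_dir`; `manifest.json` records the config,
#' per-stage seeds, and an MD5 checksum per output, so identical configs
#' yield identical checksums. A stage failure aborts with the stage name;
#' earlier outputs are preserved.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list of in-memory stage results (`world`, `report`,
#'   `fits`, `validation`, `coupling`, `stratified`, `drivers`, `manifest`).
#' @export
run_all <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list(world = stage_seed(config$seed, "world"),
                sites = stage_seed(config$seed, "sites"),
                split = stage_seed(config$seed, "split"),
                rf = stage_seed(config$seed, "rf"),
                drivers = stage_seed(config$seed, "drivers"))
  outputs <- character(0)
  emit <- function(writer, x, name) {
    path <- file.path(out_dir, name)
    writer(x, path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  res <- list()
  res$world <- stage("world", {
    wc <- do.call(world_config, c(config$world, list(seed = seeds$world)))
    generate_world(wc)
  })
  world <- res$world

  sites <- stage("sites", {
    s <- config$sites
    tbl <- sample_sites(world, n_sites = s$n_sites,
                        max_years_per_site = s$max_years_per_site,
                        missing_frac = s$missing_frac,
                        outlier_frac = s$outlier_frac,
                        obs_noise_sd = s$obs_noise_sd,
                        site_effect_sd = s$site_effect_sd,
                        seed = seeds$sites)
    emit(function(x, p) utils::write.csv(x, p, row.names = FALSE), tbl,
         "sites.csv")
    tbl
  })

  filt <- stage("ingest", {
    raw <- read_srdb(file.path(out_dir, "sites.csv"))
    fr <- filter_records(raw, year_min = config$filter$year_min,
                         year_max = config$filter$year_max,
                         sd_k = config$filter$sd_k)
    emit(function(x, p) utils::write.csv(x, p, row.names = FALSE),
         fr$records, "records_filtered.csv")
    emit(write_json_out, unclass(fr$report), "filter_report.json")
    fr
  })
  res$report <- filt$report

  indices <- stage("indices", {
    idx <- world$indices
    ld <- do.call(rbind, lapply(names(idx$loadings), function(nm) {
      data.frame(category = nm, variable = names(idx$loadings[[nm]]),
                 loading = as.numeric(idx$loadings[[nm]]),
                 var_explained = idx$var_explained[[nm]])
    }))
    emit(function(x, p) utils::write.csv(x, p, row.names = FALSE), ld,
         "index_loadings.csv")
    idx
  })

  design <- stage("design", {
    dsn <- extract_at_sites(indices, filt$records, world$geo)
    emit(function(x, p) utils::write.csv(x, p, row.names = FALSE), dsn,
         "design.csv")
    dsn
  })

  folds <- stage("split", {
    suppressWarnings(site_blocked_split(design,
                                        train_frac = config$split$train_frac,
                                        per_ecosystem = config$split$per_ecosystem,
                                        seed = seeds$split))
  })

  res$fits <- stage("fit", {
    f <- suppressWarnings(fit_rs_model(design[folds == "train", , drop = FALSE],
                                  selection = config$selection))
    ser <- lapply(f$fits, function(x) {
      list(beta = as.list(x$beta), selected = as.list(x$selected),
           residual_sd = x$residual_sd, n_train = x$n_train,
           r_squared = x$r_squared)
    })
    emit(write_json_out, list(selection = f$selection, fits = ser),
         "fits.json")
    f
  })

  res$validation <- stage("validate", {
    fb <- names(res$fits$fits)[[1]]
    v <- validate(res$fits, design, folds, fallback = fb)
    emit(write_json_out,
         list(overall = as.list(v$overall),
              per_ecosystem = cbind(ecosystem = rownames(v$per_ecosystem),
                                    v$per_ecosystem)),
         "validation.json")
    v
  })

  rs_pred <- stage("predict", {
    fb <- names(res$fits$fits)[[1]]
    p <- predict_grid(res$fits, indices, world$ecosystem, world$eco_names,
                      fallback = fb)
    emit(write_stack_csv, p, "rs_predicted.csv")
    p
  })

  stab <- stage("stability", {
    ws_rs <- moving_window_stability(rs_pred, window = config$window)
    ws_npp <- moving_window_stability(world$vegetation$NPP,
                                      window = config$window)
    ar <- aridity(world$climate$MAP, world$climate$PET,
                  edges = config$aridity_edges)
    full <- list(
      rs_stab = stability_map(rs_pred),
      npp_stab = stability_map(world$vegetation$NPP),
      lai_stab = stability_map(world$vegetation$LAI),
      temp_stab = stability_map(world$climate$MAT),
      precip_stab = stability_map(world$climate$MAP),
      ai_stab = stability_map(ar$ai_annual)
    )
    list(ws_rs = ws_rs, ws_npp = ws_npp, aridity = ar, full = full)
  })

  res$coupling <- stage("coupling", {
    cm <- windowed_coupling(stab$ws_rs, stab$ws_npp, alpha = config$alpha)
    biv <- bivariate_class_map(stab$full$rs_stab, stab$full$npp_stab,
                               p_low = config$percentiles[1],
                               p_high = config$percentiles[2])
    strat_eco <- stratified_mean_r(cm, world$ecosystem,
                                   labels = world$eco_names)
    strat_ai <- stratified_mean_r(cm, stab$aridity)
    emit(function(x, p) utils::write.csv(x, p, row.names = FALSE),
         rbind(cbind(strata = "ecosystem", strat_eco),
               cbind(strata = "aridity", strat_ai)),
         "coupling_stratified.csv")
    emit(write_json_out,
         list(mean_r = mean(cm$r[is.finite(cm$r)]),
              frac_significant = mean(cm$sig[is.finite(cm$r)]),
              n_windows = cm$n_windows, r_crit = cm$r_crit,
              bivariate_counts = as.list(table(factor(as.vector(biv$class),
                                                      levels = biv$levels)))),
         "coupling_summary.json")
    res$stratified <- list(ecosystem = strat_eco, aridity = strat_ai)
    cm
  })

  res$drivers <- stage("drivers", {
    smp <- aggregate_to_degree(stab$full, world$ecosystem, world$eco_names,
                               block = config$drivers$block,
                               min_frac = config$drivers$min_frac)
    pc <- productivity_pc1(smp$npp_stab, smp$lai_stab)
    smp$prod_pc1 <- pc$scores
    imp <- rf_importance(smp, n_perm = config$drivers$n_perm,
                         n_trees = config$drivers$n_trees,
                         seed = seeds$drivers)
    pcor <- partial_correlations(smp, group = "Ecosystem_type")
    vp <- variance_partition(smp)
    sem <- fit_sem(smp)
    emit(function(x, p) utils::write.csv(x, p, row.names = FALSE), smp,
         "driver_sample.csv")
    emit(write_json_out,
         list(rf_importance = imp, partial_correlations = pcor,
              variance_partition = as.list(vp$fractions),
              sem = list(paths = sem$paths, fit = as.list(sem$fit),
                         r_squared = as.list(sem$r_squared),
                         pass = sem$pass, saturated = sem$saturated)),
         "drivers.json")
    list(sample = smp, rf_importance = imp, partial_correlations = pcor,
         variance_partition = vp, sem = sem,
         prod_pc1_var_explained = pc$var_explained)
  })

  res$manifest <- stage("manifest", {
    sums <- tools::md5sum(outputs)
    manifest <- list(
      package_version = as.character(utils::packageVersion("stabcouple")),
      config = unclass(config),
      seeds = seeds,
      outputs = lapply(seq_along(outputs), function(i) {
        list(file = basename(outputs[i]), md5 = unname(sums[i]))
      })
    )
    write_json_out(manifest, file.path(out_dir, "manifest.json"))
    manifest
  })
  invisible(res)
}
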