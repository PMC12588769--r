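#' Pipeline run configuration
#'
#' Assembles (and defaults) every setting of the end-to-end analysis:
#' synthetic-landscape geometry and truth, occurrence sample size,
#' candidate radii, significance and correlation cutoffs, pseudo-absence
#' design, algorithms, cross-validation design, ensemble AUC cutoff,
#' scenario set, dispersal modes, and the mandatory seed.
#'
#' @param seed integer seed driving every stochastic stage (mandatory).
#' @param rows,cols,cell_size synthetic grid geometry.
#' @param n_presence presence points drawn from the true suitability.
#' @param truth a [synthetic_truth()]; its seed is re-derived from `seed`.
#' @param radii_km candidate window radii in km.
#' @param alpha characteristic-scale significance cutoff.
#' @param cor_threshold correlation-screen cutoff.
#' @param pa_sets,pa_n pseudo-absence sets and points per set.
#' @param algorithms subset of the five algorithm names.
#' @param k,repeats cross-validation design.
#' @param auc_cutoff ensemble member inclusion cutoff.
#' @param elev_min,elev_max,elev_buffer occurrence elevation filter (m).
#' @param allowed_classes land-cover classes accepted as habitat.
#' @param scenarios named list: per scenario label, a list of periods, each
#'   a list of [scenario_spec()]s (one per GCM). `NULL` = a default
#'   three-scenario, two-period, three-GCM design.
#' @param dispersal_buffer_km limited-dispersal buffer (km).
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(seed, rows = 64, cols = 64, cell_size = 1000,
                       n_presence = 150, truth = synthetic_truth(),
                       radii_km = 1:10, alpha = 0.05, cor_threshold = 0.7,
                       pa_sets = 3, pa_n = 1000,
                       algorithms = c("GLM", "GAM", "MAXENT_LIKE", "RF",
                                      "XGB"),
                       k = 5, repeats = 3, auc_cutoff = 0.7,
                       elev_min = 800, elev_max = 4000, elev_buffer = 100,
                       allowed_classes = landcover_codes()[c("forest",
                                                             "other")],
                       scenarios = NULL, dispersal_buffer_km = 110,
                       out_dir = tempfile("sdm_run_")) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(scenarios)) scenarios <- default_scenarios(seed)
  structure(list(mode = "synthetic", seed = as.integer(seed), rows = rows,
                 cols = cols, cell_size = cell_size,
                 n_presence = n_presence, truth = truth,
                 radii_km = radii_km, alpha = alpha,
                 cor_threshold = cor_threshold, pa_sets = pa_sets,
                 pa_n = pa_n, algorithms = algorithms, k = k,
                 repeats = repeats, auc_cutoff = auc_cutoff,
                 elev_min = elev_min, elev_max = elev_max,
                 elev_buffer = elev_buffer,
                 allowed_classes = allowed_classes, scenarios = scenarios,
                 dispersal_buffer_km = dispersal_buffer_km,
                 out_dir = out_dir),
            class = "run_config")
}

#' Default scenario design
#'
#' Three emission scenarios x two periods x three climate-model variants:
#' mild warming with little land conversion, intermediate, and strong
#' warming with substantial low-elevation forest loss. Warming offsets and
#' conversion rates grow with scenario severity and period.
#'
#' @param seed seed from which per-scenario conversion seeds are derived.
#' @return nested list `scenarios[[label]][[period]] = list of scenario_spec`.
#' @export
default_scenarios <- function(seed = 1L) {
  plan <- list(
    low  = list(`2070` = c(warm = 1.0, rate = 0.05),
                `2100` = c(warm = 1.2, rate = 0.08)),
    mid  = list(`2070` = c(warm = 2.5, rate = 0.15),
                `2100` = c(warm = 4.0, rate = 0.30)),
    high = list(`2070` = c(warm = 3.5, rate = 0.20),
                `2100` = c(warm = 5.5, rate = 0.40)))
  gcm_jitter <- c(gcm1 = -0.3, gcm2 = 0, gcm3 = 0.3)
  lapply(stats::setNames(names(plan), names(plan)), function(lab)
    lapply(stats::setNames(names(plan[[lab]]), names(plan[[lab]])),
           function(per) {
      p <- plan[[lab]][[per]]
      lapply(names(gcm_jitter), function(g)
        scenario_spec(label = lab, period = per, gcm_label = g,
                      warming_offset = p[["warm"]] + gcm_jitter[[g]],
                      precip_factor = 1 - 0.02 * p[["warm"]],
                      forest_to_crop_rate = p[["rate"]],
                      seed = sub_seed(seed, paste(lab, per))))
    }))
}

#' Validate a run configuration
#'
#' Pure check: returns findings without side effects. `error` findings
#' block [run_pipeline()]; `warning` findings are advisory (unsorted radii
#' are auto-sorted at run time).
#'
#' @param config a `run_config` (or plain list).
#' @return data.frame with columns `level`, `message`.
#' @export
validate_config <- function(config) {
  f <- list()
  add <- function(level, msg) f[[length(f) + 1L]] <<-
    data.frame(level = level, message = msg)
  if (is.null(config$seed) || is.na(config$seed))
    add("error", "seed is missing")
  for (nm in c("alpha", "cor_threshold", "auc_cutoff")) {
    v <- config[[nm]]
    if (!is.null(v) && (!is.numeric(v) || v <= 0 || v > 1))
      add("error", paste0(nm, " must lie in (0, 1]"))
  }
  if (!is.null(config$radii_km)) {
    if (any(config$radii_km < 0)) add("error", "radii must be non-negative")
    if (is.unsorted(config$radii_km))
      add("warning", "radii are not ascending; they will be sorted")
  }
  if (!is.null(config$pa_n) && config$pa_n < 1)
    add("error", "pa_n must be positive")
  if (!is.null(config$k) && !is.null(config$n_presence) &&
      config$k > config$n_presence)
    add("error", "k exceeds the number of presences")
  if (length(f)) do.call(rbind, f)
  else data.frame(level = character(0), message = character(0))
}

#' Run the full multi-scale ensemble analysis
#'
#' Executes, in order: synthetic landscape generation, presence sampling
#' with thinning and the three exclusion rules, pseudo-absence sampling,
#' multi-scale focal construction, characteristic-scale selection,
#' correlation screening, ensemble fitting with repeated cross-validation,
#' current-map prediction and maxSSS thresholding, scenario projection
#' with climate-model averaging, binarization and dispersal variants,
#' change accounting and time-step maps, and the range-dynamics
#' diagnostics. All tables are written as CSV, maps as ASCII grids,
#' points/polygons as GeoJSON, and a manifest (config snapshot, stage
#' timings, file inventory with checksums) as YAML.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the manifest plus the in-memory stage
#'   results (`stack`, `ensemble`, `profiles`, `screen`, `current`,
#'   `scenario_results`, `change_table`, ...).
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  if (any(findings$level == "error"))
    stop("invalid config: ",
         paste(findings$message[findings$level == "error"], collapse = "; "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  stage_t <- c(); mark <- function(nm) {
    stage_t[[nm]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    t0 <<- proc.time()[["elapsed"]]
  }
  seed <- config$seed
  radii <- sort(config$radii_km)
  out <- function(...) file.path(config$out_dir, ...)

  ## -- synthetic world ------------------------------------------------
  truth <- config$truth
  truth$seed <- sub_seed(seed, "truth")
  stack <- generate_landscape(config$rows, config$cols, config$cell_size,
                              truth)
  suit_true <- true_suitability(stack, truth)
  elev <- stack$layers$elevation
  occ_raw <- sample_occurrences(suit_true, config$n_presence * 2,
                                sub_seed(seed, "occ"), elevation = elev,
                                year = 2005L)
  hi <- which(!is.na(suit_true$values) &
                suit_true$values >= stats::quantile(suit_true$values,
                                                    0.7, na.rm = TRUE))
  nr <- nrow(suit_true$values)
  hi_xy <- cell_centers(suit_true, (hi - 1L) %% nr + 1L,
                        (hi - 1L) %/% nr + 1L)
  range_poly <- mcp(hi_xy, coverage = 1.0)$vertices
  mark("generate")

  ## -- occurrence prep ------------------------------------------------
  filt <- filter_occurrences(occ_raw, range_poly, elev, config$elev_min,
                             config$elev_max, config$elev_buffer,
                             landcover = stack$layers$landcover,
                             allowed_classes = config$allowed_classes)
  thin <- thin_occurrences(filt$kept, elev)
  presences <- utils::head(thin$kept, config$n_presence)
  pres_cells <- cell_from_xy(elev, presences$x, presences$y)$cell
  pa <- sample_pseudo_absences(elev, config$pa_n, pres_cells,
                               config$pa_sets, sub_seed(seed, "pa"))
  rejects <- rbind(filt$rejected, thin$rejected)
  mark("prep")

  ## -- multi-scale + scale selection ----------------------------------
  classes <- list(landcover = landcover_codes()[c("forest", "cropland")])
  ms_layer_names <- setdiff(names(stack$layers), c("aspect"))
  ms <- build_multiscale_stack(stack, radii, classes,
                               layers = ms_layer_names)
  profiles <- select_characteristic_scales(ms, presences, pa[[1]]$points,
                                           config$alpha)
  kept_vars <- names(profiles)[!vapply(unclass(profiles),
                                       function(p) p$excluded, TRUE)]
  chosen <- stats::setNames(lapply(kept_vars, function(v) {
    r <- unclass(profiles)[[v]]$chosen_radius_km
    ms[[sprintf("%s_r%gkm", v, r)]]$grid
  }), kept_vars)
  screen <- correlation_screen(chosen, profiles, config$cor_threshold,
                               seed = sub_seed(seed, "screen"))
  variables <- ms_variables(profiles, screen$retained, stack, classes)
  fgrids <- compute_feature_grids(stack, variables)
  mark("scales")

  ## -- ensemble -------------------------------------------------------
  pf <- features_at(fgrids, presences$x, presences$y)
  ok_p <- stats::complete.cases(pf)
  pf <- pf[ok_p, , drop = FALSE]
  bgf <- lapply(pa, function(s) {
    b <- features_at(fgrids, s$points$x, s$points$y)
    b[stats::complete.cases(b), , drop = FALSE]
  })
  specs <- lapply(config$algorithms, base_learner_spec)
  ensemble <- build_ensemble(pf, bgf, specs, config$k, config$repeats,
                             sub_seed(seed, "ens"), config$auc_cutoff)
  ensemble$variables <- variables
  current_suit <- project_suitability(ensemble, stack)
  thr <- ensemble$threshold_maxsss
  current_bin <- binarize(current_suit, thr, "current", "current")
  cell_area <- (config$cell_size / 1000)^2
  imp <- vapply(names(pf), function(v)
    variable_importance(ensemble, rbind(pf, bgf[[1]]), v,
                        seed = sub_seed(seed, "imp")), 0)
  mark("fit")

  ## -- scenario projection & change accounting ------------------------
  scen_res <- list(); change_rows <- list(); bin_rows <- list()
  bin_rows[["current"]] <- data.frame(scenario = "current",
                                      period = "current",
                                      bin_suitability(current_suit))
  tstep_maps <- list(); resil <- list()
  for (lab in names(config$scenarios)) {
    bins_seq <- list(current_bin)
    for (per in names(config$scenarios[[lab]])) {
      gcm_maps <- lapply(config$scenarios[[lab]][[per]], function(sp)
        project_suitability(ensemble, generate_future_stack(stack, sp)))
      avg <- average_gcms(gcm_maps)
      b <- binarize(avg, thr, lab, per)
      b_lim <- apply_dispersal_mask(b, "limited", range_poly,
                                    config$dispersal_buffer_km)
      cs <- change_metrics(current_bin, b, cell_area)
      cs_lim <- change_metrics(current_bin, b_lim, cell_area)
      scen_res[[paste(lab, per, sep = "_")]] <-
        list(suitability = avg, binary = b, binary_limited = b_lim,
             change = cs, change_limited = cs_lim)
      change_rows[[paste(lab, per, "perfect")]] <-
        data.frame(scenario = lab, period = per, dispersal = "perfect",
                   format_change_summary(cs))
      change_rows[[paste(lab, per, "limited")]] <-
        data.frame(scenario = lab, period = per, dispersal = "limited",
                   format_change_summary(cs_lim))
      bin_rows[[paste(lab, per)]] <- data.frame(scenario = lab,
                                                period = per,
                                                bin_suitability(avg))
      bins_seq[[length(bins_seq) + 1L]] <- b
    }
    tstep_maps[[lab]] <- time_step_map(bins_seq)
    resil[[lab]] <- resilient_area(bins_seq, cell_area)
  }
  change_table <- do.call(rbind, c(change_rows, list(make.row.names = FALSE)))
  bins_table <- do.call(rbind, c(bin_rows, list(make.row.names = FALSE)))
  mark("project")

  ## -- range dynamics -------------------------------------------------
  warm_spec <- config$scenarios[[length(config$scenarios)]][["2100"]][[2]]
  suit_late <- true_suitability(generate_future_stack(stack, warm_spec),
                                truth)
  occ_late <- sample_occurrences(suit_late, config$n_presence,
                                 sub_seed(seed, "occ2"), elevation = elev,
                                 year = 2020L)
  mcp_a <- mcp(presences); mcp_b <- mcp(occ_late)
  ov <- mcp_overlap(mcp_a, mcp_b)
  es <- elevation_shift(presences, occ_late, elev)
  range_summary <- data.frame(
    mcp_area_a = mcp_a$area, mcp_area_b = mcp_b$area,
    overlap_frac_a = ov$frac_a, overlap_frac_b = ov$frac_b,
    mean_elev_a = es$mean_a, mean_elev_b = es$mean_b,
    elev_delta = es$delta)
  mark("dynamics")

  ## -- outputs --------------------------------------------------------
  utils::write.csv(scaling_table(profiles, screen), out("scaling.csv"),
                   row.names = FALSE)
  utils::write.csv(screen$dropped, out("screened_out.csv"),
                   row.names = FALSE)
  utils::write.csv(ensemble$cv_runs, out("cv_runs.csv"), row.names = FALSE)
  utils::write.csv(data.frame(variable = names(imp), importance = imp),
                   out("importance.csv"), row.names = FALSE)
  utils::write.csv(change_table, out("change_table.csv"), row.names = FALSE)
  utils::write.csv(bins_table, out("suitability_bins.csv"),
                   row.names = FALSE)
  utils::write.csv(range_summary, out("range_dynamics.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(scenario = names(resil),
                              resilient_km2 = unlist(resil)),
                   out("resilient_areas.csv"), row.names = FALSE)
  utils::write.csv(rejects, out("rejected_occurrences.csv"),
                   row.names = FALSE)
  write_occurrences(presences, out("presences.csv"))
  write_occurrences_geojson(presences, out("presences.geojson"))
  write_polygon_geojson(range_poly, out("range_polygon.geojson"))
  write_ascii_grid(current_suit, out("suitability_current.asc"))
  write_ascii_grid(current_bin$grid, out("binary_current.asc"))
  for (nm in names(scen_res))
    write_ascii_grid(scen_res[[nm]]$suitability,
                     out(sprintf("suitability_%s.asc", nm)))
  for (lab in names(tstep_maps))
    write_ascii_grid(tstep_maps[[lab]]$grid,
                     out(sprintf("timestep_%s.asc", lab)))
  mark("write")

  files <- sort(list.files(config$out_dir))
  manifest <- list(
    package_version = as.character(utils::packageVersion("scalesdm")),
    seed = seed,
    threshold_maxsss = thr,
    config = config_snapshot(config),
    stage_seconds = as.list(stage_t),
    outputs = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(out(f)))))
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(list(manifest = manifest, stack = stack, truth = truth,
                 presences = presences, pseudo_absences = pa,
                 profiles = profiles, screen = screen,
                 ensemble = ensemble, importance = imp,
                 current = list(suitability = current_suit,
                                binary = current_bin),
                 scenario_results = scen_res,
                 change_table = change_table, bins_table = bins_table,
                 timestep_maps = tstep_maps, resilient = resil,
                 range_summary = range_summary, out_dir = config$out_dir))
}

# YAML-safe config snapshot (scenario specs and truth flattened)
config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$truth <- list(true_radii = as.list(config$truth$true_radii),
                     response_params = config$truth$response_params,
                     intercept = config$truth$intercept)
  snap$scenarios <- lapply(config$scenarios, function(lab)
    lapply(lab, function(per) lapply(per, unclass)))
  snap$allowed_classes <- as.list(snap$allowed_classes)
  snap
}
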