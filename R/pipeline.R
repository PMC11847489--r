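#' Default pipeline configuration
#'
#' Returns the standard parameterization of the full analysis: records
#' from 1965 onward, 5.5 km thinning, |r| >= 0.7 collinearity pruning,
#' <= 1% contribution exclusion, an 8 x 15 candidate grid (RM 0.5-4.0 by
#' 0.5; all nonempty subsets of l/q/p/h), omission tolerance E = 5%,
#' delta AICc <= 2, ten bootstrap replicates and a 10,000-cell background
#' cap.
#'
#' @return Named list of defaults.
#' @export
default_pipeline_config <- function() {
  list(min_year = 1965, require_date = TRUE, min_dist_km = 5.5,
       thin_attempts = 10, r_threshold = 0.7, contribution_threshold = 1,
       contribution_runs = 10, rm_values = seq(0.5, 4, by = 0.5),
       classes = c("l", "q", "p", "h"), train_frac = 0.7, alpha = 0.05,
       E = 0.05, d_aicc_max = 2, replicates = 10, background_max = 10000,
       n_knots = 50, max_iter = 500, tol = 1e-5, proc_iterations = 500,
       mop_subset_frac = 0.10, run_mop = TRUE, coverage_pct_base = "current",
       seed = 1)
}

#' Validate a raw configuration document
#'
#' Fills defaults, rejects unknown keys, and reports every type/range
#' violation at once rather than stopping at the first.
#'
#' @param raw Named list (e.g. parsed from YAML with [yaml::read_yaml()]).
#' @return Validated configuration list of class `pipeline_config`.
#' @export
validate_config <- function(raw = list()) {
  if (is.null(raw)) raw <- list()
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, raw)
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(is.numeric(cfg$min_year) && cfg$min_year >= 0, "min_year must be >= 0")
  chk(is.numeric(cfg$min_dist_km) && cfg$min_dist_km > 0,
      "min_dist_km must be > 0")
  chk(is.numeric(cfg$r_threshold) && cfg$r_threshold > 0 &&
        cfg$r_threshold <= 1, "r_threshold must be in (0, 1]")
  chk(is.numeric(cfg$contribution_threshold) &&
        cfg$contribution_threshold >= 0 && cfg$contribution_threshold < 100,
      "contribution_threshold must be in [0, 100)")
  chk(is.numeric(cfg$rm_values) && length(cfg$rm_values) > 0 &&
        all(cfg$rm_values > 0), "rm_values must be positive")
  chk(all(cfg$classes %in% c("l", "q", "p", "h")) && length(cfg$classes) > 0,
      "classes must be a nonempty subset of l, q, p, h")
  chk(is.numeric(cfg$train_frac) && cfg$train_frac > 0 && cfg$train_frac < 1,
      "train_frac must be in (0, 1)")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha must be in (0, 1)")
  chk(is.numeric(cfg$E) && cfg$E >= 0 && cfg$E < 1, "E must be in [0, 1)")
  chk(is.numeric(cfg$d_aicc_max) && cfg$d_aicc_max >= 0,
      "d_aicc_max must be >= 0")
  chk(is.numeric(cfg$replicates) && cfg$replicates >= 1,
      "replicates must be >= 1")
  chk(is.numeric(cfg$background_max) && cfg$background_max >= 100,
      "background_max must be >= 100")
  chk(is.numeric(cfg$seed) && abs(cfg$seed) < 2^31, "seed must be a
      32-bit integer")
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read and validate a pipeline configuration file
#'
#' @param path Path to a YAML configuration document.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  validate_config(yaml::read_yaml(path))
}

write_table <- function(df, dir, file) {
  path <- file.path(dir, file)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full habitat-suitability analysis
#'
#' Stage order: clean -> dedup -> thin -> mask to the calibration region ->
#' correlation/VIF pruning -> contribution pruning -> candidate grid ->
#' evaluate/select -> final bootstrap-replicate fit on all occurrences ->
#' project each scenario (with clamping, plus MOP) -> MTSS threshold ->
#' binarize -> change, centroid-shift and protected-area summaries. All
#' randomness derives from the master seed via per-stage seeds.
#'
#' @param occurrences An `occurrence_table` (or path to a CSV).
#' @param current_stack Present-day predictor `niche_stack`.
#' @param scenarios Named list of scenario `niche_stack`s (may be empty).
#' @param m_area Optional calibration-region `niche_region`; also used as
#'   the record range filter when `range_polygons` is absent.
#' @param mpas Optional protected-area `niche_region`.
#' @param config A [validate_config()] list (raw lists are validated).
#' @param outdir Output directory for artifacts (created); `NULL` skips
#'   file output.
#' @param range_polygons Optional record range filter region.
#' @param verbose Log stage progress.
#' @return List of class `pipeline_result`: occurrence tables, predictor
#'   reports, candidate results, the final replicate set, per-scenario
#'   suitability/binary/change layers and summaries, the manifest.
#' @export
run_pipeline <- function(occurrences, current_stack, scenarios = list(),
                         m_area = NULL, mpas = NULL, config = list(),
                         outdir = NULL, range_polygons = NULL,
                         verbose = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  warnings_log <- character()
  note_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  if (is.character(occurrences)) occurrences <- read_occurrences(occurrences)
  occurrences <- occurrence_table(occurrences)

  # 1. clean / dedup / thin
  cln <- withCallingHandlers(
    clean_occurrences(occurrences,
                      cleaning_config(min_year = cfg$min_year,
                                      range_polygons = range_polygons %||%
                                        m_area,
                                      require_date = cfg$require_date)),
    warning = note_warn)
  say("cleaning: %d -> %d records", nrow(occurrences), nrow(cln$table))
  occ <- deduplicate(cln$table, current_stack$grid)
  say("deduplication: %d records", nrow(occ))
  occ <- thin(occ, thin_config(min_dist_km = cfg$min_dist_km,
                               n_attempts = cfg$thin_attempts,
                               seed = derive_seed(cfg$seed, "thin")))
  say("thinning: %d records retained", nrow(occ))

  # 2. mask and predictor selection
  stack <- if (!is.null(m_area)) mask_to_region(current_stack, m_area) else
    current_stack
  vif <- vifcor_prune(stack, cfg$r_threshold)
  say("vifcor: kept %s", paste(vif$kept, collapse = ", "))
  stack_v <- stack_subset(stack, vif$kept)
  contrib <- withCallingHandlers(
    contribution_prune(occ, stack_v,
                       threshold_pct = cfg$contribution_threshold,
                       runs = cfg$contribution_runs,
                       seed = derive_seed(cfg$seed, "contribution"),
                       background_max = cfg$background_max,
                       n_knots = cfg$n_knots),
    warning = note_warn)
  say("contribution pruning: kept %s", paste(contrib$kept, collapse = ", "))
  stack_m <- stack_subset(stack_v, contrib$kept)

  # 3. calibration grid
  split <- split_occurrences(occ, cfg$train_frac,
                             seed = derive_seed(cfg$seed, "split"))
  cands <- generate_candidates(cfg$rm_values, cfg$classes)
  crit <- selection_criteria(cfg$alpha, cfg$E, cfg$d_aicc_max)
  eval <- withCallingHandlers(
    evaluate_candidates(cands, split$train, split$test, stack_m, crit,
                        background_max = cfg$background_max,
                        seed = derive_seed(cfg$seed, "calibration"),
                        n_knots = cfg$n_knots, max_iter = cfg$max_iter,
                        tol = cfg$tol,
                        proc_iterations = cfg$proc_iterations),
    warning = note_warn)
  sel <- eval$results[eval$results$selected, , drop = FALSE]
  if (!nrow(sel)) {
    sel_id <- eval$results$id[which.min(eval$results$delta_aicc)]
    warnings_log <- c(warnings_log,
                      "no candidate met all three criteria; using the lowest delta AICc")
  } else sel_id <- sel$id[1L]
  say("selected candidate: %s", sel_id)
  sel_spec <- cands$spec[[match(sel_id, cands$id)]]

  # 4. final model: bootstrap replicates on the complete occurrence set
  occ_cells <- cell_index(stack_m$grid, occ$lon, occ$lat)
  occ_cells <- occ_cells[!is.na(occ_cells) & occ_cells %in%
                           data_cells(stack_m)]
  pres_env <- stack_env(stack_m, occ_cells)
  bg <- sample_background(stack_m, cfg$background_max,
                          seed = derive_seed(cfg$seed, "background"))
  bg_env <- stack_env(stack_m, bg)
  reps <- replicate_fit(pres_env, bg_env, sel_spec, n = cfg$replicates,
                        seed = derive_seed(cfg$seed, "replicates"),
                        stack = stack_m, max_iter = cfg$max_iter,
                        tol = cfg$tol, n_knots = cfg$n_knots)
  final <- fit_maxent(pres_env, bg_env, sel_spec, max_iter = cfg$max_iter,
                      tol = cfg$tol, n_knots = cfg$n_knots)
  say("final model: gain %.3f, training AUC %.3f", final$gain,
      training_auc(final))

  # 5. threshold on training data, binary current map
  thr <- mtss_threshold(cloglog_output(final, pres_env),
                        cloglog_output(final, bg_env))
  say("MTSS threshold: %.4f", thr$threshold)
  current_suit <- suitability_raster(final, stack_m, clamp = TRUE)
  current_bin <- binarize(current_suit, thr$threshold)
  areas <- cell_areas(stack_m$grid)
  cur_total <- sum(areas$values[!is.na(current_bin$values) &
                                  current_bin$values == 1])
  cur_centroid <- centroid(current_bin, areas)
  cur_overlap <- if (!is.null(mpas)) {
    mpa_overlap(current_bin, mpas, areas, cur_total)
  } else NULL

  # 6. scenarios: project, MOP, change, centroid shift, MPA overlap
  scen_out <- list()
  for (nm in names(scenarios)) {
    scen <- scenarios[[nm]]
    scen_m <- if (!is.null(m_area)) mask_to_region(scen, m_area) else scen
    suit <- project(final, scen_m, clamp = TRUE,
                    name = paste0("suitability_", nm))
    bin <- binarize(suit, thr$threshold)
    cm <- change_map(current_bin, bin)
    cs <- change_summary(cm, areas)
    ct <- centroid(bin, areas)
    sh <- shift(cur_centroid, ct)
    ov <- if (!is.null(mpas)) {
      mpa_overlap(bin, mpas, areas, cur_total,
                  current_inside_km2 = cur_overlap$inside_km2)
    } else NULL
    mopmap <- if (isTRUE(cfg$run_mop)) {
      mop(stack_m, scen_m, subset_frac = cfg$mop_subset_frac,
          sample_cap = cfg$background_max,
          seed = derive_seed(cfg$seed, paste0("mop_", nm)),
          vars = stack_names(stack_m))
    } else NULL
    scen_out[[nm]] <- list(suitability = suit, binary = bin,
                           change_map = cm, change_summary = cs,
                           centroid = ct, shift = sh, overlap = ov,
                           mop = mopmap)
    say("scenario %s: %+.1f%% habitat change, centroid shift %.1f km @ %.0f deg",
        nm, cs$total_change_pct, sh$distance_km, sh$bearing_deg)
  }

  result <- structure(list(
    config = cfg, cleaning_report = cln$report, occurrences = occ,
    vif = vif, contribution = contrib, variables = contrib$kept,
    split = split, candidates = eval$results, selected_id = sel_id,
    final_model = final, replicates = reps, threshold = thr,
    current = list(suitability = current_suit, binary = current_bin,
                   total_km2 = cur_total, centroid = cur_centroid,
                   overlap = cur_overlap),
    scenarios = scen_out, warnings = warnings_log),
    class = "pipeline_result")
  if (!is.null(outdir)) {
    result$manifest <- write_pipeline_artifacts(result, stack_m, areas,
                                                outdir)
  }
  result
}

# Write CSV/asc/JSON artifacts and a manifest with file hashes.
write_pipeline_artifacts <- function(result, stack, areas, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  add <- function(p) files <<- c(files, p)
  occ <- result$occurrences
  add(write_table(occ, outdir, "occurrences_thinned.csv"))
  add(write_table(data.frame(filter = names(result$cleaning_report),
                             count = as.integer(result$cleaning_report)),
                  outdir, "cleaning_report.csv"))
  add(write_table(result$vif$report$steps, outdir, "vifcor_steps.csv"))
  add(write_table(result$contribution$report, outdir,
                  "contribution_report.csv"))
  add(write_table(result$candidates[, setdiff(names(result$candidates),
                                              "spec")],
                  outdir, "candidate_results.csv"))
  add(write_raster(result$current$suitability,
                   file.path(outdir, "suitability_current.asc")))
  add(write_raster(result$current$binary,
                   file.path(outdir, "binary_current.asc")))
  write_model_json(result$final_model, file.path(outdir, "model.json"))
  add(file.path(outdir, "model.json"))
  tab1 <- list(); tab2 <- list(); shifts <- list()
  for (nm in names(result$scenarios)) {
    s <- result$scenarios[[nm]]
    add(write_raster(s$suitability,
                     file.path(outdir, sprintf("suitability_%s.asc", nm))))
    add(write_raster(s$change_map,
                     file.path(outdir, sprintf("change_%s.asc", nm))))
    cs <- s$change_summary
    tab1[[nm]] <- data.frame(
      scenario = nm, total_km2 = cs$total_future_km2,
      maintained_km2 = cs$maintained_km2, pct_maintained = cs$pct_maintained,
      gained_km2 = cs$gained_km2, pct_gained = cs$pct_gained,
      lost_km2 = cs$lost_km2, pct_lost = cs$pct_lost,
      total_change_pct = cs$total_change_pct)
    shifts[[nm]] <- data.frame(scenario = nm, lon = s$centroid[["lon"]],
                               lat = s$centroid[["lat"]],
                               distance_km = s$shift$distance_km,
                               bearing_deg = s$shift$bearing_deg)
    if (!is.null(s$overlap)) {
      tab2[[nm]] <- data.frame(
        scenario = nm, total_km2 = cs$total_future_km2,
        inside_km2 = s$overlap$inside_km2, pct_inside = s$overlap$pct_inside,
        outside_km2 = s$overlap$outside_km2,
        pct_outside = s$overlap$pct_outside,
        change_inside_km2 = s$overlap$change_inside_km2,
        change_inside_pct = s$overlap$change_inside_pct)
    }
  }
  if (length(tab1)) {
    add(write_table(do.call(rbind, tab1), outdir, "change_summaries.csv"))
    add(write_table(do.call(rbind, shifts), outdir, "centroid_shifts.csv"))
  }
  if (length(tab2)) {
    add(write_table(do.call(rbind, tab2), outdir, "mpa_overlap.csv"))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("nichecast")),
    config = unclass(result$config), selected = result$selected_id,
    threshold = result$threshold$threshold,
    warnings = result$warnings,
    files = lapply(setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_result> %d records, variables: %s; ",
                     "selected %s; MTSS %.4f; %d scenario(s)\n"),
              nrow(x$occurrences), paste(x$variables, collapse = ", "),
              x$selected_id, x$threshold$threshold, length(x$scenarios)))
  invisible(x)
}
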