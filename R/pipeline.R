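#' Analysis configuration with documented defaults
#'
#' Collects every tunable of the pipeline in one resolved list. Precedence is
#' caller argument over default; every [run_stage()] call serialises the
#' fully-resolved configuration next to its outputs so deterministic stages
#' re-run bit-identically from that file.
#'
#' @param ... overrides of the defaults below.
#' @return named list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  defaults <- list(
    magnitude_threshold = 200,     # V/m, sweet-spot coverage threshold
    coverage_fraction = 0.5,
    mirror = "left",               # fold bilateral fields onto one hemisphere
    candidate_magnitude = 800,     # V/m (0.8 V/mm), fiber candidate gate
    candidate_fraction = 0.005,
    sweet_top_fraction = 0.01,
    score_peak_fraction = 0.05,
    step_mm = 0.5,
    fwhm_spot_mm = 2,              # visualisation smoothing of spot maps
    fwhm_density_mm = 8,           # visualisation smoothing of density maps
    k = 5,
    n_permutations = 5000,
    seed = 1,
    n_patients = 60,
    cohort_dir = NULL,
    cohort_dirs = NULL,            # named vector of dirs for specificity
    mahalanobis_cut = 2,
    out_dir = NULL,
    rng_kind = "Mersenne-Twister")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  defaults[names(over)] <- over
  structure(defaults, class = "analysis_config")
}

#' Run one pipeline stage
#'
#' Thin orchestration over the package's fitting and validation functions.
#' Stages: `simulate` (write a phantom cohort directory), `sweetspot` (fit
#' and write r/p/mask maps + scores), `fiberfilter` (fit and write the
#' streamline table, sweet TRK subset + scores), `crossval` (fivefold CV with
#' permutation p), `report` (collate stage outputs into one JSON). Each
#' stage writes `config_resolved.json` and a `log.json` with parameter and
#' count bookkeeping into `config$out_dir`.
#'
#' @param stage one of `"simulate"`, `"sweetspot"`, `"fiberfilter"`,
#'   `"crossval"`, `"specificity"`, `"controls"`, `"report"`.
#' @param config an [analysis_config()].
#' @return stage-specific result, invisibly (artifacts on disk).
#' @export
run_stage <- function(stage = c("simulate", "sweetspot", "fiberfilter",
                                "crossval", "specificity", "controls",
                                "report"),
                      config = analysis_config()) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "analysis_config"))
  out <- config$out_dir
  if (is.null(out)) stop("config$out_dir is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  res <- switch(stage,
                simulate = stage_simulate(config),
                sweetspot = stage_sweetspot(config),
                fiberfilter = stage_fiberfilter(config),
                crossval = stage_crossval(config),
                specificity = stage_specificity(config),
                controls = stage_controls(config),
                report = stage_report(config))
  cfg <- unclass(config)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, TRUE)],
                       file.path(out, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA)
  log <- c(list(stage = stage,
                elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))),
           res$log)
  jsonlite::write_json(log, file.path(out, paste0("log_", stage, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(res$value)
}

stage_simulate <- function(config) {
  scene <- phantom_scene(seed = config$seed)
  truth <- simulation_truth("spot",
                            planted_spot_center = scene$nucleus$left$center,
                            seed = config$seed)
  coh <- make_cohort(scene, config$n_patients, truth,
                     write_dir = config$out_dir)
  list(value = coh,
       log = list(n_patients = length(coh$records),
                  n_efields = 2L * length(coh$records),
                  target_kind = truth$target_kind))
}

load_stage_cohort <- function(config) {
  dir <- config$cohort_dir
  if (is.null(dir)) stop("config$cohort_dir is required for this stage")
  tab <- file.path(dir, "cohort.csv")
  man <- file.path(dir, "manifest.csv")
  if (!file.exists(tab)) stop("no cohort table at ", tab)
  load_cohort(tab, if (file.exists(man)) man else NULL)
}

stage_sweetspot <- function(config) {
  coh <- load_stage_cohort(config)
  model <- sweet_spot_map(coh,
                          magnitude_threshold = config$magnitude_threshold,
                          coverage_fraction = config$coverage_fraction,
                          mirror = config$mirror)
  out <- config$out_dir
  save_volume(model$r_map, file.path(out, "r_map.nii"))
  save_volume(model$p_map, file.path(out, "p_map.nii"))
  save_volume(model$mask, file.path(out, "mask.nii"))
  save_volume(gaussian_smooth(model$r_map, config$fwhm_spot_mm),
              file.path(out, "r_map_smoothed.nii"))
  scores <- predict(model, coh)
  utils::write.csv(data.frame(patient_id = names(scores),
                              sweet_spot_score = as.numeric(scores),
                              improvement_pct = improvements(coh)),
                   file.path(out, "scores.csv"), row.names = FALSE)
  list(value = model,
       log = list(mask_voxels = sum(model$mask$data), n_obs = model$n_obs,
                  peak_r = max(model$r_map$data)))
}

stage_fiberfilter <- function(config) {
  coh <- load_stage_cohort(config)
  set <- load_streamlines(file.path(config$cohort_dir, "bundles.trk"))
  model <- fiber_filter(coh, set,
                        candidate_magnitude = config$candidate_magnitude,
                        candidate_fraction = config$candidate_fraction,
                        sweet_top_fraction = config$sweet_top_fraction,
                        score_peak_fraction = config$score_peak_fraction,
                        step_mm = config$step_mm, mirror = config$mirror)
  out <- config$out_dir
  utils::write.csv(fiber_model_table(model),
                   file.path(out, "fiber_model.csv"), row.names = FALSE)
  if (length(model$sweet_ids) > 0)
    save_streamlines(model$sweet_streamlines,
                     file.path(out, "sweet_streamlines.tck"))
  scores <- predict(model, coh)
  utils::write.csv(data.frame(patient_id = names(scores),
                              fiber_r_score = as.numeric(scores),
                              improvement_pct = improvements(coh)),
                   file.path(out, "scores.csv"), row.names = FALSE)
  list(value = model,
       log = list(n_streamlines = length(model$r),
                  n_candidates = sum(model$candidate),
                  n_sweet = length(model$sweet_ids)))
}

stage_crossval <- function(config) {
  coh <- load_stage_cohort(config)
  cv <- sweet_spot_cv(coh, k = config$k,
                      n_permutations = config$n_permutations,
                      seed = config$seed,
                      magnitude_threshold = config$magnitude_threshold,
                      coverage_fraction = config$coverage_fraction,
                      mirror = config$mirror)
  jsonlite::write_json(
    list(k = cv$k, seed = cv$seed, n_permutations = cv$n_permutations,
         scheme = cv$scheme,
         rho_obs = cv$rho_obs, p_perm = cv$p_perm,
         fold_of_patient = as.list(cv$fold_of_patient),
         estimates = as.list(cv$estimates)),
    file.path(config$out_dir, "cv_report.json"), auto_unbox = TRUE,
    digits = NA)
  list(value = cv, log = list(rho_obs = cv$rho_obs, p_perm = cv$p_perm))
}

fit_fiber_for_dir <- function(dir, config) {
  coh <- load_cohort(file.path(dir, "cohort.csv"),
                     file.path(dir, "manifest.csv"))
  set <- load_streamlines(file.path(dir, "bundles.trk"))
  model <- fiber_filter(coh, set,
                        candidate_magnitude = config$candidate_magnitude,
                        candidate_fraction = config$candidate_fraction,
                        sweet_top_fraction = config$sweet_top_fraction,
                        score_peak_fraction = config$score_peak_fraction,
                        step_mm = config$step_mm, mirror = config$mirror)
  list(cohort = coh, model = model)
}

stage_specificity <- function(config) {
  dirs <- config$cohort_dirs
  if (is.null(dirs) || length(dirs) < 2)
    stop("config$cohort_dirs must name at least 2 cohort directories")
  if (is.null(names(dirs))) names(dirs) <- basename(unlist(dirs))
  fits <- lapply(dirs, fit_fiber_for_dir, config = config)
  models <- lapply(fits, `[[`, "model")
  cohorts <- lapply(fits, `[[`, "cohort")
  sm <- cross_disorder_matrix(models, cohorts)
  ratios <- specificity_ratio(models)
  out <- config$out_dir
  utils::write.csv(as.data.frame(sm$rho),
                   file.path(out, "specificity_matrix.csv"))
  utils::write.csv(as.data.frame(sm$p),
                   file.path(out, "specificity_matrix_p.csv"))
  utils::write.csv(do.call(cbind, lapply(ratios, as.numeric)),
                   file.path(out, "specificity_ratios.csv"),
                   row.names = FALSE)
  list(value = sm,
       log = list(n_disorders = length(dirs),
                  diagonal_rho = as.numeric(diag(sm$rho))))
}

stage_controls <- function(config) {
  dir <- config$cohort_dir
  if (is.null(dir)) stop("config$cohort_dir is required for this stage")
  cf <- file.path(dir, "contacts.csv")
  if (!file.exists(cf)) stop("no contact table at ", cf)
  contacts <- utils::read.csv(cf, stringsAsFactors = FALSE)
  set <- load_streamlines(file.path(dir, "bundles.trk"))
  groups <- rep("all", length(set$streamlines))
  gj <- file.path(dir, "bundle_groups.json")
  if (file.exists(gj))
    groups <- unlist(jsonlite::read_json(gj)$groups)
  act <- contacts[contacts$active, , drop = FALSE]
  # pool hemispheres by reflecting the off-side contacts across the midline
  if (config$mirror == "left") act$x[act$hemisphere == "right"] <-
      -act$x[act$hemisphere == "right"]
  if (config$mirror == "right") act$x[act$hemisphere == "left"] <-
      -act$x[act$hemisphere == "left"]
  std <- act[, c("x", "y", "z")]
  res <- gaussian_contact_control(as.matrix(std), set,
                                  mahalanobis_cut = config$mahalanobis_cut,
                                  step_mm = config$step_mm)
  sel_by_group <- tapply(res$selected, groups, sum)
  tot_by_group <- table(groups)[names(sel_by_group)]
  prop <- equality_of_proportions(as.integer(sel_by_group),
                                  as.integer(tot_by_group))
  tt <- two_sample_ttest(contacts$z[contacts$hemisphere == "left" &
                                      contacts$active],
                         contacts$z[contacts$hemisphere == "right" &
                                      contacts$active])
  out <- list(gaussian_mean = as.numeric(res$mean),
              gaussian_cov = res$cov,
              selected_by_group = as.list(sel_by_group),
              total_by_group = stats::setNames(
                as.list(as.integer(tot_by_group)), names(sel_by_group)),
              proportions_chi2 = prop$chi2, proportions_p = prop$p,
              contact_depth_t = tt$t, contact_depth_p = tt$p)
  jsonlite::write_json(out, file.path(config$out_dir, "controls.json"),
                       auto_unbox = TRUE, digits = NA)
  list(value = out,
       log = list(n_contacts = nrow(std),
                  n_selected = sum(res$selected)))
}

stage_report <- function(config) {
  out <- config$out_dir
  collect <- list()
  for (f in c("scores.csv", "cv_report.json", "fiber_model.csv")) {
    p <- file.path(out, f)
    if (file.exists(p))
      collect[[f]] <- if (grepl("json$", f)) jsonlite::read_json(p)
      else utils::read.csv(p)
  }
  summary <- list(artifacts = names(collect))
  if (!is.null(collect[["cv_report.json"]]))
    summary$cv <- collect[["cv_report.json"]][c("rho_obs", "p_perm")]
  jsonlite::write_json(summary, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  list(value = summary, log = list(n_artifacts = length(collect)))
}
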