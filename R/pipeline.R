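# End-to-end orchestration: phantom pair -> DVC -> rigid removal ->
# strains / kinematics -> clinical metrics -> (optional) cohort regression,
# with a deterministic manifest.

#' Pipeline run configuration
#'
#' Bundles every tunable of a pipeline run: the phantom geometry and
#' deformation (standing in for a neutral/extension scan pair), the
#' correlation schedule, the precision constants used for screening, and
#' the statistical thresholds.
#'
#' @param seed RNG seed driving every stochastic stage.
#' @param geometry a [spine_geometry()].
#' @param deformation a [deformation_spec()] applied between the "neutral"
#'   and "extension" phantom volumes.
#' @param spacing isotropic voxel size (mm).
#' @param schedule a [subset_schedule()].
#' @param precision named list of precision constants, see
#'   [dvc_precision()].
#' @param screen_factor order-of-magnitude screening multiple.
#' @param p_out backward-elimination threshold.
#' @param alpha significance / diagnostics level.
#' @param search direct-correlation search half-width (voxels).
#' @param cohort optional list `(n, true_betas, noise_sd, outcomes)`
#'   driving a synthetic-cohort regression stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            geometry = spine_geometry(levels = 2L,
                              depth = 28, vertebra_height = 18,
                              disc_anterior = 11, disc_posterior = 8.5,
                              sacral_angle = 38, width = 26),
                            deformation = deformation_spec(
                              translation = c(1.0, -0.6, 0.3),
                              rotation_axis = c(0, 0, 1),
                              rotation_angle = 1.0),
                            spacing = 0.58,
                            schedule = subset_schedule(),
                            precision = dvc_precision(),
                            screen_factor = 10, p_out = 0.10, alpha = 0.05,
                            search = 2L, cohort = NULL) {
  stopifnot(inherits(geometry, "spine_geometry"),
            inherits(deformation, "deformation_spec"),
            inherits(schedule, "subset_schedule"))
  consts <- unlist(precision)
  if (any(consts <= 0)) stop_input("all precision constants must be positive")
  if (screen_factor <= 0 || p_out <= 0 || alpha <= 0) {
    stop_input("screen_factor, p_out and alpha must be positive")
  }
  structure(list(seed = as.integer(seed), geometry = geometry,
                 deformation = deformation, spacing = spacing,
                 schedule = schedule, precision = precision,
                 screen_factor = screen_factor, p_out = p_out,
                 alpha = alpha, search = as.integer(search),
                 cohort = cohort),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on a synthetic scan pair
#'
#' Generates the spine phantom and its deformed counterpart, recovers the
#' displacement field by multipass correlation, estimates and removes the
#' common rigid-body motion, maps Green-Lagrange strains and summarises
#' them per disc, computes vertebral translations / anterolisthesis with
#' precision screening, measures the clinical landmark metrics, and (when
#' configured) fits the backward-regression models on a synthetic cohort.
#' The run is deterministic given the seed; the manifest records the
#' package version, a configuration hash, and per-stage logs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, volumes (NIfTI), the
#'   displacement field, landmark JSON and all result tables (CSV/JSON)
#'   are written there.
#' @return a report bundle: list with `phantom` truth, `field`,
#'   `field_residual`, `rigid`, `strain_summary`, `kinematics`, `metrics`,
#'   `models` (or `NULL`) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(fmt, ...) {
    log <<- c(log, sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_input("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  ph <- stage("phantom", make_spine_phantom(config$geometry,
                                            spacing = config$spacing,
                                            seed = config$seed))
  note("phantom: %s voxels", paste(dim(ph$volume), collapse = "x"))
  warped <- stage("warp", warp_volume(ph$texture, config$deformation,
                                      dim(ph$volume), config$spacing))
  field <- stage("dvc", run_multipass(ph$volume, warped$volume,
                                      config$schedule,
                                      search = config$search))
  note("dvc: %d/%d valid nodes", sum(field$valid), length(field$valid))
  rigid <- stage("rigid", estimate_rigid(field))
  residual <- stage("rigid", remove_rigid(field, rigid))
  strain <- stage("strain", green_lagrange(displacement_gradient(residual)))
  discs <- ph$truth$disc$level
  strain_summary <- stage("strain",
                          summarize_levels(strain, ph$mask, discs))
  vertebrae <- ph$landmarks$vertebrae
  kin <- stage("kinematics",
               vertebral_kinematics_table(field, ph$mask, vertebrae,
                                          precision = config$precision,
                                          factor = config$screen_factor))
  kin$vertebrae$screen <- vapply(seq_len(nrow(kin$vertebrae)), function(i) {
    if (!kin$vertebrae$resolved[i]) return("unresolvable")
    precision_screen(kin$vertebrae$vtot[i], config$precision$vtot,
                     config$screen_factor)
  }, character(1))
  metrics <- stage("metrics", spine_metrics(ph$landmarks))
  models <- NULL
  if (!is.null(config$cohort)) {
    co <- config$cohort
    sim <- stage("regress", make_synthetic_cohort(
      n = co$n, true_betas = co$true_betas, noise_sd = co$noise_sd,
      seed = config$seed + 1000L))
    models <- stage("regress", fit_level_models(
      sim$table, outcomes = co$outcomes %||% "outcome",
      predictors = cohort_predictors(), p_out = config$p_out,
      alpha = config$alpha))
    models$truth <- sim$truth
    note("regress: %d models fitted", length(models$models))
  }

  manifest <- list(
    package = "spinedvc",
    version = as.character(utils::packageVersion("spinedvc")),
    seed = config$seed,
    config_hash = hash_object(config[setdiff(names(config), "cohort")]),
    schedule = paste(config$schedule$sizes, collapse = "-"),
    stages = log)

  report <- list(phantom = ph$truth, field = field,
                 field_residual = residual, rigid = rigid,
                 strain = strain, strain_summary = strain_summary,
                 kinematics = kin, metrics = metrics, models = models,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(ph$volume, file.path(out_dir, "neutral.nii.gz"))
    write_volume(warped$volume, file.path(out_dir, "extension.nii.gz"))
    write_volume(ph$mask, file.path(out_dir, "mask.nii.gz"))
    write_landmarks(ph$landmarks, file.path(out_dir, "landmarks.json"))
    write_displacement_field(field, file.path(out_dir, "field"))
    jsonlite::write_json(list(translation = rigid$translation,
                              rotation = rigid$rotation,
                              centroid = rigid$centroid),
                         file.path(out_dir, "rigid.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    utils::write.csv(strain_summary,
                     file.path(out_dir, "strain_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(kin$vertebrae, file.path(out_dir, "kinematics.csv"),
                     row.names = FALSE)
    utils::write.csv(kin$segments, file.path(out_dir, "segments.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics$levels, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Column means and standard deviations of a cohort table
#'
#' Summarises numeric demographic columns as mean and sample (n-1)
#' standard deviation, rounded to one decimal for reporting.
#'
#' @param table data.frame with at least 2 rows.
#' @param columns columns to summarise (default: all numeric columns).
#' @return data.frame with `column`, `mean`, `sd`, `n`.
#' @examples
#' cohort_summary(load_demographics())
#' @export
cohort_summary <- function(table, columns = NULL) {
  if (nrow(table) < 2L) stop_input("need at least 2 rows")
  columns <- columns %||% names(table)[vapply(table, is.numeric, logical(1))]
  bad <- columns[!vapply(columns, function(cn) {
    cn %in% names(table) && is.numeric(table[[cn]])
  }, logical(1))]
  if (length(bad)) {
    stop_input("input error: non-numeric or missing column(s): %s",
               paste(bad, collapse = ", "))
  }
  data.frame(
    column = columns,
    mean = vapply(columns, function(cn) round(mean(table[[cn]]), 1),
                  numeric(1)),
    sd = vapply(columns, function(cn) round(stats::sd(table[[cn]]), 1),
                numeric(1)),
    n = nrow(table), row.names = NULL)
}

#' Reference cohort demographics
#'
#' The packaged demographics table of the 15-participant reference cohort
#' (gender, age, height, weight, BMI) used for cohort-summary reporting.
#'
#' @return data.frame with one row per participant.
#' @export
load_demographics <- function() {
  utils::read.csv(system.file("extdata", "cohort_demographics.csv",
                              package = "spinedvc", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
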