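#' Read and validate a run configuration
#'
#' A run configuration is a JSON object tying the stages together. Fields
#' (with defaults): \code{phantom} (path to a phantom JSON, or the string
#' \code{"reference"}), \code{pattern} (\code{n_electrodes}, \code{skip},
#' \code{current_ma}, \code{frequency_khz}), \code{noise} (\code{type},
#' \code{sd} or \code{fraction}, \code{seed}), \code{mesh}
#' (\code{target_element_size}), \code{inversion} (\code{sigma0},
#' \code{lambda}, \code{alpha}, \code{within_weight}, \code{cross_weight},
#' \code{tol}, \code{max_iter}, \code{electrode_model},
#' \code{contact_impedance}), \code{cohort} (\code{fixture} policy or a
#' cohort CSV path), \code{out_dir}. Validation errors name the offending
#' field.
#'
#' @param path JSON config path
#' @return validated config list
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop("config file does not exist: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$configPath <- normalizePath(path)
  validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
  bad <- function(field, why) stop(sprintf("invalid config field '%s': %s",
                                           field, why), call. = FALSE)
  cfg$phantom <- cfg$phantom %||% "reference"
  if (!identical(cfg$phantom, "reference") && !file.exists(cfg$phantom))
    bad("phantom", paste("file not found:", cfg$phantom))
  pat <- cfg$pattern %||% list()
  pat$n_electrodes <- pat$n_electrodes %||% 32L
  pat$skip <- pat$skip %||% 4L
  pat$current_ma <- pat$current_ma %||% 2
  pat$frequency_khz <- pat$frequency_khz %||% 50
  if (pat$skip < 0 || pat$skip >= pat$n_electrodes - 1)
    bad("pattern.skip", "need 0 <= skip < n_electrodes - 1")
  cfg$pattern <- pat
  mesh <- cfg$mesh %||% list()
  mesh$target_element_size <- mesh$target_element_size %||% 2.5
  if (mesh$target_element_size <= 0) bad("mesh.target_element_size", "must be > 0")
  cfg$mesh <- mesh
  noise <- cfg$noise %||% list(type = "none")
  if (!noise$type %in% c("none", "additive", "multiplicative"))
    bad("noise.type", "must be none, additive or multiplicative")
  if (noise$type != "none" && is.null(noise$seed))
    bad("noise.seed", "required when noise is applied")
  cfg$noise <- noise
  inv <- cfg$inversion %||% list()
  inv$lambda <- inv$lambda %||% NA_real_
  inv$alpha <- inv$alpha %||% 10
  inv$within_weight <- inv$within_weight %||% 1
  inv$cross_weight <- inv$cross_weight %||% 0.05
  inv$tol <- inv$tol %||% 1e-3
  inv$max_iter <- inv$max_iter %||% 25L
  inv$electrode_model <- inv$electrode_model %||% "complete"
  inv$contact_impedance <- inv$contact_impedance %||% 30
  if (!inv$electrode_model %in% c("complete", "point"))
    bad("inversion.electrode_model", "must be complete or point")
  cfg$inversion <- inv
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg
}

configPhantom <- function(cfg) {
  if (identical(cfg$phantom, "reference")) referencePhantom()
  else readPhantomSpec(cfg$phantom)
}

writeManifest <- function(cfg, outDir, stage, extra = list()) {
  man <- c(list(
    stage = stage,
    package_version = as.character(utils::packageVersion("liverEIT")),
    r_version = as.character(getRversion()),
    config = cfg[setdiff(names(cfg), "configPath")],
    config_md5 = if (!is.null(cfg$configPath))
      unname(tools::md5sum(cfg$configPath)) else NULL,
    seed = cfg$noise$seed), extra)
  jsonlite::write_json(man, file.path(outDir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Simulate boundary-voltage data from a configuration
#'
#' Builds the configured phantom and mesh, runs the forward solver under the
#' configured skip pattern, applies the configured noise, and writes the
#' measurement CSV (+ JSON sidecar), the mesh, and a manifest recording the
#' configuration and seed, so the run is reproducible bit for bit.
#'
#' @param cfg validated config list from \code{\link{readRunConfig}}
#' @param outDir output directory (defaults to the config's \code{out_dir})
#' @return path of the measurement CSV, invisibly
#' @export
runSimulate <- function(cfg, outDir = cfg$out_dir) {
  cfg <- validateRunConfig(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  spec <- configPhantom(cfg)
  mesh <- buildPhantom(spec, cfg$mesh$target_element_size)
  pat <- makeSkipPattern(cfg$pattern$n_electrodes, cfg$pattern$skip,
                         cfg$pattern$current_ma)
  data <- solveForward(mesh, trueConductivity(mesh), pat,
                       electrodeModel = cfg$inversion$electrode_model,
                       contactImpedance = cfg$inversion$contact_impedance,
                       frequencyKHz = cfg$pattern$frequency_khz)
  if (cfg$noise$type == "additive")
    data <- addNoise(data, "additive", sd = cfg$noise$sd, seed = cfg$noise$seed)
  else if (cfg$noise$type == "multiplicative")
    data <- addNoise(data, "multiplicative", fraction = cfg$noise$fraction,
                     seed = cfg$noise$seed)
  csv <- file.path(outDir, "measurements.csv")
  writeMeasurements(data, csv)
  writeMesh(mesh, file.path(outDir, "mesh.txt"))
  writeManifest(cfg, outDir, "simulate",
                list(n_measurements = length(data@voltages)))
  invisible(csv)
}

#' Reconstruct conductivity from simulated or imported measurements
#'
#' Rebuilds the configured mesh, reads the measurement CSV, runs the iterated
#' Gauss-Newton reconstruction and writes the conductivity map, a JSON
#' report (lambda, iterations, objective trace, liver mean and SD) and a
#' manifest. No partial outputs are left behind on error.
#'
#' @param cfg validated config list
#' @param dataPath measurement CSV path (sidecar expected alongside)
#' @param outDir output directory
#' @return the \code{\link{ReconstructionResult}}, invisibly
#' @export
runReconstruct <- function(cfg, dataPath, outDir = cfg$out_dir) {
  cfg <- validateRunConfig(cfg)
  data <- readMeasurements(dataPath)
  spec <- configPhantom(cfg)
  mesh <- buildPhantom(spec, cfg$mesh$target_element_size)
  if (nchar(data@meshId) && data@meshId != mesh@meshId)
    stop("measurement data were simulated on a different mesh than the config builds",
         call. = FALSE)
  inv <- cfg$inversion
  res <- reconstruct(mesh, data, sigma0 = inv$sigma0,
                     reg = regularization(inv$lambda, inv$alpha,
                                          inv$within_weight, inv$cross_weight),
                     tol = inv$tol, maxIter = inv$max_iter,
                     electrodeModel = inv$electrode_model,
                     contactImpedance = inv$contact_impedance)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeReconstruction(res, mesh, file.path(outDir, "conductivity_map.txt"),
                      file.path(outDir, "reconstruction_report.json"))
  writeManifest(cfg, outDir, "reconstruct",
                list(converged = res@converged, iterations = res@iterations))
  invisible(res)
}

#' Run the cohort statistics stage
#'
#' Runs the correlation grid of \code{\link{runStudyAnalysis}} on either the
#' packaged study tables (\code{cohortPath = "fixture"}) or a cohort CSV,
#' writes the reports as CSV and JSON plus scatter plots with slope
#' confidence bands, and a manifest.
#'
#' @param cfg validated config list (\code{cfg$cohort$fixture} selects the
#'   exclusion policy for fixture runs, default \code{"study_n16"})
#' @param cohortPath \code{"fixture"} or a cohort CSV path
#' @param outDir output directory
#' @param plots write PNG scatter plots (default TRUE)
#' @return the report data.frame, invisibly
#' @export
runStats <- function(cfg, cohortPath = "fixture", outDir = cfg$out_dir,
                     plots = TRUE) {
  cfg <- validateRunConfig(cfg)
  policy <- (cfg$cohort %||% list())$fixture %||% "study_n16"
  if (!policy %in% c("none", "study_n16", "study_n18"))
    stop("invalid config field 'cohort.fixture': unknown policy ", policy,
         call. = FALSE)
  cohort <- if (identical(cohortPath, "fixture")) loadStudyTables(policy)
            else setExclusionPolicy(readCohort(cohortPath), policy)
  reports <- runStudyAnalysis(cohort)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeReports(reports, file.path(outDir, "correlation_reports.csv"),
               file.path(outDir, "correlation_reports.json"))
  if (plots) {
    rec <- cohortRecords(cohort)
    grDevices::png(file.path(outDir, "eit_vs_pdff.png"), width = 720,
                   height = 560)
    print(correlationPlot(rec$pdff, rec$eit_mean, "MRI PDFF (%)",
                          "Liver EIT conductivity (S/m)"))
    grDevices::dev.off()
  }
  writeManifest(cfg, outDir, "stats", list(policy = policy,
                                           n = nrow(cohortRecords(cohort))))
  invisible(reports)
}
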