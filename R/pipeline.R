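## End-to-end pipeline: ingestion -> controllers -> calibration -> metrics ->
## reports, driven by a YAML run configuration. Human-readable logs go to
## standard error (message()); machine artifacts go to files only. Every
## artifact records a hash of the configuration so reports refuse to mix
## profiles generated under different settings.

#' Load a run configuration
#'
#' A run configuration is a YAML file (or equivalent list) with fields:
#' `gait_type` (`walk`/`run`), `output_dir`, `toe_off_percent` (walking),
#' `param_file` (optional fiber/controller YAML), `reference` (path or
#' `"walk"`/`"run"` for the bundled synthetic stand-ins), `calibration`
#' (`anchor_speed`, optional `target_peak` overriding the reference mean
#' peak) and `conditions`: a list with one entry per speed, each giving
#' `speed` plus either `files` (per-quantity csv path/column/negate, and a
#' `phase_column`) or `synthetic` (a seed; generator defaults for the gait
#' and speed are used).
#'
#' @param config path to a YAML file, or a list already in that shape.
#' @return The validated configuration list, with a `hash` attribute.
#' @export
loadRunConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("run config not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a list")
  if (is.null(config$gait_type) || !config$gait_type %in% .GAIT_TYPES)
    stop("config needs gait_type 'walk' or 'run'")
  if (is.null(config$output_dir)) stop("config needs output_dir")
  if (is.null(config$conditions)) config$conditions <- list()
  if (length(config$conditions)) {
    if (is.null(config$calibration$anchor_speed))
      stop("config needs calibration$anchor_speed (one anchor per gait type)")
    sp <- vapply(config$conditions, function(cn) as.numeric(cn$speed), numeric(1))
    if (!config$calibration$anchor_speed %in% sp)
      stop("calibration anchor_speed must be one of the condition speeds")
  }
  attr(config, "hash") <- .configHash(config)
  config
}

.configHash <- function(config) {
  attr(config, "hash") <- NULL
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

.conditionDynamics <- function(cond, gaitType) {
  if (!is.null(cond$synthetic)) {
    seed <- if (!is.null(cond$synthetic$seed)) cond$synthetic$seed else 1L
    noise <- if (!is.null(cond$synthetic$noise_sd)) cond$synthetic$noise_sd else 0
    return(synthDynamics(SynthConfig(gaitType, as.numeric(cond$speed),
                                     noiseSd = noise, seed = as.integer(seed))))
  }
  if (is.null(cond$files))
    stop("condition needs either 'files' or 'synthetic'")
  phaseCol <- if (!is.null(cond$phase_column)) cond$phase_column else "phase"
  readOne <- function(quantity) {
    spec <- cond$files[[quantity]]
    if (is.null(spec)) stop("condition files must name ", quantity)
    if (!file.exists(spec$path)) stop("input file does not exist: ", spec$path)
    readCurveTable(spec$path,
                   valueColumn = if (!is.null(spec$column)) spec$column else quantity,
                   quantity = quantity, phaseKind = "stance",
                   phaseColumn = phaseCol,
                   negate = isTRUE(spec$negate))
  }
  MtuDynamics(readOne("joint_torque"), readOne("fascicle_velocity"),
              readOne("tendon_velocity"), speed = as.numeric(cond$speed),
              gaitType = gaitType)
}

.fmtSpeed <- function(speed) gsub("[.]", "p", sprintf("%.1f", speed))

#' Generate calibrated FS and DB profiles for every condition
#'
#' For each condition the muscle-tendon dynamics are ingested (or
#' synthesized), resampled to the 101-point stance grid, and turned into
#' uncalibrated FS and DB profiles. The condition at the calibration anchor
#' speed is peak-matched to the target peak (the reference study's mean peak
#' torque unless `calibration$target_peak` overrides it), and the anchor's
#' scale factor is reused for every other speed of the gait, one constant per
#' controller. Calibrated and uncalibrated profiles are written as csv, with
#' a per-condition metadata sidecar recording controller, scale factor,
#' deadband threshold, anchor speed and the configuration hash.
#'
#' @param config run configuration (path or list, see [loadRunConfig()]).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `profiles` (per condition, calibrated FS/DB
#'   [TorqueProfile-class]s and the [DeadbandResult-class]), `scaleFactors`,
#'   and the configuration `hash`.
#' @export
runGenerate <- function(config, quiet = FALSE) {
  config <- loadRunConfig(config)
  hash <- attr(config, "hash")
  say <- function(...) if (!quiet) message(...)
  if (!length(config$conditions)) {
    warning("no conditions configured; nothing to generate")
    return(invisible(list(profiles = list(), scaleFactors = NULL, hash = hash)))
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  gait <- config$gait_type
  ctrl <- defaultControllerConfig(gait, config$param_file)
  ref <- loadReferenceParams(if (!is.null(config$reference)) config$reference
                             else gait)
  targetPeak <- if (!is.null(config$calibration$target_peak))
    config$calibration$target_peak else ref$meanParams@peakTorque

  speeds <- vapply(config$conditions, function(cn) as.numeric(cn$speed),
                   numeric(1))
  raw <- lapply(config$conditions, function(cn) {
    dyn <- resample(.conditionDynamics(cn, gait), 101L)
    db <- deadbandSpeed(dyn)
    say(sprintf("[generate] %s %.1f m/s: deadband %.4g l0/s at %.1f%% stance",
                gait, dyn@speed, db@thresholdSpeed, db@tendonPeakPhase))
    list(dyn = dyn, deadband = db,
         fs = fsProfile(dyn, ctrl), db = dbProfile(dyn, ctrl, threshold = db))
  })

  anchorI <- which(speeds == config$calibration$anchor_speed)[1L]
  cFS <- scaleFactor(calibrate(raw[[anchorI]]$fs, targetPeak))
  cDB <- scaleFactor(calibrate(raw[[anchorI]]$db, targetPeak))
  say(sprintf("[generate] anchor %.1f m/s, target peak %.3f Nm/kg: C_FS = %.5g, C_DB = %.5g",
              speeds[anchorI], targetPeak, cFS, cDB))

  profiles <- vector("list", length(raw))
  names(profiles) <- .fmtSpeed(speeds)
  for (i in seq_along(raw)) {
    fsCal <- applyScaleFactor(raw[[i]]$fs, cFS)
    dbCal <- applyScaleFactor(raw[[i]]$db, cDB)
    stem <- file.path(config$output_dir, sprintf("%s_%s", gait,
                                                 .fmtSpeed(speeds[i])))
    writeCurveTable(raw[[i]]$fs, paste0(stem, "_FS_uncalibrated.csv"))
    writeCurveTable(raw[[i]]$db, paste0(stem, "_DB_uncalibrated.csv"))
    writeCurveTable(fsCal, paste0(stem, "_FS.csv"))
    writeCurveTable(dbCal, paste0(stem, "_DB.csv"))
    meta <- list(gait_type = gait, speed = speeds[i],
                 anchor_speed = speeds[anchorI],
                 config_hash = hash,
                 deadband_threshold = raw[[i]]$deadband@thresholdSpeed,
                 tendon_peak_phase = raw[[i]]$deadband@tendonPeakPhase,
                 scale_factors = list(FS = cFS, DB = cDB))
    writeLines(yaml::as.yaml(meta), paste0(stem, "_meta.yaml"))
    profiles[[i]] <- list(FS = fsCal, DB = dbCal, deadband = raw[[i]]$deadband,
                          dynamics = raw[[i]]$dyn)
  }
  invisible(list(profiles = profiles,
                 scaleFactors = c(FS = cFS, DB = cDB), hash = hash))
}

.referenceProfileAt <- function(ref, speed, useEo) {
  params <- if (useEo && !is.null(ref$eoAnchors))
    suppressWarnings(eoParams(speed, ref$eoAnchors, extrapolate = TRUE))
  else ref$meanParams
  prof <- hitlCurve(params, seq(0, 100, by = 1),
                    phaseKind = if (ref$phaseKind == "gait") "gait" else "stance",
                    controller = if (useEo && !is.null(ref$eoAnchors)) "EO"
                    else "HITL")
  if (ref$phaseKind == "gait")
    prof <- gaitToStance(prof, ref$toeOffPercent)
  resample(prof, 101L)
}

.inRange <- function(x, rng) x >= rng[1L] && x <= rng[2L]

#' Compare generated profiles with the reference
#'
#' Reads the calibrated profiles written by [runGenerate()] (refusing
#' profiles whose recorded configuration hash differs from the current one),
#' builds the reference profile for each condition (speed-interpolated EO
#' parameters where the reference file carries anchors, otherwise the HITL
#' mean parameters), and reports, per condition and controller: key points
#' (percent gait for walking, percent stance for running), membership of each
#' key point in the published HITL min--max range, cosine similarity and
#' discrete Frechet distance on the shared 101-point stance grid. Writes a
#' machine-readable `comparison_report.yaml` (full precision) and a rendered
#' `comparison_report.txt` with timings at one decimal place.
#'
#' @param config run configuration (path or list, see [loadRunConfig()]).
#' @param quiet suppress progress messages.
#' @return Invisibly, the report as a list.
#' @export
runCompare <- function(config, quiet = FALSE) {
  config <- loadRunConfig(config)
  hash <- attr(config, "hash")
  say <- function(...) if (!quiet) message(...)
  gait <- config$gait_type
  ref <- loadReferenceParams(if (!is.null(config$reference)) config$reference
                             else gait)
  useEo <- !is.null(ref$eoAnchors)
  report <- list(gait_type = gait, reference = ref$study,
                 config_hash = hash, conditions = list())
  for (cond in config$conditions) {
    speed <- as.numeric(cond$speed)
    stem <- file.path(config$output_dir, sprintf("%s_%s", gait,
                                                 .fmtSpeed(speed)))
    metaPath <- paste0(stem, "_meta.yaml")
    if (!file.exists(metaPath))
      stop("no generated profiles for ", speed, " m/s; run runGenerate() first")
    meta <- yaml::read_yaml(metaPath)
    if (!identical(meta$config_hash, hash))
      stop("refusing to compare: profiles at ", speed,
           " m/s were generated under a different configuration")
    refProf <- .referenceProfileAt(ref, speed, useEo)
    entry <- list(speed = speed)
    for (ctl in c("FS", "DB")) {
      curve <- readCurveTable(paste0(stem, "_", ctl, ".csv"),
                              valueColumn = "assistive_torque",
                              quantity = "assistive_torque",
                              phaseKind = "stance")
      prof <- TorqueProfile(resample(curve, 101L),
                            scaleFactor = meta$scale_factors[[ctl]],
                            controller = ctl)
      kpProf <- if (gait == "walk") stanceToGait(prof, ref$toeOffPercent)
                else prof
      kp <- keyPoints(kpProf, ref$onsetFraction)
      sim <- similarityReport(prof, refProf)
      entry[[ctl]] <- list(
        onset_percent = kp@onsetPercent, peak_percent = kp@peakPercent,
        offset_percent = kp@offsetPercent, peak_torque = kp@peakValue,
        in_hitl_range = list(
          onset = .inRange(kp@onsetPercent, ref$range$onset),
          peak = .inRange(kp@peakPercent, ref$range$peak),
          offset = .inRange(kp@offsetPercent, ref$range$offset)),
        cosine_similarity = sim@cosineSimilarity,
        frechet_distance = sim@frechetDistance)
      say(sprintf("[compare] %s %.1f m/s %s: onset %.1f peak %.1f offset %.1f, CS %.2f FD %.2f",
                  gait, speed, ctl, kp@onsetPercent, kp@peakPercent,
                  kp@offsetPercent, sim@cosineSimilarity, sim@frechetDistance))
    }
    report$conditions[[length(report$conditions) + 1L]] <- entry
  }
  writeLines(yaml::as.yaml(report),
             file.path(config$output_dir, "comparison_report.yaml"))
  writeLines(formatComparisonReport(report),
             file.path(config$output_dir, "comparison_report.txt"))
  invisible(report)
}

#' Render a comparison report as fixed-width text
#'
#' Timings are shown to one decimal place (full precision stays in the YAML
#' report).
#'
#' @param report the list returned by [runCompare()].
#' @return Character vector of lines.
#' @export
formatComparisonReport <- function(report) {
  axis <- if (report$gait_type == "walk") "percent gait" else "percent stance"
  lines <- c(sprintf("Comparison vs %s (%s, timings in %s)",
                     report$reference, report$gait_type, axis),
             sprintf("config hash: %s", report$config_hash),
             sprintf("%-6s %-4s %8s %8s %8s %10s %6s %6s",
                     "speed", "ctl", "onset", "peak", "offset",
                     "peak Nm/kg", "CS", "FD"))
  for (cn in report$conditions) {
    for (ctl in c("FS", "DB")) {
      e <- cn[[ctl]]
      mark <- function(v, ok) sprintf("%7.1f%s", v, if (ok) "*" else " ")
      lines <- c(lines, sprintf(
        "%-6.1f %-4s %s %s %s %10.3f %6.2f %6.2f",
        cn$speed, ctl,
        mark(e$onset_percent, e$in_hitl_range$onset),
        mark(e$peak_percent, e$in_hitl_range$peak),
        mark(e$offset_percent, e$in_hitl_range$offset),
        e$peak_torque, e$cosine_similarity, e$frechet_distance))
    }
  }
  c(lines, "(* = within the published HITL min-max range)")
}

#' Write synthetic condition sets in the ingestion dialect
#'
#' Generates synthetic dynamics for each speed, writes the three curve tables
#' per condition as csv, and writes a ready-to-run configuration YAML wired
#' to those files (anchor: 1.4 m/s for walking, 3.0 m/s for running, when
#' present, else the median speed).
#'
#' @param dir output directory (created if needed).
#' @param gaitType `"walk"` or `"run"`.
#' @param speeds condition speeds, m/s.
#' @param seed base RNG seed; condition i uses `seed + i - 1`.
#' @param noiseSd additive noise standard deviation for the generator.
#' @return Path to the written run-config YAML, invisibly.
#' @export
writeFixtures <- function(dir, gaitType = c("walk", "run"),
                          speeds = if (gaitType == "walk") c(0.7, 1.4, 2.0)
                          else c(2.0, 3.0, 4.0, 5.0),
                          seed = 1L, noiseSd = 0) {
  gaitType <- match.arg(gaitType)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  anchor <- if (gaitType == "walk" && 1.4 %in% speeds) 1.4
            else if (gaitType == "run" && 3.0 %in% speeds) 3.0
            else sort(speeds)[ceiling(length(speeds) / 2)]
  conditions <- list()
  for (i in seq_along(speeds)) {
    dyn <- synthDynamics(SynthConfig(gaitType, speeds[i], noiseSd = noiseSd,
                                     seed = as.integer(seed + i - 1L)))
    stem <- file.path(dir, sprintf("%s_%s", gaitType, .fmtSpeed(speeds[i])))
    files <- list()
    for (q in c("joint_torque", "fascicle_velocity", "tendon_velocity")) {
      p <- paste0(stem, "_", q, ".csv")
      writeCurveTable(slot(dyn, switch(q, joint_torque = "torque",
                                       fascicle_velocity = "fascicleVelocity",
                                       tendon_velocity = "tendonVelocity")), p)
      files[[q]] <- list(path = p, column = q)
    }
    conditions[[i]] <- list(speed = speeds[i], files = files,
                            phase_column = "phase")
  }
  cfg <- list(gait_type = gaitType,
              output_dir = file.path(dir, "profiles"),
              reference = gaitType,
              calibration = list(anchor_speed = anchor),
              conditions = conditions)
  if (gaitType == "walk") cfg$toe_off_percent <- 62.7
  cfgPath <- file.path(dir, sprintf("run_config_%s.yaml", gaitType))
  writeLines(yaml::as.yaml(cfg), cfgPath)
  invisible(cfgPath)
}
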