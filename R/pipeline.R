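#' @include phantom.R rwe_segment.R features.R concordance.R
NULL

#' Default pipeline configuration
#'
#' Nested list of every tunable of the end-to-end pipeline with its
#' default. Unknown keys in a user configuration are rejected by
#' [runAll()]; absent keys take these defaults.
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    cohort = list(
      n_patients = 20L,
      master_seed = 1L,
      grid = c(128L, 128L),
      n_slices = 5L,
      nodule_radius = 10,
      nodule_intensity = 20,
      lung_intensity = -800,
      wall_intensity = 40,
      vessel_intensity = 10,
      vessel_radius = 3,
      noise_sd = 20,
      lobulation = 3L,
      jitter = defaultJitter()
    ),
    window = list(p_low = 0, p_high = 100),
    rw = list(beta = 130, threshold = 0.5, tol = 1e-8, connectivity = 4L,
              max_passes = 5L, integrate = "or", dilation_radius = 5L,
              fg_method = "interior"),
    features = list(levels = 64L, dialect = "corrected", use_raw_hu = TRUE),
    hist = list(bins = 64L),
    select = list(gcm = 12L, grlm = 6L, hist = 6L),
    log_level = "info"
  )
}

# Merge a partial config into the defaults, rejecting unknown keys with
# dotted-path names (e.g. "rw.betta").
mergeConfig <- function(config, defaults = defaultRunConfig(), path = character(0L)) {
  if (is.null(config)) return(defaults)
  if (!is.list(config))
    stop("configuration must be a named list", call. = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste(paste(c(path, ""), collapse = "."), unknown,
               sep = "", collapse = ", "), call. = FALSE)
  out <- defaults
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && nm != "jitter") {
      out[[nm]] <- mergeConfig(config[[nm]], defaults[[nm]], c(path, nm))
    } else {
      out[[nm]] <- config[[nm]]
    }
  }
  out
}

cohortTemplate <- function(cc) {
  PhantomSpec(
    patientId = "template", noduleClass = "solid",
    grid = cc$grid, nSlices = cc$n_slices,
    noduleRadius = cc$nodule_radius, noduleIntensity = cc$nodule_intensity,
    lungIntensity = cc$lung_intensity, wallIntensity = cc$wall_intensity,
    vesselIntensity = cc$vessel_intensity, vesselRadius = cc$vessel_radius,
    noiseSd = cc$noise_sd, lobulation = cc$lobulation, rngSeed = 1L)
}

#' Run the full phantom-to-concordance pipeline
#'
#' Generates a phantom cohort, windows each stack, segments it with the
#' random-walker ensemble, extracts the 38 canonical features from both
#' the segmentation masks and the analytic ground-truth masks, and
#' computes the feature-wise Spearman concordance table with per-family
#' feature selection. All artifacts (manifest, feature tables,
#' concordance table, selected features, per-feature rank pairs,
#' per-patient masks, run metadata) are written under `outDir`.
#'
#' @param config partial configuration list (see [defaultRunConfig()]) or
#'   a path to a YAML file holding one; unknown keys are rejected.
#' @param outDir output directory (created if needed); NULL to skip all
#'   file output.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `cohort`, `segmentations`,
#'   `featuresRwe`, `featuresTruth`, `concordance`, `selected`, `config`.
#' @export
runAll <- function(config = list(), outDir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(config)
  cc <- cfg$cohort
  say <- function(...) if (!quiet) message(sprintf(...))

  say("generating %d-patient phantom cohort (master seed %d)",
      cc$n_patients, cc$master_seed)
  cohort <- generateCohort(cc$n_patients, cohortTemplate(cc),
                           jitter = cc$jitter, masterSeed = cc$master_seed)

  segs <- vector("list", length(cohort$cases))
  for (i in seq_along(cohort$cases)) {
    case <- cohort$cases[[i]]
    win <- autoWindow(case@stack, cfg$window$p_low, cfg$window$p_high)
    segs[[i]] <- segmentPatient(
      win, case@seeds, beta = cfg$rw$beta, threshold = cfg$rw$threshold,
      tol = cfg$rw$tol, maxPasses = cfg$rw$max_passes,
      integrate = cfg$rw$integrate, dilationRadius = cfg$rw$dilation_radius,
      fgMethod = cfg$rw$fg_method)
    say("segmented %s (%s): %d pass(es)",
        patientId(case@stack), case@spec@noduleClass, nPasses(segs[[i]]))
  }

  featArgs <- list(levels = cfg$features$levels, dialect = cfg$features$dialect,
                   histBins = cfg$hist$bins, useRawHu = cfg$features$use_raw_hu,
                   pLow = cfg$window$p_low, pHigh = cfg$window$p_high)
  stacks <- lapply(cohort$cases, function(cs) cs@stack)
  say("extracting features (levels=%d, dialect=%s)",
      cfg$features$levels, cfg$features$dialect)
  featRwe <- do.call(extractCohortFeatures,
    c(list(stacks, lapply(segs, perSliceMasks), provenance = "rwe"), featArgs))
  featTruth <- do.call(extractCohortFeatures,
    c(list(stacks, lapply(cohort$cases, function(cs) cs@truth),
           provenance = "ground_truth"), featArgs))

  conc <- concordanceTable(featRwe, featTruth)
  selected <- selectFeatures(conc, c(cfg$select$gcm, cfg$select$grlm,
                                     cfg$select$hist))

  if (!is.null(outDir)) {
    writePipelineArtifacts(outDir, cohort, segs, featRwe, featTruth,
                           conc, selected, cfg)
    say("artifacts written to %s", outDir)
  }
  invisible(list(cohort = cohort, segmentations = segs,
                 featuresRwe = featRwe, featuresTruth = featTruth,
                 concordance = conc, selected = selected, config = cfg))
}

writePipelineArtifacts <- function(outDir, cohort, segs, featRwe, featTruth,
                                   conc, selected, cfg) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  utils::write.csv(cohort$manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  writeFeatureTable(featRwe, file.path(outDir, "features_rwe.csv"))
  writeFeatureTable(featTruth, file.path(outDir, "features_gt.csv"))
  utils::write.csv(conc, file.path(outDir, "concordance.csv"), row.names = FALSE)
  writeLines(selected, file.path(outDir, "selected_features.txt"))

  scatterDir <- file.path(outDir, "scatter")
  dir.create(scatterDir, showWarnings = FALSE)
  rp <- attr(conc, "rankPairs")
  for (f in names(rp))
    utils::write.csv(data.frame(patient_id = rownames(featureValues(featTruth)),
                                rp[[f]], check.names = FALSE),
                     file.path(scatterDir, paste0(f, "_ranks.csv")),
                     row.names = FALSE)

  maskDir <- file.path(outDir, "masks")
  for (i in seq_along(segs)) {
    pid <- patientId(cohort$cases[[i]]@stack)
    writeMaskStack(perSliceMasks(segs[[i]]), file.path(maskDir, pid))
    png::writePNG(ensembleMask(segs[[i]]) + 0,
                  file.path(maskDir, pid, "ensemble.png"))
  }

  report <- list(
    package_version = as.character(utils::packageVersion("rwensemble")),
    r_version = R.version.string,
    config = cfg,
    passes = vapply(segs, nPasses, integer(1L)),
    dice_traces = lapply(segs, diceTrace))
  jsonlite::write_json(report, file.path(outDir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
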