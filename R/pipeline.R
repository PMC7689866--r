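#' @include AllClasses.R synth_cohort.R synth_traces.R synth_volume.R
#'   detect.R inputs.R seg3d.R stats_sfr.R io.R
NULL

#' Simulate a cohort and identify its inputs
#'
#' For every cell of a synthetic cohort, generates the stimulation protocol
#' and a spontaneous recording, runs EPSP detection and input identification,
#' and tabulates identified against true input strengths. All per-cell seeds
#' derive deterministically from `params@seed`.
#'
#' @param params a [CohortParams-class].
#' @param intensities stimulation ladder, mA.
#' @param sweepsPerLevel sweeps per intensity.
#' @param sweepMs sweep window, ms.
#' @param spontDuration spontaneous recording length, s.
#' @return list with `cells` (ground truth) and `results`: one row per cell
#'   with `age`, identified `strongest`/`second`/`n_inputs`/
#'   `competition_index` and the matching ground-truth columns.
#' @export
runCohortPhysiology <- function(params,
                                intensities = seq(0.05, 0.45, length.out = 8),
                                sweepsPerLevel = 30L, sweepMs = 15,
                                spontDuration = 6.5) {
  cells <- makeCohort(params)
  seeds <- withSeed(params@seed + 1L,
                    matrix(sample.int(.Machine$integer.max - 1L,
                                      2L * length(cells)), ncol = 2))
  rows <- lapply(seq_along(cells), function(i) {
    cell <- cells[[i]]
    stim <- synthStimExperiment(cell, intensities,
                                sweepsPerLevel = sweepsPerLevel,
                                sweepMs = sweepMs, seed = seeds[i, 1])
    spont <- synthSpontActivity(cell, duration = spontDuration,
                                seed = seeds[i, 2])
    res <- try(identifyInputs(stim, spont, age = cell@age), silent = TRUE)
    tr <- cell@inputs$true_ror
    if (inherits(res, "try-error"))
      return(data.frame(age = cell@age, strongest = NA_real_,
                        second = NA_real_, n_inputs = 0L,
                        competition_index = NA_real_,
                        prespike = FALSE, p_ap = NA_real_,
                        true_strongest = max(tr), true_second = sort(tr, TRUE)[2],
                        true_n = length(tr)))
    inp <- res@inputs
    data.frame(age = cell@age,
               strongest = inp$mean_ror[1],
               second = if (nrow(inp) >= 2) inp$mean_ror[2] else NA_real_,
               n_inputs = nrow(inp),
               competition_index = res@competitionIndex,
               prespike = isTRUE(inp$prespike[1]),
               p_ap = inp$p_ap[1],
               true_strongest = max(tr),
               true_second = sort(tr, TRUE)[2],
               true_n = length(tr))
  })
  list(cells = cells, results = do.call(rbind, rows))
}

#' Developmental summaries of an identified cohort
#'
#' Age regression of the strongest input's rate of rise (slope in V/s per
#' day), the mean second-strongest strength, and the competition-index slope.
#'
#' @param results the `results` table of [runCohortPhysiology()].
#' @return list with `strongestSlope`, `secondMean`, `ciSlope` and the
#'   underlying `"RegressionResult"` objects.
#' @export
developmentalFit <- function(results) {
  ok <- complete.cases(results[, c("age", "strongest")])
  fitS <- regressionF(results$age[ok], results$strongest[ok])
  ok2 <- complete.cases(results[, c("age", "competition_index")])
  fitC <- regressionF(results$age[ok2], results$competition_index[ok2])
  list(strongestSlope = fitS$coefficients["x", "estimate"],
       secondMean = mean(results$second, na.rm = TRUE),
       ciSlope = fitC$coefficients["x", "estimate"],
       strongestFit = fitS, ciFit = fitC)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages `simulate` (cohort ground truth), `identify`
#' (trace synthesis + detection + input identification), `segment` (volume
#' synthesis + 3D segmentation + contact quantification) and `correlate`
#' (structure-function power-law fit) in dependency order. The run is
#' deterministic for a fixed config; every output carries provenance (config,
#' derived seeds, package version). Results are returned and, when `outDir`
#' is set, written as JSON/TSV.
#'
#' @param config named list overriding the defaults: `nCells`, `seed`,
#'   `stages`, `outDir`, `voxelSize` (µm, ZYX), `somaScale` (scales soma radii
#'   for quicker volumes), `intensities`, `sweepsPerLevel`, `spontDuration`,
#'   `areaMethod`, `probeRadius`, `marginVoxels`, plus any
#'   [CohortParams-class] field under `cohort`.
#' @return list with `table` (one row per cell), `fit`
#'   (a [PowerLawFit-class] or NULL), `provenance`.
#' @export
runPipeline <- function(config = list()) {
  cfg <- list(nCells = 12L, seed = 1L,
              stages = c("simulate", "identify", "segment", "correlate"),
              outDir = NULL, voxelSize = c(0.33, 0.123, 0.123),
              somaScale = 0.6, intensities = seq(0.05, 0.45, by = 0.05),
              sweepsPerLevel = 30L, spontDuration = 8, areaMethod = "normal",
              probeRadius = 0.4, marginVoxels = 10L,
              cohort = list())
  bad <- setdiff(names(config), names(cfg))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(config)] <- config
  stopifnot1("simulate" %in% cfg$stages, "the simulate stage is required")

  params <- do.call(cohortParams,
                    c(list(nCells = cfg$nCells, seed = cfg$seed), cfg$cohort))
  phys <- NULL
  if ("identify" %in% cfg$stages) {
    phys <- runCohortPhysiology(params, intensities = cfg$intensities,
                                sweepsPerLevel = cfg$sweepsPerLevel,
                                spontDuration = cfg$spontDuration)
    cells <- phys$cells
    tab <- phys$results
  } else {
    cells <- makeCohort(params)
    tab <- data.frame(
      age = vapply(cells, function(c) c@age, numeric(1)),
      strongest = vapply(cells, function(c) max(c@inputs$true_ror), numeric(1)),
      second = vapply(cells, function(c) sort(c@inputs$true_ror, TRUE)[2], numeric(1)),
      n_inputs = vapply(cells, function(c) nrow(c@inputs), integer(1)))
    tab$competition_index <- tab$second / tab$strongest
    tab$true_strongest <- tab$strongest
    tab$true_second <- tab$second
    tab$true_n <- tab$n_inputs
  }

  if ("segment" %in% cfg$stages) {
    segSeeds <- withSeed(cfg$seed + 2L,
                         sample.int(.Machine$integer.max - 1L, length(cells)))
    seg <- lapply(seq_along(cells), function(i) {
      cell <- cells[[i]]
      cell@somaRadius <- cell@somaRadius * cfg$somaScale
      ## the PSF is a physical property of the imaging, not of the grid
      vp <- volumeParams(seed = segSeeds[i], voxelSize = cfg$voxelSize,
                         psfSigma = c(0.25, 0.10, 0.10),
                         marginVoxels = cfg$marginVoxels)
      vol <- NULL
      for (tryi in 0:4) {
        vp@seed <- segSeeds[i] + tryi
        vol <- try(synthVolume(cell, vp, minCapArea = 0.3), silent = TRUE)
        if (!inherits(vol, "try-error")) break
      }
      if (inherits(vol, "try-error")) return(rep(NA_real_, 4))
      sc <- try(segmentCell(vol$fill, vol$marker,
                            probeRadius = cfg$probeRadius,
                            step = cfg$voxelSize[3],
                            areaMethod = cfg$areaMethod), silent = TRUE)
      if (inherits(sc, "try-error")) return(rep(NA_real_, 4))
      c(sc$report@largestArea, sc$report@secondLargestArea,
        sc$report@contactRatio, sc$report@coverageFraction)
    })
    seg <- do.call(rbind, seg)
    tab$largest_area <- seg[, 1]
    tab$second_area <- seg[, 2]
    tab$contact_ratio <- seg[, 3]
    tab$coverage <- seg[, 4]
  }

  fit <- NULL
  if ("correlate" %in% cfg$stages && !is.null(tab$largest_area)) {
    ok <- complete.cases(tab[, c("largest_area", "strongest")]) &
      tab$largest_area > 0 & tab$strongest > 0
    if (sum(ok) >= 3) fit <- powerlawFit(tab$largest_area[ok], tab$strongest[ok])
  }

  prov <- list(config = cfg[setdiff(names(cfg), "outDir")],
               package_version = as.character(utils::packageVersion("calyxSFR")),
               timestamp = NA)
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
    write.table(tab, file.path(cfg$outDir, "cohort.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    out <- list(provenance = prov)
    if (!is.null(fit))
      out$powerlaw <- list(beta = fit@beta, alpha = fit@alpha,
                           se_beta = fit@seBeta, se_alpha = fit@seAlpha,
                           r_log = fit@rLog, F = fit@Fstat, p = fit@p, n = fit@n)
    jsonlite::write_json(out, file.path(cfg$outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(table = tab, fit = fit, provenance = prov)
}

## hand-built ground truth for one fixture cell
.fixtureCell <- function(age, rors, latencies, calyceal, prespikeAmp, soma,
                         beta = 6.8, alpha = 0.35) {
  n <- length(rors)
  inputs <- data.frame(
    true_ror = rors, dev_ror = rors,
    recruitment_threshold = seq(0.10, 0.38, length.out = n),
    activation_prob = rep(0.9, n),
    latency_mean = latencies,
    latency_cv = rep(0.023, n),
    is_calyceal = seq_len(n) == 1 & calyceal,
    prespike_amp = ifelse(seq_len(n) == 1 & calyceal, prespikeAmp, 0),
    ror_trial_cv = rep(0.15, n))
  new("CellGroundTruth", age = age, inputs = inputs,
      trueContactAreas = areaFromRoR(rors, beta, alpha), somaRadius = soma)
}

#' Write a small fixed fixture cohort
#'
#' Four cells spanning the developmental range: one calyceal P6-like cell
#' (large prespike-associated input with a >19 µm² terminal), one
#' intermediate P4-like cell, and two immature P2-like cells without a
#' calyceal input. Each cell directory holds a stimulation trace, a
#' spontaneous trace (CSV + JSON), a two-channel volume (TIFF + JSON) and the
#' ground truth JSON.
#'
#' @param outDir writable output directory.
#' @param seed integer seed.
#' @param voxelSize voxel size for the fixture volumes (coarse by default to
#'   keep them small).
#' @return invisibly, the list of cell directories.
#' @export
makeFixtures <- function(outDir, seed = 1L,
                         voxelSize = c(0.44, 0.164, 0.164)) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create ", outDir, call. = FALSE)
  cells <- list(
    p6_calyceal = .fixtureCell(6, c(25, 3.7, 1.5, 0.9), c(2.0, 4.5, 5.5, 6.5),
                               TRUE, 0.30, soma = 5),
    p4_intermediate = .fixtureCell(4, c(14, 3.5, 1.8, 1.2), c(2.2, 2.6, 5, 7),
                                   FALSE, 0, soma = 4.5),
    p2_immature_a = .fixtureCell(2, c(6.5, 3.9, 1.6), c(2.4, 4.8, 6.2),
                                 FALSE, 0, soma = 4),
    p2_immature_b = .fixtureCell(2, c(4.5, 3.2, 1.2, 0.8), c(2.5, 3.0, 5.2, 7.4),
                                 FALSE, 0, soma = 4))
  dirs <- character()
  for (i in seq_along(cells)) {
    nm <- names(cells)[i]
    cell <- cells[[i]]
    d <- file.path(outDir, nm)
    dir.create(d, showWarnings = FALSE)
    stim <- synthStimExperiment(cell, seq(0.08, 0.40, by = 0.08),
                                sweepsPerLevel = 12L, seed = seed + 10L * i)
    spont <- synthSpontActivity(cell, duration = 3, seed = seed + 10L * i + 1L)
    writeTrace(stim, file.path(d, "stim"))
    writeTrace(spont, file.path(d, "spont"))
    vol <- synthVolume(cell, volumeParams(seed = seed + 10L * i + 2L,
                                          voxelSize = voxelSize,
                                          psfSigma = c(0.25, 0.10, 0.10)),
                       minCapArea = 0.3)
    writeVolume(vol$fill, file.path(d, "fill"))
    writeVolume(vol$marker, file.path(d, "marker"))
    jsonlite::write_json(
      list(age = cell@age, soma_radius_um = cell@somaRadius,
           inputs = cell@inputs, true_contact_areas_um2 = cell@trueContactAreas,
           rendered_cap_areas_um2 = vol$capAreas, seed = seed),
      file.path(d, "truth.json"), auto_unbox = TRUE, digits = NA)
    dirs <- c(dirs, d)
  }
  invisible(dirs)
}
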