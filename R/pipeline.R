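# End-to-end orchestration: synthetic benchmark experiment, error suite,
# configuration and logging.

#' Build a run configuration
#'
#' Collects every setting of an end-to-end synthetic run. Defaults mirror
#' the experimental protocol: pressure pairs 5-10 and 5-45 mm Hg, 200 um
#' CRAV radius, degree-6 displacement smoothing, strain reported on a
#' 10 um (in-plane) by 6 um (axial) grid. The phantom grid size is the
#' package's desk-scale choice.
#'
#' @param nSpecimens number of synthetic specimens (default 6).
#' @param gridShape phantom voxel counts per specimen.
#' @param voxelSize micrometres per voxel of the specimen volumes. The
#'   default samples a 1.2 mm field of view at 5 um in-plane so that a
#'   realistically sized LC (about 1 mm across) surrounds the fixed 200 um
#'   CRAV disk at desk-scale voxel counts.
#' @param semiAxes nominal LC ellipse semi-axes (micrometres); each
#'   specimen jitters these slightly.
#' @param cravRadius CRAV exclusion radius (micrometres, default 200).
#' @param ppsRingWidth saturated scleral ring width (micrometres).
#' @param effect post-treatment deformation amplitude ratio (0.8 = a 20
#'   percent reduction after treatment; 1 = null experiment).
#' @param pressurePairs subset of c("5-10", "5-45").
#' @param dvc an \code{"lcDvcConfig"}.
#' @param degree polynomial degree for strain smoothing.
#' @param noiseSigma acquisition noise level (intensity units).
#' @param bandFraction band fraction for thickness mapping.
#' @param outputDir optional directory for persisted outputs.
#' @param seed global seed; every stochastic stage derives its seed from it.
#' @return list of class \code{"lcRunConfig"}.
#' @export
runConfig <- function(nSpecimens = 6, gridShape = c(240, 240, 48),
                      voxelSize = c(5, 5, 3),
                      semiAxes = c(500, 450), cravRadius = 200,
                      ppsRingWidth = 40,
                      effect = 0.8, pressurePairs = c("5-10", "5-45"),
                      dvc = dvcConfig(), degree = 6, noiseSigma = 0.02,
                      bandFraction = 0.1, outputDir = NULL, seed = 1L) {
  stopifnot(all(pressurePairs %in% c("5-10", "5-45")))
  structure(list(nSpecimens = as.integer(nSpecimens),
                 gridShape = as.integer(gridShape),
                 voxelSize = as.numeric(voxelSize),
                 semiAxes = as.numeric(semiAxes),
                 cravRadius = as.numeric(cravRadius),
                 ppsRingWidth = as.numeric(ppsRingWidth),
                 effect = effect,
                 pressurePairs = pressurePairs, dvc = dvc,
                 degree = as.integer(degree), noiseSigma = noiseSigma,
                 bandFraction = bandFraction, outputDir = outputDir,
                 seed = as.integer(seed)),
            class = "lcRunConfig")
}

#' Load a run configuration from YAML
#'
#' Top-level keys are \code{runConfig} arguments; an optional \code{dvc}
#' mapping holds \code{dvcConfig} arguments.
#'
#' @param path YAML file path.
#' @return list of class \code{"lcRunConfig"}.
#' @export
loadRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$dvc)) y$dvc <- do.call(dvcConfig, y$dvc)
  do.call(runConfig, y)
}

configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f)
  unname(tools::md5sum(f))
}

# Per-specimen synthetic setup: phantom spec (noise-free base; acquisition
# noise is added per imaging run) and ground-truth inflation deformations.
syntheticSpecimen <- function(s, cfg) {
  sd0 <- childSeed(cfg$seed, s)
  jitScale <- min(cfg$semiAxes) / 25
  jit <- withSeed(sd0, list(ab = runif(2, -jitScale, jitScale),
                            amp = runif(1, 0.9, 1.2),
                            aniso = runif(1, 0.75, 0.9)))
  spec <- phantomSpec(gridShape = cfg$gridShape, voxelSize = cfg$voxelSize,
                      semiAxes = cfg$semiAxes + jit$ab,
                      cravRadius = cfg$cravRadius,
                      ppsRingWidth = cfg$ppsRingWidth, darkPatchCount = 2,
                      darkPatchRadius = pmin(c(15, 40), 0.2 * min(cfg$semiAxes)),
                      noiseSigma = 0, seed = sd0)
  # inflation from 5 mm Hg: posterior bowing plus in-plane stretch; the
  # 5-10 mm Hg step is a scaled-down version of the 5-45 mm Hg response
  ampBase <- 0.047 * min(cfg$semiAxes)   # posterior bowing peak, um
  mkDef <- function(scale) {
    deformation("bowing",
                amplitude = ampBase * jit$amp * scale,
                width = 0.55 * spec$semiAxes[1],
                lambda = 1 + c(0.022, 0.022 * jit$aniso) * jit$amp * scale,
                center = c(spec$cravCenter, 0))
  }
  list(spec = spec, ageGroup = if (s <= 2) "middle" else "older",
       defFor = function(pair, effect) {
         mkDef((if (pair == "5-10") 0.3 else 1) * effect)
       })
}

#' Run the full synthetic inflation analysis
#'
#' For each synthetic specimen and treatment state (before / after, the
#' after state carrying the configured deformation-amplitude reduction):
#' image acquisition with fresh noise, DVC for each pressure pair, strain
#' fields, depth-averaged maps and regional average strain magnitudes.
#' Then: paired specimen-level Wilcoxon tests and the four regional GEE
#' models per strain measure and pressure pair.
#'
#' @param cfg an \code{"lcRunConfig"}.
#' @param verbose print per-stage progress.
#' @return list of class \code{"lcRunBundle"}: specimenSummary (data.frame
#'   of specimen-averaged strain magnitudes), regional (long regional
#'   table), pairedTable, wilcoxon (nested list by measure/pair), gee
#'   (nested list), geometries, log, configHash.
#' @export
runInflationAnalysis <- function(cfg = runConfig(), verbose = FALSE) {
  stopifnot(inherits(cfg, "lcRunConfig"))
  measures <- c("EXX", "EYY", "EMAX", "GMAX")
  states <- c("before", "after")
  regionalRows <- list(); summaryRows <- list(); logRows <- list()
  geoms <- list()
  meta <- data.frame(specimen = character(), ageGroup = character())

  for (s in seq_len(cfg$nSpecimens)) {
    sp <- syntheticSpecimen(s, cfg)
    sid <- sprintf("S%d", s)
    meta <- rbind(meta, data.frame(specimen = sid, ageGroup = sp$ageGroup))
    base <- generatePhantom(sp$spec)
    bpts <- phantomBoundaryPoints(sp$spec, seed = childSeed(cfg$seed, 100 + s))
    ell <- fitEllipse(bpts)
    geom <- NULL
    for (st in states) {
      eff <- if (st == "before") 1 else cfg$effect
      for (pair in cfg$pressurePairs) {
        t0 <- proc.time()[3]
        k <- s * 1000 + match(st, states) * 100 + match(pair, c("5-10", "5-45")) * 10
        ref <- addAcquisitionNoise(base, cfg$noiseSigma, childSeed(cfg$seed, k + 1))
        def <- addAcquisitionNoise(warpVolume(base, sp$defFor(pair, eff)),
                                   cfg$noiseSigma, childSeed(cfg$seed, k + 2))
        field <- runFidvc(ref, def, cfg$dvc)
        strain <- computeStrain(field, cfg$degree)
        maps <- averageThroughZ(strain)
        if (is.null(geom)) {
          geom <- segmentRegions(ell, sp$spec$cravCenter,
                                 cravRadius = sp$spec$cravRadius,
                                 x = maps$x, y = maps$y)
          geoms[[sid]] <- geom
        }
        for (ms in measures) {
          reg <- regionalAverageMagnitude(maps$maps[[ms]], geom, maps$valid)
          regionalRows[[length(regionalRows) + 1L]] <- data.frame(
            specimen = sid, state = st, pressurePair = pair, measure = ms,
            region = names(reg), value = unname(reg))
          summaryRows[[length(summaryRows) + 1L]] <- data.frame(
            specimen = sid, state = st, pressurePair = pair, measure = ms,
            value = lcAverageMagnitude(maps$maps[[ms]], geom, maps$valid))
        }
        logRows[[length(logRows) + 1L]] <- data.frame(
          specimen = sid, state = st, pressurePair = pair,
          seconds = round(proc.time()[3] - t0, 1),
          validFraction = mean(field@valid))
        if (verbose)
          message(sprintf("%s %s %s mm Hg: %.1fs, %.0f%% nodes valid",
                          sid, st, pair, proc.time()[3] - t0,
                          100 * mean(field@valid)))
      }
    }
  }

  regional <- do.call(rbind, regionalRows)
  summary <- do.call(rbind, summaryRows)
  keep <- setdiff(names(regional), "state")
  pairedTable <- buildPairedTable(regional[regional$state == "before", keep],
                                  regional[regional$state == "after", keep],
                                  meta)
  wil <- list(); gee <- list()
  for (pair in cfg$pressurePairs) {
    for (ms in measures) {
      b <- summary[summary$state == "before" & summary$pressurePair == pair &
                   summary$measure == ms, ]
      a <- summary[summary$state == "after" & summary$pressurePair == pair &
                   summary$measure == ms, ]
      b <- b[order(b$specimen), ]; a <- a[order(a$specimen), ]
      wil[[pair]][[ms]] <- wilcoxonSignedRankExact(a$value, b$value)
      gee[[pair]][[ms]] <- if (cfg$nSpecimens >= 2)
        geeStrainModels(pairedTable, ms, pair) else NULL
    }
  }
  bundle <- structure(list(specimenSummary = summary, regional = regional,
                           pairedTable = pairedTable, wilcoxon = wil,
                           gee = gee, geometries = geoms,
                           log = do.call(rbind, logRows),
                           configHash = configHash(cfg), config = cfg),
                      class = "lcRunBundle")
  if (!is.null(cfg$outputDir)) persistBundle(bundle, cfg$outputDir)
  bundle
}

persistBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$specimenSummary, file.path(dir, "specimen_summary.csv"),
            row.names = FALSE)
  write.csv(bundle$regional, file.path(dir, "regional_magnitudes.csv"),
            row.names = FALSE)
  write.csv(bundle$pairedTable, file.path(dir, "paired_table.csv"),
            row.names = FALSE)
  write.csv(bundle$log, file.path(dir, "run_log.csv"), row.names = FALSE)
  res <- list(configHash = bundle$configHash,
              wilcoxon = lapply(bundle$wilcoxon, function(byPair)
                lapply(byPair, function(w)
                  list(V = w$statistic, p = w$p.value, n = w$n))),
              gee = lapply(bundle$gee, function(byPair)
                lapply(byPair, function(models)
                  lapply(models, function(m)
                    if (is.null(m)) NULL else
                    list(coef = as.list(m$coefficients),
                         robustSe = as.list(m$robust.se),
                         p = as.list(m$p.value), rho = m$rho)))))
  jsonlite::write_json(res, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.lcRunBundle <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic inflation analysis: %d specimens, pairs %s, effect %.2f\n",
              cfg$nSpecimens, paste(cfg$pressurePairs, collapse = ", "),
              cfg$effect))
  for (pair in names(x$wilcoxon)) {
    cat(sprintf("  %s mm Hg specimen-level Wilcoxon:\n", pair))
    for (ms in names(x$wilcoxon[[pair]])) {
      w <- x$wilcoxon[[pair]][[ms]]
      cat(sprintf("    %-4s P = %.4g (n = %d)\n", ms, w$p.value, w$n))
    }
  }
  invisible(x)
}

#' Run the DVC error suite
#'
#' Executes the two error analyses on a seeded phantom: the baseline error
#' (correlating two noisy acquisitions of the same state) and the
#' applied-deformation recovery error for the four canonical cases.
#'
#' @param cfg an \code{"lcRunConfig"}; \code{cfg$errorGridShape} (default
#'   c(256, 256, 64)) sizes the error phantom.
#' @param verbose print progress.
#' @return list of class \code{"lcErrorReport"}: baseline and applied
#'   data.frames.
#' @export
runErrorSuite <- function(cfg = runConfig(), verbose = FALSE) {
  gs <- if (!is.null(cfg$errorGridShape)) cfg$errorGridShape else c(256, 256, 64)
  spec <- phantomSpec(gridShape = gs, noiseSigma = 0,
                      seed = childSeed(cfg$seed, 999))
  base <- generatePhantom(spec)
  a <- addAcquisitionNoise(base, cfg$noiseSigma, childSeed(cfg$seed, 51))
  b <- addAcquisitionNoise(base, cfg$noiseSigma, childSeed(cfg$seed, 52))
  if (verbose) message("baseline duplicate correlation")
  bl <- baselineError(a, b, cfg$dvc, cfg$degree)
  ap <- appliedDeformationError(a, cfg$dvc, degree = cfg$degree,
                                verbose = verbose)
  report <- structure(list(baseline = bl, applied = ap,
                           configHash = configHash(cfg)),
                      class = "lcErrorReport")
  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(bl, file.path(cfg$outputDir, "baseline_error.csv"),
              row.names = FALSE)
    write.csv(ap, file.path(cfg$outputDir, "applied_deformation_error.csv"),
              row.names = FALSE)
    jsonlite::write_json(list(baseline = bl, applied = ap,
                              configHash = report$configHash),
                         file.path(cfg$outputDir, "error_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.lcErrorReport <- function(x, ...) {
  cat("Baseline DVC error (duplicate correlation):\n")
  print(x$baseline, row.names = FALSE)
  cat("Applied-deformation recovery:\n")
  print(x$applied, row.names = FALSE)
  invisible(x)
}
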