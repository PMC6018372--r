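# Thickness-change mapping between treatment states and the two DVC error
# analyses (baseline duplicate correlation and applied numerical
# deformations).

#' Map LC thickness change between treatment states
#'
#' Correlates the buffer-treated volume (reference) against the
#' enzyme-treated volume (deformed) at the same pressure and, per (X, Y)
#' column, subtracts the average anterior-posterior displacement of the
#' anterior-most band from that of the posterior-most band of the imaged
#' depth. Positive values mean thickening.
#'
#' @param refVol,defVol \linkS4class{ImageVolume}s at the same pressure.
#' @param geom optional \linkS4class{LcGeometry} on the displacement node
#'   grid; when supplied, the scalar summary averages over LC analysis
#'   nodes only.
#' @param bandFraction fraction of the imaged depth forming each band
#'   (default 0.1).
#' @param cfg DVC configuration.
#' @param field optional precomputed \linkS4class{DisplacementField}
#'   (skips the DVC run).
#' @return list of class \code{"lcThicknessMap"}: x, y, dt (2D matrix,
#'   micrometres), valid, meanDt.
#' @export
thicknessChange <- function(refVol, defVol, geom = NULL, bandFraction = 0.1,
                            cfg = dvcConfig(), field = NULL) {
  if (is.null(field)) {
    if (!isTRUE(all.equal(refVol@pressure, defVol@pressure)))
      stopMsg("thickness mapping requires both volumes at the same pressure")
    field <- runFidvc(refVol, defVol, cfg)
  }
  stopifnot(is(field, "DisplacementField"))
  z <- field@z
  # imaged depth: axial span of planes that actually correlated
  zv <- z[apply(field@valid, 3, any)]
  if (length(zv) < 2) stopMsg("fewer than two correlated axial planes")
  D <- diff(range(zv))
  antMask <- z <= min(zv) + bandFraction * D
  postMask <- z >= max(zv) - bandFraction * D
  nx <- length(field@x); ny <- length(field@y)
  dt <- matrix(NA_real_, nx, ny)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    uz <- field@UZ[i, j, ]
    va <- field@valid[i, j, ] & antMask & !is.na(uz)
    vp <- field@valid[i, j, ] & postMask & !is.na(uz)
    if (any(va) && any(vp))
      dt[i, j] <- mean(uz[vp]) - mean(uz[va])
  }
  valid <- !is.na(dt)
  if (!is.null(geom)) {
    stopifnot(is(geom, "LcGeometry"))
    if (!identical(dim(dt), dim(geom@labels)))
      stopMsg("geometry grid does not match the displacement node grid")
    lcSel <- geom@labels > 2L
    meanDt <- mean(dt[valid & lcSel])
  } else {
    meanDt <- mean(dt[valid])
  }
  structure(list(x = field@x, y = field@y, dt = dt, valid = valid,
                 meanDt = meanDt, bandFraction = bandFraction),
            class = "lcThicknessMap")
}

#' Baseline DVC error from nominally identical acquisitions
#'
#' Runs the full DVC + strain pipeline on two acquisitions of the same
#' state (duplicate z-stacks) and reports the mean absolute displacement
#' per axis and mean absolute in-plane strain per component -- the
#' intrinsic error floor of the method.
#'
#' @param stackA,stackB \linkS4class{ImageVolume}s (nominal duplicates).
#' @param cfg DVC configuration.
#' @param degree polynomial degree for the strain stage.
#' @return data.frame with columns quantity, value, units.
#' @export
baselineError <- function(stackA, stackB, cfg = dvcConfig(), degree = 6) {
  field <- runFidvc(stackA, stackB, cfg)
  ok <- field@valid
  strain <- computeStrain(field, degree)
  sok <- strain@valid
  data.frame(
    quantity = c("U_X", "U_Y", "U_Z", "E_XX", "E_YY", "E_XY"),
    value = c(mean(abs(field@UX[ok])), mean(abs(field@UY[ok])),
              mean(abs(field@UZ[ok])),
              mean(abs(strain@components$EXX[sok])),
              mean(abs(strain@components$EYY[sok])),
              mean(abs(strain@components$EXY[sok]))),
    units = c(rep("um", 3), rep("strain", 3)))
}

# The four canonical applied-deformation error cases for a given volume.
canonicalErrorCases <- function(vol) {
  vx <- vol@voxelSize
  dm <- dim(vol@data)
  ctr <- (dm - 1) * vx / 2
  list(
    inplane_translation = list(
      d = deformation("translation", t = c(10, 10, 0), units = "voxel",
                      voxelSize = vx),
      type = "translation", applied = c(X = 10, Y = 10), units = "pixels"),
    z_translation = list(
      d = deformation("translation", t = c(0, 0, 3), units = "voxel",
                      voxelSize = vx),
      type = "translation", applied = c(Z = 3), units = "slices"),
    inplane_stretch = list(
      d = deformation("uniformStrain", lambda = c(1.02, 1.02, 1),
                      center = ctr),
      type = "stretch", applied = c(X = 2, Y = 2), units = "percent"),
    z_compression = list(
      d = deformation("uniformStrain", lambda = c(1, 1, 0.95), center = ctr),
      type = "stretch", applied = c(Z = -5), units = "percent"))
}

#' Applied-deformation recovery error
#'
#' Numerically applies canonical deformations to a reference volume (by
#' default the four protocol cases: a 10-pixel X and Y translation, a
#' 3-slice Z translation, a 2 percent uniform in-plane stretch, and a
#' 5 percent uniform Z compression), runs the DVC (+ polynomial gradient)
#' pipeline, and tabulates recovered versus applied values. Translations
#' are recovered as the mean valid displacement (pixels/slices); stretches
#' as 100 x the mean fitted displacement gradient (percent).
#'
#' @param ref an \linkS4class{ImageVolume}.
#' @param cfg DVC configuration.
#' @param cases optional case list (see \code{canonicalErrorCases} source
#'   for the structure); defaults to the four protocol cases.
#' @param degree polynomial degree for gradient estimation.
#' @param verbose print per-case progress.
#' @return data.frame with columns case, component, applied, recovered,
#'   error, units.
#' @export
appliedDeformationError <- function(ref, cfg = dvcConfig(), cases = NULL,
                                    degree = 6, verbose = FALSE) {
  stopifnot(is(ref, "ImageVolume"))
  if (is.null(cases)) cases <- canonicalErrorCases(ref)
  vx <- ref@voxelSize
  rows <- list()
  for (nm in names(cases)) {
    cs <- cases[[nm]]
    if (verbose) message("applied-deformation case: ", nm)
    def <- warpVolume(ref, cs$d)
    field <- runFidvc(ref, def, cfg)
    ok <- field@valid
    if (cs$type == "translation") {
      rec <- c(X = mean(field@UX[ok]) / vx[1],
               Y = mean(field@UY[ok]) / vx[2],
               Z = mean(field@UZ[ok]) / vx[3])
    } else {
      fit <- fitPolynomialField(field, degree)
      strain <- strainFieldFromFit(fit, field)
      g <- as.matrix(expand.grid(strain@x, strain@y, strain@z))
      G <- displacementGradient(fit, g)
      sok <- as.vector(strain@valid)
      rec <- 100 * c(X = mean(G[sok, 1, 1]), Y = mean(G[sok, 2, 2]),
                     Z = mean(G[sok, 3, 3]))
    }
    for (comp in names(cs$applied)) {
      rows[[length(rows) + 1L]] <- data.frame(
        case = nm, component = comp, applied = unname(cs$applied[comp]),
        recovered = unname(rec[comp]),
        error = abs(unname(rec[comp]) - unname(cs$applied[comp])),
        units = cs$units)
    }
  }
  do.call(rbind, rows)
}
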