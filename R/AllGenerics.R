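#' @name lcstrain-accessors
#' @title Accessors for lcstrain data classes
#' @param object an lcstrain S4 object.
#' @description Slot accessors for \linkS4class{ImageVolume},
#'   \linkS4class{DisplacementField}, \linkS4class{StrainField} and
#'   \linkS4class{LcGeometry}.
NULL

#' @rdname lcstrain-accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("pressure", function(object) standardGeneric("pressure"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("treatment", function(object) standardGeneric("treatment"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("focalOffset", function(object) standardGeneric("focalOffset"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("nodeCoords", function(object) standardGeneric("nodeCoords"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("displacements", function(object) standardGeneric("displacements"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("quality", function(object) standardGeneric("quality"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("strainComponents", function(object) standardGeneric("strainComponents"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("maxPrincipal", function(object) standardGeneric("maxPrincipal"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("maxShear", function(object) standardGeneric("maxShear"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname lcstrain-accessors
#' @export
setGeneric("ellipseParams", function(object) standardGeneric("ellipseParams"))

#' @rdname lcstrain-accessors
#' @export
setMethod("intensities", "ImageVolume", function(object) object@data)
#' @rdname lcstrain-accessors
#' @export
setMethod("voxelSize", "ImageVolume", function(object) object@voxelSize)
#' @rdname lcstrain-accessors
#' @export
setMethod("voxelSize", "DisplacementField", function(object) object@voxelSize)
#' @rdname lcstrain-accessors
#' @export
setMethod("pressure", "ImageVolume", function(object) object@pressure)
#' @rdname lcstrain-accessors
#' @export
setMethod("treatment", "ImageVolume", function(object) object@treatment)
#' @rdname lcstrain-accessors
#' @export
setMethod("focalOffset", "ImageVolume", function(object) object@focalOffset)
#' @rdname lcstrain-accessors
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))

#' @rdname lcstrain-accessors
#' @export
setMethod("nodeCoords", "DisplacementField",
          function(object) list(x = object@x, y = object@y, z = object@z))
#' @rdname lcstrain-accessors
#' @export
setMethod("nodeCoords", "StrainField",
          function(object) list(x = object@x, y = object@y, z = object@z))
#' @rdname lcstrain-accessors
#' @export
setMethod("displacements", "DisplacementField",
          function(object) list(UX = object@UX, UY = object@UY, UZ = object@UZ))
#' @rdname lcstrain-accessors
#' @export
setMethod("quality", "DisplacementField", function(object) object@quality)
#' @rdname lcstrain-accessors
#' @export
setMethod("validMask", "DisplacementField", function(object) object@valid)
#' @rdname lcstrain-accessors
#' @export
setMethod("validMask", "StrainField", function(object) object@valid)
#' @rdname lcstrain-accessors
#' @export
setMethod("strainComponents", "StrainField", function(object) object@components)
#' @rdname lcstrain-accessors
#' @export
setMethod("maxPrincipal", "StrainField", function(object) object@EMAX)
#' @rdname lcstrain-accessors
#' @export
setMethod("maxShear", "StrainField", function(object) object@GMAX)
#' @rdname lcstrain-accessors
#' @export
setMethod("regionLabels", "LcGeometry", function(object) {
  structure(object@labels, levels = object@labelLevels)
})
#' @rdname lcstrain-accessors
#' @export
setMethod("ellipseParams", "LcGeometry", function(object) object@ellipse)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %d x %d x %d voxels (%.1f x %.1f x %.1f um)\n",
              d[1], d[2], d[3], d[1] * object@voxelSize[1],
              d[2] * object@voxelSize[2], d[3] * object@voxelSize[3]))
  cat(sprintf("  specimen %s (%s), pressure %s mm Hg, treatment %s, focal offset %.1f um\n",
              object@specimen, object@eye,
              ifelse(is.na(object@pressure), "?", format(object@pressure)),
              ifelse(is.na(object@treatment), "?", object@treatment),
              object@focalOffset))
})

setMethod("show", "DisplacementField", function(object) {
  d <- dim(object@valid)
  cat(sprintf("DisplacementField on %d x %d x %d nodes, %.1f%% valid\n",
              d[1], d[2], d[3], 100 * mean(object@valid)))
  if (any(object@valid))
    cat(sprintf("  mean |U| (um): X %.3f, Y %.3f, Z %.3f\n",
                mean(abs(object@UX[object@valid])),
                mean(abs(object@UY[object@valid])),
                mean(abs(object@UZ[object@valid]))))
})

setMethod("show", "StrainField", function(object) {
  d <- dim(object@valid)
  cat(sprintf("StrainField on %d x %d x %d nodes, %.1f%% valid\n",
              d[1], d[2], d[3], 100 * mean(object@valid)))
  if (any(object@valid))
    cat(sprintf("  mean |EXX| %.4f, |EYY| %.4f, |EXY| %.4f, Emax %.4f, Gmax %.4f\n",
                mean(abs(object@components$EXX[object@valid])),
                mean(abs(object@components$EYY[object@valid])),
                mean(abs(object@components$EXY[object@valid])),
                mean(object@EMAX[object@valid]),
                mean(object@GMAX[object@valid])))
})

setMethod("show", "LcGeometry", function(object) {
  e <- object@ellipse
  cat(sprintf("LcGeometry: ellipse a=%.0f b=%.0f um at (%.0f, %.0f), CRAV r=%.0f um\n",
              e$a, e$b, e$center[1], e$center[2], object@cravRadius))
  tab <- table(factor(object@labelLevels[object@labels],
                      levels = object@labelLevels))
  cat("  region node counts:\n")
  print(tab)
})

setMethod("show", "PolynomialFit", function(object) {
  cat(sprintf("PolynomialFit degree %d (%d terms/component); residual RMS (um): %s\n",
              object@degree, nrow(object@coef),
              paste(sprintf("%.2e", object@rms), collapse = ", ")))
})
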