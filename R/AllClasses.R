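#' ImageVolume: a 3D intensity volume with acquisition metadata
#'
#' Container for one volumetric acquisition (a z-stack). The X axis is the
#' nasal-temporal direction, Y the inferior-superior direction, and Z the
#' anterior-posterior (out-of-plane) direction. Intensities are stored as a
#' numeric array scaled to [0, 1].
#'
#' @slot data numeric 3D array of intensities (X, Y, Z order).
#' @slot voxelSize numeric(3), micrometres per voxel along X, Y, Z.
#' @slot pressure numeric(1), chamber pressure in mm Hg (NA if unknown).
#' @slot treatment character(1), "buffer", "enzyme" or NA.
#' @slot focalOffset numeric(1), recorded focal-depth adjustment in
#'   micrometres, added back to anterior-posterior displacements.
#' @slot specimen character(1) specimen identifier.
#' @slot eye character(1) laterality, "OD" (right) or "OS" (left).
#' @slot meta list of additional metadata (phantom specs, boundary points,
#'   ground-truth deformations, ...).
#' @export
setClass("ImageVolume",
  representation(data = "array", voxelSize = "numeric", pressure = "numeric",
                 treatment = "character", focalOffset = "numeric",
                 specimen = "character", eye = "character", meta = "list"))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive values (micrometres)")
  if (length(object@pressure) != 1L)
    msg <- c(msg, "pressure must be a single value")
  if (!is.na(object@treatment) && !object@treatment %in% c("buffer", "enzyme"))
    msg <- c(msg, "treatment must be 'buffer', 'enzyme' or NA")
  if (!object@eye %in% c("OD", "OS"))
    msg <- c(msg, "eye must be 'OD' or 'OS'")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageVolume
#'
#' @param data numeric 3D array (X, Y, Z).
#' @param voxelSize micrometres per voxel along X, Y, Z.
#' @param pressure pressure in mm Hg.
#' @param treatment "buffer" or "enzyme".
#' @param focalOffset focal adjustment in micrometres.
#' @param specimen specimen identifier.
#' @param eye "OD" or "OS".
#' @param meta list of extra metadata.
#' @return An \linkS4class{ImageVolume}.
#' @export
imageVolume <- function(data, voxelSize = c(2.5, 2.5, 3), pressure = NA_real_,
                        treatment = NA_character_, focalOffset = 0,
                        specimen = "specimen", eye = "OD", meta = list()) {
  new("ImageVolume", data = data, voxelSize = as.numeric(voxelSize),
      pressure = as.numeric(pressure), treatment = as.character(treatment),
      focalOffset = as.numeric(focalOffset), specimen = specimen, eye = eye,
      meta = meta)
}

#' DisplacementField: gridded 3D displacements in the reference frame
#'
#' Displacements recovered by digital volume correlation on a regular node
#' grid. Node coordinates and displacements are in micrometres; invalid nodes
#' (low correlation quality or zero-variance subsets) carry NA displacements.
#'
#' @slot x,y,z numeric node coordinates (micrometres) along each axis.
#' @slot UX,UY,UZ numeric 3D arrays of displacement components (micrometres).
#' @slot quality numeric 3D array of peak normalized correlation coefficients.
#' @slot valid logical 3D array marking usable nodes.
#' @slot voxelSize numeric(3) micrometres per voxel of the source volumes.
#' @export
setClass("DisplacementField",
  representation(x = "numeric", y = "numeric", z = "numeric",
                 UX = "array", UY = "array", UZ = "array",
                 quality = "array", valid = "array", voxelSize = "numeric"))

setValidity("DisplacementField", function(object) {
  d <- c(length(object@x), length(object@y), length(object@z))
  msg <- character()
  for (nm in c("UX", "UY", "UZ", "quality", "valid"))
    if (!identical(dim(slot(object, nm)), as.integer(d)))
      msg <- c(msg, sprintf("%s dimensions must match node grid", nm))
  if (!is.logical(object@valid)) msg <- c(msg, "valid must be logical")
  if (any(!is.na(object@UX[!object@valid])))
    msg <- c(msg, "invalid nodes must carry NA displacements")
  if (length(msg)) msg else TRUE
})

#' StrainField: Green-Lagrange strain components on a regular grid
#'
#' In-plane components EXX (normal strain along nasal-temporal X), EYY
#' (inferior-superior Y) and EXY (in-plane shear) are always present; the
#' out-of-plane components EZZ, EXZ, EYZ are retained as well. EMAX is the
#' maximum in-plane principal strain and GMAX the maximum in-plane
#' (tensorial) shear strain, both derived from the in-plane components.
#'
#' @slot x,y,z numeric grid coordinates (micrometres).
#' @slot components named list of 3D strain component arrays.
#' @slot EMAX,GMAX numeric 3D arrays of derived strain measures.
#' @slot valid logical 3D array.
#' @export
setClass("StrainField",
  representation(x = "numeric", y = "numeric", z = "numeric",
                 components = "list", EMAX = "array", GMAX = "array",
                 valid = "array"))

setValidity("StrainField", function(object) {
  need <- c("EXX", "EYY", "EXY", "EZZ", "EXZ", "EYZ")
  msg <- character()
  if (!all(need %in% names(object@components)))
    msg <- c(msg, "components must contain EXX, EYY, EXY, EZZ, EXZ, EYZ")
  d <- c(length(object@x), length(object@y), length(object@z))
  if (!identical(dim(object@EMAX), as.integer(d)))
    msg <- c(msg, "EMAX dimensions must match grid")
  ok <- object@valid & is.finite(object@EMAX)
  if (any(ok)) {
    exx <- object@components$EXX[ok]; eyy <- object@components$EYY[ok]
    if (any(object@EMAX[ok] < pmax(exx, eyy) - 1e-10))
      msg <- c(msg, "EMAX must dominate EXX and EYY")
    if (any(object@GMAX[ok] < abs(object@components$EXY[ok]) - 1e-10))
      msg <- c(msg, "GMAX must dominate |EXY|")
  }
  if (length(msg)) msg else TRUE
})

#' LcGeometry: elliptical segmentation of the lamina cribrosa
#'
#' Holds the fitted boundary ellipse, the central retinal artery/vein (CRAV)
#' exclusion disk, and the per-node region labels over a 2D analysis grid:
#' background, CRAV, and the eight analysis regions (central/peripheral x
#' superior/inferior/temporal/nasal quadrants).
#'
#' @slot ellipse list with center (micrometres), semi-axes a >= b
#'   (micrometres) and orientation angle (radians).
#' @slot cravCenter numeric(2) CRAV center (micrometres).
#' @slot cravRadius numeric(1) CRAV disk radius (micrometres, default 200).
#' @slot x,y numeric grid coordinates (micrometres).
#' @slot labels integer matrix of region codes over the grid.
#' @slot labelLevels character vector mapping codes to region names.
#' @export
setClass("LcGeometry",
  representation(ellipse = "list", cravCenter = "numeric",
                 cravRadius = "numeric", x = "numeric", y = "numeric",
                 labels = "matrix", labelLevels = "character"))

setValidity("LcGeometry", function(object) {
  msg <- character()
  if (!all(c("center", "a", "b", "angle") %in% names(object@ellipse)))
    msg <- c(msg, "ellipse must have center, a, b, angle")
  else if (object@ellipse$a < object@ellipse$b || object@ellipse$b <= 0)
    msg <- c(msg, "ellipse semi-axes must satisfy a >= b > 0")
  if (object@cravRadius <= 0) msg <- c(msg, "cravRadius must be positive")
  if (!identical(dim(object@labels),
                 c(length(object@x), length(object@y))))
    msg <- c(msg, "labels must be an x-by-y matrix")
  if (any(!object@labels %in% seq_along(object@labelLevels)))
    msg <- c(msg, "labels must index labelLevels")
  if (length(msg)) msg else TRUE
})

#' PolynomialFit: trivariate polynomial smoothing of a displacement field
#'
#' One least-squares trivariate polynomial (total degree \code{degree},
#' default 6) per displacement component, fitted on the normalized domain
#' [-1,1]^3 defined by an affine map of the node coordinates.
#'
#' @slot degree integer total degree.
#' @slot powers integer matrix (terms x 3) of monomial exponents.
#' @slot coef numeric matrix (terms x 3), one column per component UX, UY, UZ.
#' @slot center,halfwidth numeric(3) of the domain normalization
#'   (micrometres): normalized coordinate = (x - center) / halfwidth.
#' @slot rms numeric(3) residual root-mean-square per component (micrometres).
#' @export
setClass("PolynomialFit",
  representation(degree = "integer", powers = "matrix", coef = "matrix",
                 center = "numeric", halfwidth = "numeric", rms = "numeric"))

setValidity("PolynomialFit", function(object) {
  msg <- character()
  if (nrow(object@powers) != nrow(object@coef))
    msg <- c(msg, "powers and coef must have matching rows")
  if (ncol(object@coef) != 3L) msg <- c(msg, "coef must have 3 columns")
  if (any(object@halfwidth <= 0)) msg <- c(msg, "halfwidth must be positive")
  if (length(msg)) msg else TRUE
})
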