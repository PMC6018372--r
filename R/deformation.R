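#' Analytic ground-truth deformations
#'
#' Constructs an analytic deformation whose displacement field can be
#' evaluated exactly at any reference coordinate, for warping phantom
#' volumes and benchmarking the DVC pipeline against known ground truth.
#'
#' Supported kinds:
#' \describe{
#'   \item{translation}{rigid translation; \code{t} is the 3-vector, in
#'     micrometres (\code{units = "um"}) or voxels (\code{units = "voxel"},
#'     converted with \code{voxelSize}).}
#'   \item{uniformStrain}{homogeneous stretch about \code{center}:
#'     U = (lambda - 1) * (X - center) per axis.}
#'   \item{polynomial}{displacement components given by trivariate
#'     polynomials: \code{coef} is a list with elements UX, UY, UZ, each a
#'     list(powers = terms x 3 exponent matrix, coef = numeric) evaluated on
#'     coordinates in micrometres.}
#'   \item{bowing}{posterior bowing with optional in-plane stretch:
#'     UZ = amplitude * exp(-r^2 / (2 width^2)) about \code{center[1:2]},
#'     UX/UY = (lambda - 1) * (X - center) for the in-plane axes.}
#'   \item{composite}{sequential application of two deformations (see
#'     \code{\link{composeDeformations}}).}
#' }
#'
#' @param kind one of "translation", "uniformStrain", "polynomial", "bowing".
#' @param t translation 3-vector (for kind "translation").
#' @param units "um" or "voxel" for translation components.
#' @param voxelSize micrometres per voxel, required when \code{units="voxel"}.
#' @param lambda stretch ratios (length 3) for "uniformStrain"; for "bowing"
#'   the in-plane ratios (length 2).
#' @param center reference point in micrometres (length 3; default origin).
#' @param coef polynomial coefficient specification (see above).
#' @param amplitude bowing peak displacement (micrometres).
#' @param width bowing Gaussian radial width (micrometres).
#' @return An object of class \code{"lcDeformation"}.
#' @export
deformation <- function(kind, t = NULL, units = "um", voxelSize = NULL,
                        lambda = NULL, center = c(0, 0, 0), coef = NULL,
                        amplitude = NULL, width = NULL) {
  kinds <- c("translation", "uniformStrain", "polynomial", "bowing")
  if (!kind %in% kinds)
    stopMsg("unknown deformation kind '%s' (expected one of %s)",
            kind, paste(kinds, collapse = ", "))
  d <- list(kind = kind, center = as.numeric(center))
  if (kind == "translation") {
    if (length(t) != 3L) stopMsg("translation requires a length-3 vector t")
    if (units == "voxel") {
      if (is.null(voxelSize)) stopMsg("units='voxel' requires voxelSize")
      t <- as.numeric(t) * as.numeric(voxelSize)
    } else if (units != "um") stopMsg("units must be 'um' or 'voxel'")
    d$t <- as.numeric(t)
  } else if (kind == "uniformStrain") {
    if (length(lambda) != 3L || any(lambda <= 0))
      stopMsg("uniformStrain requires 3 positive stretch ratios")
    d$lambda <- as.numeric(lambda)
  } else if (kind == "polynomial") {
    if (!all(c("UX", "UY", "UZ") %in% names(coef)))
      stopMsg("polynomial coef must name UX, UY, UZ")
    d$coef <- coef
  } else if (kind == "bowing") {
    if (is.null(amplitude) || is.null(width) || width <= 0)
      stopMsg("bowing requires amplitude and positive width")
    d$amplitude <- as.numeric(amplitude)
    d$width <- as.numeric(width)
    d$lambda <- if (is.null(lambda)) c(1, 1) else as.numeric(lambda)
    if (length(d$lambda) != 2L) stopMsg("bowing lambda must have length 2")
  }
  structure(d, class = "lcDeformation")
}

#' Compose two deformations
#'
#' Returns the deformation equivalent to applying \code{d1} first and
#' \code{d2} to the result: phi = phi2 o phi1, so
#' U(X) = U1(X) + U2(X + U1(X)).
#'
#' @param d1,d2 objects of class \code{"lcDeformation"}.
#' @return A composite \code{"lcDeformation"}.
#' @export
composeDeformations <- function(d1, d2) {
  stopifnot(inherits(d1, "lcDeformation"), inherits(d2, "lcDeformation"))
  structure(list(kind = "composite", first = d1, second = d2),
            class = "lcDeformation")
}

#' Evaluate a deformation's displacement field
#'
#' @param d an \code{"lcDeformation"}.
#' @param coords numeric matrix (n x 3) of reference coordinates in
#'   micrometres.
#' @return numeric matrix (n x 3) of displacements in micrometres.
#' @export
evaluateDeformation <- function(d, coords) {
  stopifnot(inherits(d, "lcDeformation"))
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  switch(d$kind,
    translation = matrix(d$t, n, 3, byrow = TRUE),
    uniformStrain = sweep(coords, 2, d$center) %*% diag(d$lambda - 1),
    polynomial = {
      u <- matrix(0, n, 3)
      for (i in 1:3) {
        cmp <- d$coef[[c("UX", "UY", "UZ")[i]]]
        P <- cmp$powers
        for (k in seq_along(cmp$coef))
          u[, i] <- u[, i] + cmp$coef[k] *
            coords[, 1]^P[k, 1] * coords[, 2]^P[k, 2] * coords[, 3]^P[k, 3]
      }
      u
    },
    bowing = {
      dx <- coords[, 1] - d$center[1]
      dy <- coords[, 2] - d$center[2]
      cbind((d$lambda[1] - 1) * dx, (d$lambda[2] - 1) * dy,
            d$amplitude * exp(-(dx^2 + dy^2) / (2 * d$width^2)))
    },
    composite = {
      u1 <- evaluateDeformation(d$first, coords)
      u1 + evaluateDeformation(d$second, coords + u1)
    },
    stopMsg("unknown deformation kind '%s'", d$kind))
}

# Inverse mapping: reference coordinates X such that X + U(X) = x.
# Closed form for affine kinds, fixed-point iteration otherwise.
inverseMapCoords <- function(d, coords, iters = 12L) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (d$kind == "translation")
    return(sweep(coords, 2, d$t))
  if (d$kind == "uniformStrain")
    return(sweep(sweep(coords, 2, d$center) %*% diag(1 / d$lambda),
                 2, d$center, "+"))
  X <- coords
  for (i in seq_len(iters))
    X <- coords - evaluateDeformation(d, X)
  X
}

# Sampled check that the mapping X -> X + U(X) has positive Jacobian
# determinant over the volume extent (micrometres).
checkJacobianPositive <- function(d, extent, n = 6L) {
  gx <- seq(0, extent[1], length.out = n)
  gy <- seq(0, extent[2], length.out = n)
  gz <- seq(0, extent[3], length.out = n)
  g <- as.matrix(expand.grid(gx, gy, gz))
  h <- max(extent) * 1e-5
  J <- array(0, c(nrow(g), 3, 3))
  for (j in 1:3) {
    e <- rep(0, 3); e[j] <- h
    up <- evaluateDeformation(d, sweep(g, 2, e, "+"))
    dn <- evaluateDeformation(d, sweep(g, 2, e, "-"))
    J[, , j] <- (up - dn) / (2 * h)
    J[, j, j] <- J[, j, j] + 1
  }
  dets <- J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
          J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
          J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  all(dets > 0)
}
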