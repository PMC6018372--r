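# Trivariate polynomial smoothing of displacement fields and
# Green-Lagrange strain computation.

# exponent table for a full trivariate polynomial of total degree <= deg
monomialPowers <- function(deg) {
  p <- expand.grid(i = 0:deg, j = 0:deg, k = 0:deg)
  p <- as.matrix(p[rowSums(p) <= deg, , drop = FALSE])
  dimnames(p) <- NULL
  storage.mode(p) <- "integer"
  p[order(rowSums(p), p[, 1], p[, 2], p[, 3]), , drop = FALSE]
}

vandermonde <- function(tx, ty, tz, powers) {
  A <- matrix(1, length(tx), nrow(powers))
  for (t in seq_len(nrow(powers))) {
    if (powers[t, 1] > 0) A[, t] <- tx^powers[t, 1]
    if (powers[t, 2] > 0) A[, t] <- A[, t] * ty^powers[t, 2]
    if (powers[t, 3] > 0) A[, t] <- A[, t] * tz^powers[t, 3]
  }
  A
}

#' Fit smoothing polynomials to a displacement field
#'
#' Least-squares fit of one full trivariate polynomial of total degree
#' \code{degree} (default 6, i.e. 84 coefficients) per displacement
#' component, over the valid nodes only, on coordinates affinely normalized
#' to [-1, 1]^3.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param degree total polynomial degree (default 6).
#' @return A \linkS4class{PolynomialFit}.
#' @export
fitPolynomialField <- function(field, degree = 6) {
  stopifnot(is(field, "DisplacementField"))
  degree <- as.integer(degree)
  ok <- field@valid
  g <- expand.grid(x = field@x, y = field@y, z = field@z)
  axes <- c("X", "Y", "Z")
  for (a in 1:3) {
    nun <- length(unique(g[ok, a]))
    if (nun < degree + 1)
      stopMsg("valid nodes span only %d distinct %s positions; degree-%d fit needs %d (deficient axis: %s)",
              nun, axes[a], degree, degree + 1, axes[a])
  }
  center <- vapply(1:3, function(a) mean(range(g[ok, a])), 0)
  halfwidth <- vapply(1:3, function(a) diff(range(g[ok, a])) / 2, 0)
  powers <- monomialPowers(degree)
  if (sum(ok) < nrow(powers))
    stopMsg("%d valid nodes are fewer than the %d polynomial coefficients",
            sum(ok), nrow(powers))
  A <- vandermonde((g[ok, 1] - center[1]) / halfwidth[1],
                   (g[ok, 2] - center[2]) / halfwidth[2],
                   (g[ok, 3] - center[3]) / halfwidth[3], powers)
  qrA <- qr(A)
  if (qrA$rank < ncol(A))
    stopMsg("rank-deficient polynomial design (%d < %d): degenerate node layout",
            qrA$rank, ncol(A))
  U <- cbind(field@UX[ok], field@UY[ok], field@UZ[ok])
  cf <- qr.coef(qrA, U)
  resid <- U - A %*% cf
  new("PolynomialFit", degree = degree, powers = powers,
      coef = unname(cf), center = center, halfwidth = halfwidth,
      rms = sqrt(colMeans(resid^2)))
}

# Evaluate fitted displacement components at coords (n x 3, micrometres).
evaluatePolynomialFit <- function(fit, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  A <- vandermonde((coords[, 1] - fit@center[1]) / fit@halfwidth[1],
                   (coords[, 2] - fit@center[2]) / fit@halfwidth[2],
                   (coords[, 3] - fit@center[3]) / fit@halfwidth[3],
                   fit@powers)
  A %*% fit@coef
}

#' Displacement gradient of a polynomial fit
#'
#' Analytic differentiation of the fitted polynomials, chain-ruled through
#' the domain normalization. Points outside the fitted domain are flagged
#' in the "outside" attribute of the result.
#'
#' @param fit a \linkS4class{PolynomialFit}.
#' @param coords numeric matrix (n x 3) in micrometres.
#' @return numeric array (n x 3 x 3): element [q, i, j] is dU_i/dx_j
#'   (dimensionless), with attribute "outside" (logical n).
#' @export
displacementGradient <- function(fit, coords) {
  stopifnot(is(fit, "PolynomialFit"))
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  tn <- lapply(1:3, function(a) (coords[, a] - fit@center[a]) / fit@halfwidth[a])
  outside <- Reduce(`|`, lapply(tn, function(t) t < -1 - 1e-9 | t > 1 + 1e-9))
  P <- fit@powers
  G <- array(0, c(n, 3, 3))
  pw <- function(t, e) if (e == 0) rep(1, n) else t^e
  for (j in 1:3) {
    # d/dx_j of each monomial, times 1/halfwidth_j
    dA <- matrix(0, n, nrow(P))
    for (t in seq_len(nrow(P))) {
      e <- P[t, ]
      if (e[j] == 0) next
      v <- e[j] * pw(tn[[j]], e[j] - 1L)
      for (a in setdiff(1:3, j)) v <- v * pw(tn[[a]], e[a])
      dA[, t] <- v
    }
    G[, , j] <- (dA %*% fit@coef) / fit@halfwidth[j]
  }
  attr(G, "outside") <- outside
  G
}

#' Green-Lagrange strain tensor from a displacement gradient
#'
#' E = (grad u + grad u' + grad u' grad u) / 2 -- the finite-strain tensor,
#' including the quadratic term, objective under rigid rotations.
#'
#' @param gradU numeric array (n x 3 x 3) of displacement gradients, or a
#'   single 3 x 3 matrix.
#' @return numeric array (n x 3 x 3) of symmetric strain tensors (or a
#'   3 x 3 matrix if a single gradient was supplied).
#' @export
greenLagrange <- function(gradU) {
  single <- length(dim(gradU)) == 2L
  if (single) gradU <- array(gradU, c(1, 3, 3))
  stopifnot(all(is.finite(gradU)))
  E <- array(0, dim(gradU))
  for (i in 1:3) for (j in 1:3) {
    q <- gradU[, i, j] + gradU[, j, i]
    for (k in 1:3) q <- q + gradU[, k, i] * gradU[, k, j]
    E[, i, j] <- q / 2
  }
  if (single) E[1, , ] else E
}

#' Maximum in-plane principal and shear strain
#'
#' Mohr-circle closed forms for the 2D (X-Y) strain state:
#' Emax = (EXX + EYY)/2 + R and Gmax = R with
#' R = sqrt(((EXX - EYY)/2)^2 + EXY^2). Gmax is the tensorial maximum
#' shear (the Mohr radius).
#'
#' @param EXX,EYY,EXY numeric vectors or arrays of in-plane components.
#' @return list(EMAX, GMAX) with the shape of the inputs.
#' @export
principalAndShear <- function(EXX, EYY, EXY) {
  R <- sqrt(((EXX - EYY) / 2)^2 + EXY^2)
  list(EMAX = (EXX + EYY) / 2 + R, GMAX = R)
}

#' Evaluate a strain field on a regular grid
#'
#' Evaluates the polynomial displacement gradient on a regular grid at the
#' strain-reporting resolution (default every 4 in-plane voxels = 10 um and
#' every 2 slices = 6 um for the default voxel size), forms the
#' Green-Lagrange tensor and the derived in-plane measures. Grid nodes are
#' valid when the nearest displacement node was valid.
#'
#' @param fit a \linkS4class{PolynomialFit}.
#' @param field the \linkS4class{DisplacementField} the fit came from
#'   (supplies the valid mask and voxel size).
#' @param spacingVoxels integer(3) strain-grid spacing in voxels.
#' @return A \linkS4class{StrainField}.
#' @export
strainFieldFromFit <- function(fit, field, spacingVoxels = c(4, 4, 2)) {
  stopifnot(is(fit, "PolynomialFit"), is(field, "DisplacementField"))
  sp <- spacingVoxels * field@voxelSize
  gx <- seq(min(field@x), max(field@x), by = sp[1])
  gy <- seq(min(field@y), max(field@y), by = sp[2])
  gz <- seq(min(field@z), max(field@z), by = sp[3])
  g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  G <- displacementGradient(fit, g)
  E <- greenLagrange(G)
  dmg <- c(length(gx), length(gy), length(gz))
  comp <- list(EXX = E[, 1, 1], EYY = E[, 2, 2], EXY = E[, 1, 2],
               EZZ = E[, 3, 3], EXZ = E[, 1, 3], EYZ = E[, 2, 3])
  comp <- lapply(comp, function(v) { dim(v) <- dmg; v })
  ps <- principalAndShear(comp$EXX, comp$EYY, comp$EXY)
  # nearest displacement node determines validity
  nx <- pmin(pmax(vapply(gx, function(v) which.min(abs(field@x - v)), 1L), 1L),
             length(field@x))
  ny <- vapply(gy, function(v) which.min(abs(field@y - v)), 1L)
  nz <- vapply(gz, function(v) which.min(abs(field@z - v)), 1L)
  valid <- field@valid[nx, ny, nz, drop = FALSE]
  dim(valid) <- dmg
  new("StrainField", x = gx, y = gy, z = gz, components = comp,
      EMAX = ps$EMAX, GMAX = ps$GMAX, valid = valid)
}

#' Full displacement-to-strain pipeline step
#'
#' Convenience wrapper: degree-6 polynomial fit of the displacement field
#' followed by strain evaluation on the reporting grid.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param degree polynomial degree (default 6).
#' @param spacingVoxels strain-grid spacing in voxels.
#' @return A \linkS4class{StrainField}.
#' @export
computeStrain <- function(field, degree = 6, spacingVoxels = c(4, 4, 2)) {
  strainFieldFromFit(fitPolynomialField(field, degree), field, spacingVoxels)
}

#' Average strain fields through depth
#'
#' Signed mean over valid Z nodes at each (X, Y) column, for the five
#' reported fields EXX, EYY, EXY, EMAX and GMAX. The derived measures are
#' averaged as fields, not recomputed from the averaged components. Columns
#' with no valid node are flagged invalid.
#'
#' @param strain a \linkS4class{StrainField}.
#' @return list of class \code{"lcStrainMaps"}: x, y, maps (named list of
#'   2D matrices), valid (2D logical), nValid (2D integer).
#' @export
averageThroughZ <- function(strain) {
  stopifnot(is(strain, "StrainField"))
  fields <- c(strain@components[c("EXX", "EYY", "EXY")],
              list(EMAX = strain@EMAX, GMAX = strain@GMAX))
  v <- strain@valid
  nValid <- apply(v, c(1, 2), sum)
  maps <- lapply(fields, function(f) {
    f[!v] <- NA_real_
    m <- apply(f, c(1, 2), function(col) mean(col, na.rm = TRUE))
    m[nValid == 0] <- NA_real_
    m
  })
  structure(list(x = strain@x, y = strain@y, maps = maps,
                 valid = nValid > 0, nValid = nValid),
            class = "lcStrainMaps")
}
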