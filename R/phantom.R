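#' Specification of a synthetic lamina cribrosa phantom
#'
#' Defines the geometry, texture and noise of an SHG-like synthetic z-stack:
#' an elliptical lamina cribrosa (LC) filled with bright collagen-beam
#' texture, surrounded by an oversaturated peripapillary scleral ring, with a
#' dark central-vessel (CRAV) disk and optional dark non-correlating patches.
#'
#' @param gridShape integer(3) voxel counts along X, Y, Z.
#' @param voxelSize numeric(3) micrometres per voxel (default 2.5 in-plane,
#'   3 axially, matching a 10 um / 4 px strain grid and 3 um z-steps).
#' @param ellipseCenter LC ellipse center in micrometres (default: volume
#'   center).
#' @param semiAxes numeric(2) ellipse semi-axes a, b in micrometres; must
#'   exceed \code{cravRadius}.
#' @param tilt ellipse orientation angle in radians.
#' @param cravCenter CRAV center (micrometres; default ellipse center).
#' @param cravRadius CRAV disk radius in micrometres (default 200).
#' @param beamDensity fraction of the LC interior occupied by bright beams,
#'   in [0, 1].
#' @param ppsRingWidth width of the saturated scleral ring (micrometres).
#' @param darkPatchCount number of dark spherical non-correlating patches.
#' @param darkPatchRadius numeric(2) min/max patch radius (micrometres).
#' @param noiseSigma additive Gaussian noise standard deviation (intensity
#'   units on the [0,1] scale).
#' @param background background intensity level.
#' @param seed integer RNG seed; fixed seed gives bit-identical phantoms.
#' @return A validated list of class \code{"lcPhantomSpec"}.
#' @export
phantomSpec <- function(gridShape = c(256, 256, 64),
                        voxelSize = c(2.5, 2.5, 3),
                        ellipseCenter = NULL,
                        semiAxes = c(280, 240),
                        tilt = 0,
                        cravCenter = NULL,
                        cravRadius = 200,
                        beamDensity = 0.35,
                        ppsRingWidth = 30,
                        darkPatchCount = 3,
                        darkPatchRadius = c(15, 40),
                        noiseSigma = 0.02,
                        background = 0.05,
                        seed = 1L) {
  gridShape <- as.integer(gridShape)
  extent <- (gridShape - 1) * voxelSize
  if (is.null(ellipseCenter)) ellipseCenter <- extent[1:2] / 2
  if (is.null(cravCenter)) cravCenter <- ellipseCenter
  spec <- list(gridShape = gridShape, voxelSize = as.numeric(voxelSize),
               ellipseCenter = as.numeric(ellipseCenter),
               semiAxes = as.numeric(semiAxes), tilt = as.numeric(tilt),
               cravCenter = as.numeric(cravCenter),
               cravRadius = as.numeric(cravRadius),
               beamDensity = as.numeric(beamDensity),
               ppsRingWidth = as.numeric(ppsRingWidth),
               darkPatchCount = as.integer(darkPatchCount),
               darkPatchRadius = as.numeric(darkPatchRadius),
               noiseSigma = as.numeric(noiseSigma),
               background = as.numeric(background), seed = as.integer(seed))
  if (any(spec$semiAxes <= spec$cravRadius))
    stopMsg("ellipse semi-axes (%s um) must exceed the CRAV radius (%g um)",
            paste(spec$semiAxes, collapse = ", "), spec$cravRadius)
  if (spec$beamDensity < 0 || spec$beamDensity > 1)
    stopMsg("beamDensity must lie in [0, 1]")
  # outer (ellipse + ring) bounding half-extents must fit in the grid
  ao <- spec$semiAxes[1] + spec$ppsRingWidth
  bo <- spec$semiAxes[2] + spec$ppsRingWidth
  hx <- sqrt((ao * cos(spec$tilt))^2 + (bo * sin(spec$tilt))^2)
  hy <- sqrt((ao * sin(spec$tilt))^2 + (bo * cos(spec$tilt))^2)
  if (spec$ellipseCenter[1] - hx < 0 || spec$ellipseCenter[1] + hx > extent[1] ||
      spec$ellipseCenter[2] - hy < 0 || spec$ellipseCenter[2] + hy > extent[2])
    stopMsg("grid too small for ellipse plus peripapillary ring")
  structure(spec, class = "lcPhantomSpec")
}

#' Generate a synthetic LC phantom volume
#'
#' Deterministic for a fixed spec seed. The LC interior carries spatially
#' broadband beam texture suitable for subset correlation; the scleral ring
#' saturates at full intensity; the CRAV disk and dark patches sit at
#' background level (emulating regions that fail to correlate).
#'
#' @param spec an \code{"lcPhantomSpec"} from \code{\link{phantomSpec}}.
#' @return An \linkS4class{ImageVolume} whose \code{meta} records the spec
#'   and the true geometry.
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "lcPhantomSpec"))
  d <- spec$gridShape
  vx <- spec$voxelSize
  xs <- (0:(d[1] - 1)) * vx[1]
  ys <- (0:(d[2] - 1)) * vx[2]

  # 2D masks shared across z (the LC opening, ring and CRAV are cylindrical)
  dxm <- outer(xs - spec$ellipseCenter[1], rep(1, d[2]))
  dym <- outer(rep(1, d[1]), ys - spec$ellipseCenter[2])
  ct <- cos(spec$tilt); st <- sin(spec$tilt)
  xr <- ct * dxm + st * dym
  yr <- -st * dxm + ct * dym
  insideLc <- (xr / spec$semiAxes[1])^2 + (yr / spec$semiAxes[2])^2 <= 1
  ao <- spec$semiAxes[1] + spec$ppsRingWidth
  bo <- spec$semiAxes[2] + spec$ppsRingWidth
  insideOuter <- (xr / ao)^2 + (yr / bo)^2 <= 1
  ring <- insideOuter & !insideLc
  rc <- sqrt(outer(xs - spec$cravCenter[1], rep(1, d[2]))^2 +
             outer(rep(1, d[1]), ys - spec$cravCenter[2])^2)
  crav <- rc < spec$cravRadius

  vol <- withSeed(spec$seed, {
    v <- array(spec$background, dim = d)
    if (spec$beamDensity > 0) {
      # broadband beam texture: thresholded, modulated smooth noise
      s <- gaussianSmooth3(array(rnorm(prod(d)), dim = d), c(1.5, 1.5, 1.0))
      s <- (s - mean(s)) / sd(s)
      q <- qnorm(1 - spec$beamDensity)
      beam <- s > q
      tex <- 0.55 + 0.35 * tanh(s - q)
      lc3 <- array(insideLc & !crav, dim = d)
      sel <- lc3 & beam
      v[sel] <- tex[sel]
    }
    ring3 <- array(ring, dim = d)
    v[ring3] <- 1.0
    if (spec$darkPatchCount > 0) {
      zs <- (0:(d[3] - 1)) * vx[3]
      for (p in seq_len(spec$darkPatchCount)) {
        # rejection-sample a patch center well inside the LC
        repeat {
          th <- runif(1, 0, 2 * pi); rr <- sqrt(runif(1))
          cxr <- 0.85 * spec$semiAxes[1] * rr * cos(th)
          cyr <- 0.85 * spec$semiAxes[2] * rr * sin(th)
          cx <- spec$ellipseCenter[1] + ct * cxr - st * cyr
          cy <- spec$ellipseCenter[2] + st * cxr + ct * cyr
          if (sqrt((cx - spec$cravCenter[1])^2 +
                   (cy - spec$cravCenter[2])^2) > spec$cravRadius) break
        }
        cz <- runif(1, min(zs), max(zs))
        pr <- runif(1, spec$darkPatchRadius[1], spec$darkPatchRadius[2])
        ix <- which(abs(xs - cx) <= pr); iy <- which(abs(ys - cy) <= pr)
        iz <- which(abs(zs - cz) <= pr)
        if (length(ix) && length(iy) && length(iz)) {
          d2 <- outer(outer((xs[ix] - cx)^2, (ys[iy] - cy)^2, "+"),
                      (zs[iz] - cz)^2, "+")
          sub <- v[ix, iy, iz, drop = FALSE]
          sub[d2 <= pr^2] <- spec$background
          v[ix, iy, iz] <- sub
        }
      }
    }
    if (spec$noiseSigma > 0)
      v <- v + rnorm(prod(d), sd = spec$noiseSigma)
    pmin(pmax(v, 0), 1)
  })

  imageVolume(vol, voxelSize = vx,
              meta = list(spec = spec,
                          ellipse = list(center = spec$ellipseCenter,
                                         a = spec$semiAxes[1],
                                         b = spec$semiAxes[2],
                                         angle = spec$tilt),
                          cravCenter = spec$cravCenter,
                          cravRadius = spec$cravRadius))
}

#' Noisy samples of a phantom's LC boundary
#'
#' Emulates manually picked LC/sclera boundary points by sampling the true
#' ellipse and perturbing each point with isotropic Gaussian noise.
#'
#' @param spec an \code{"lcPhantomSpec"}.
#' @param n number of points.
#' @param sdNoise point noise standard deviation (micrometres).
#' @param seed RNG seed.
#' @return n x 2 matrix of boundary points (micrometres).
#' @export
phantomBoundaryPoints <- function(spec, n = 40, sdNoise = 5, seed = 1L) {
  stopifnot(inherits(spec, "lcPhantomSpec"))
  withSeed(seed, {
    th <- sort(runif(n, 0, 2 * pi))
    ct <- cos(spec$tilt); st <- sin(spec$tilt)
    px <- spec$semiAxes[1] * cos(th); py <- spec$semiAxes[2] * sin(th)
    cbind(spec$ellipseCenter[1] + ct * px - st * py + rnorm(n, sd = sdNoise),
          spec$ellipseCenter[2] + st * px + ct * py + rnorm(n, sd = sdNoise))
  })
}

#' Add acquisition noise to a volume
#'
#' Models the independent sensor noise of a repeated acquisition of the same
#' specimen (used to emulate duplicate z-stacks).
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param sigma Gaussian noise standard deviation (intensity units).
#' @param seed RNG seed.
#' @return A new \linkS4class{ImageVolume}.
#' @export
addAcquisitionNoise <- function(vol, sigma, seed) {
  stopifnot(is(vol, "ImageVolume"))
  v <- withSeed(seed,
    pmin(pmax(vol@data + rnorm(length(vol@data), sd = sigma), 0), 1))
  dim(v) <- dim(vol@data)
  initialize(vol, data = v)
}

#' Warp an image volume by an analytic deformation
#'
#' Produces the deformed volume by backward mapping: the output voxel at
#' deformed coordinate x takes the reference intensity at the inverse-mapped
#' coordinate X with X + U(X) = x (closed form for affine deformations,
#' fixed-point iteration otherwise), sampled by Catmull-Rom cubic
#' interpolation. Voxels mapped from outside the reference grid are filled
#' with the background level and flagged in \code{meta$outsideMask}.
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param d an \code{"lcDeformation"}.
#' @param fill fill intensity for unmapped voxels (default: the volume's
#'   5th percentile, a background estimate).
#' @return A warped \linkS4class{ImageVolume}; \code{meta$deformation}
#'   records the applied ground truth.
#' @export
warpVolume <- function(vol, d, fill = NULL) {
  stopifnot(is(vol, "ImageVolume"), inherits(d, "lcDeformation"))
  dm <- dim(vol@data)
  vx <- vol@voxelSize
  if (!checkJacobianPositive(d, (dm - 1) * vx))
    stopMsg("deformation mapping is not invertible on the grid (non-positive Jacobian)")
  if (is.null(fill)) fill <- as.numeric(quantile(vol@data, 0.05))
  g <- expand.grid(x = (0:(dm[1] - 1)) * vx[1],
                   y = (0:(dm[2] - 1)) * vx[2],
                   z = (0:(dm[3] - 1)) * vx[3])
  X <- inverseMapCoords(d, as.matrix(g))
  res <- cpp_interp3(vol@data, X[, 1] / vx[1], X[, 2] / vx[2], X[, 3] / vx[3],
                     fill, TRUE)
  w <- res$values
  dim(w) <- dm
  outside <- !res$inside
  dim(outside) <- dm
  meta <- vol@meta
  meta$deformation <- d
  meta$outsideMask <- outside
  initialize(vol, data = w, meta = meta)
}
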