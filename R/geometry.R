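# LC boundary ellipse fitting, CRAV disk, and the eight analysis regions.

#' Direct least-squares ellipse fit
#'
#' Stable direct conic fit constrained to an ellipse (Fitzgibbon constraint
#' 4ac - b^2 = 1 solved via the Halir-Flusser block decomposition), returned
#' in geometric form.
#'
#' @param points numeric matrix (n x 2) of boundary points (micrometres),
#'   n >= 6 and not collinear.
#' @return list(center, a, b, angle) with semi-axes a >= b (micrometres) and
#'   the orientation of the a axis in radians in (-pi/2, pi/2].
#' @export
fitEllipse <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 6) stopMsg("ellipse fit needs at least 6 points")
  mu <- colMeans(points)
  x <- points[, 1] - mu[1]; y <- points[, 2] - mu[2]
  if (abs(max(x) - min(x)) < 1e-12 || abs(max(y) - min(y)) < 1e-12 ||
      qr(cbind(x, y))$rank < 2)
    stopMsg("boundary points are collinear or degenerate")
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  sel <- which(cond > 0)
  if (!length(sel)) stopMsg("direct fit did not yield an ellipse")
  a1 <- vecs[, sel[1]]
  cf <- c(a1, Tm %*% a1)        # A B C D E F on centered coordinates
  A <- cf[1]; B <- cf[2]; C <- cf[3]; Dc <- cf[4]; E <- cf[5]; Fc <- cf[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stopMsg("direct fit did not yield an ellipse")
  xc <- (2 * C * Dc - B * E) / den
  yc <- (2 * A * E - B * Dc) / den
  # centered conic: A u^2 + B uv + C v^2 = -val; radius along angle phi
  val <- A * xc^2 + B * xc * yc + C * yc^2 + Dc * xc + E * yc + Fc
  radiusAt <- function(phi) {
    gq <- A * cos(phi)^2 + B * cos(phi) * sin(phi) + C * sin(phi)^2
    sqrt(-val / gq)
  }
  th0 <- 0.5 * atan2(B, A - C)
  r0 <- radiusAt(th0); r90 <- radiusAt(th0 + pi / 2)
  if (!is.finite(r0) || !is.finite(r90))
    stopMsg("degenerate conic: could not recover ellipse axes")
  if (r0 >= r90) {
    a <- r0; b <- r90; theta <- th0
  } else {
    a <- r90; b <- r0; theta <- th0 + pi / 2
  }
  theta <- ((theta + pi / 2) %% pi) - pi / 2
  list(center = c(xc + mu[1], yc + mu[2]), a = a, b = b, angle = theta)
}

# Distance from `from` to the ellipse boundary along direction angle theta
# (vectorized over theta).
ellipseRayDistance <- function(ellipse, from, theta) {
  ct <- cos(ellipse$angle); st <- sin(ellipse$angle)
  # to ellipse frame
  dx <- from[1] - ellipse$center[1]; dy <- from[2] - ellipse$center[2]
  p0x <- ct * dx + st * dy; p0y <- -st * dx + ct * dy
  dvx <- cos(theta); dvy <- sin(theta)
  dfx <- ct * dvx + st * dvy; dfy <- -st * dvx + ct * dvy
  A <- (dfx / ellipse$a)^2 + (dfy / ellipse$b)^2
  B <- 2 * (p0x * dfx / ellipse$a^2 + p0y * dfy / ellipse$b^2)
  C <- (p0x / ellipse$a)^2 + (p0y / ellipse$b)^2 - 1
  disc <- B^2 - 4 * A * C
  ifelse(disc < 0, NA_real_, (-B + sqrt(pmax(disc, 0))) / (2 * A))
}

lcRegionLevels <- function() {
  c("background", "CRAV",
    "central.S", "central.I", "central.T", "central.N",
    "peripheral.S", "peripheral.I", "peripheral.T", "peripheral.N")
}

#' Segment the LC into the eight analysis regions
#'
#' Partitions a 2D analysis grid into background (outside the LC ellipse),
#' the CRAV exclusion disk (radial distance < \code{cravRadius} from the
#' CRAV center), and central/peripheral quadrant regions. The
#' central/peripheral boundary along each ray from the CRAV center is the
#' mid-radial distance between the CRAV circle and the ellipse intersection
#' on that ray. Quadrants use 45 and 135 degree bisectors about the CRAV
#' center; the nasal quadrant lies toward +X for right eyes ("OD") and -X
#' for left eyes ("OS"), with +Y superior.
#'
#' @param ellipse geometric ellipse (list center, a, b, angle), e.g. from
#'   \code{\link{fitEllipse}}.
#' @param cravCenter numeric(2) CRAV center (micrometres).
#' @param cravRadius CRAV radius in micrometres (default 200).
#' @param x,y grid coordinates (micrometres).
#' @param eye "OD" or "OS" laterality for the quadrant-anatomy mapping.
#' @return An \linkS4class{LcGeometry}.
#' @export
segmentRegions <- function(ellipse, cravCenter, cravRadius = 200, x, y,
                           eye = "OD") {
  # CRAV disk must lie strictly inside the ellipse
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  rho <- ellipseRayDistance(ellipse, cravCenter, th)
  if (anyNA(rho) || any(rho <= cravRadius))
    stopMsg("CRAV disk (r=%g um) crosses the LC ellipse boundary", cravRadius)

  lev <- lcRegionLevels()
  dx <- outer(x - cravCenter[1], rep(1, length(y)))
  dy <- outer(rep(1, length(x)), y - cravCenter[2])
  r <- sqrt(dx^2 + dy^2)
  thetaN <- atan2(dy, if (eye == "OD") dx else -dx)  # 0 = nasal direction
  # inside-ellipse test in the ellipse frame
  ex <- outer(x - ellipse$center[1], rep(1, length(y)))
  ey <- outer(rep(1, length(x)), y - ellipse$center[2])
  ct <- cos(ellipse$angle); st <- sin(ellipse$angle)
  xr <- ct * ex + st * ey; yr <- -st * ex + ct * ey
  inside <- (xr / ellipse$a)^2 + (yr / ellipse$b)^2 <= 1

  theta <- atan2(dy, dx)
  rho <- matrix(ellipseRayDistance(ellipse, cravCenter, as.numeric(theta)),
                nrow = length(x))
  midR <- (cravRadius + rho) / 2

  quad <- ifelse(thetaN > pi / 4 & thetaN <= 3 * pi / 4, "S",
          ifelse(thetaN <= -pi / 4 & thetaN > -3 * pi / 4, "I",
          ifelse(thetaN > -pi / 4 & thetaN <= pi / 4, "N", "T")))
  band <- ifelse(r < midR, "central", "peripheral")
  name <- matrix("background", length(x), length(y))
  name[inside] <- paste(band[inside], quad[inside], sep = ".")
  name[inside & r < cravRadius] <- "CRAV"
  labels <- matrix(match(name, lev), length(x), length(y))

  new("LcGeometry", ellipse = ellipse, cravCenter = as.numeric(cravCenter),
      cravRadius = as.numeric(cravRadius), x = as.numeric(x),
      y = as.numeric(y), labels = labels, labelLevels = lev)
}

#' Regional average strain magnitudes
#'
#' Mean absolute value over valid nodes per analysis region (CRAV and
#' background excluded). The average magnitude, rather than the signed
#' mean, prevents compressive and tensile areas from cancelling. Regions
#' with no valid nodes are omitted from the result.
#'
#' @param map numeric 2D matrix over the geometry grid (e.g. a Z-averaged
#'   strain component).
#' @param geom an \linkS4class{LcGeometry} on the same grid.
#' @param valid optional logical matrix of usable nodes.
#' @return Named numeric vector of per-region average magnitudes.
#' @export
regionalAverageMagnitude <- function(map, geom, valid = NULL) {
  stopifnot(is(geom, "LcGeometry"))
  if (!identical(dim(map), dim(geom@labels)))
    stopMsg("map dimensions (%s) do not match geometry grid (%s)",
            paste(dim(map), collapse = "x"),
            paste(dim(geom@labels), collapse = "x"))
  if (is.null(valid)) valid <- !is.na(map)
  regions <- lcRegionLevels()[-(1:2)]
  out <- vapply(regions, function(rg) {
    sel <- geom@labels == match(rg, geom@labelLevels) & valid & !is.na(map)
    if (!any(sel)) NA_real_ else mean(abs(map[sel]))
  }, 0)
  out <- out[!is.na(out)]
  if (!length(out)) stopMsg("no region contains valid nodes")
  out
}

#' Whole-LC average strain magnitude
#'
#' Mean absolute value over all valid nodes in the eight analysis regions
#' (the specimen-level strain outcome).
#'
#' @inheritParams regionalAverageMagnitude
#' @return A single numeric value.
#' @export
lcAverageMagnitude <- function(map, geom, valid = NULL) {
  stopifnot(is(geom, "LcGeometry"))
  if (is.null(valid)) valid <- !is.na(map)
  sel <- geom@labels > 2L & valid & !is.na(map)
  if (!any(sel)) stopMsg("no valid LC nodes")
  mean(abs(map[sel]))
}
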