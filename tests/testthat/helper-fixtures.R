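# Shared fixtures: small phantoms and displacement fields built in code.

# Compact textured phantom for correlation tests (run time matters more
# than anatomical realism here).
smallPhantom <- function(grid = c(96, 96, 32), seed = 7, noise = 0.02,
                         patches = 0) {
  generatePhantom(phantomSpec(
    gridShape = grid, semiAxes = c(95, 85) * min(grid[1:2]) / 96,
    cravRadius = 30, ppsRingWidth = 10, darkPatchCount = patches,
    darkPatchRadius = c(10, 20), noiseSigma = noise, seed = seed))
}

smallDvcConfig <- function(...) {
  dvcConfig(subsetSchedule = c(48, 24, 16), ...)
}

# Displacement field on a regular grid with analytic U and full validity.
analyticField <- function(fun, nx = 9, ny = 9, nz = 8,
                          spacing = c(20, 20, 12), voxel = c(2.5, 2.5, 3)) {
  x <- (0:(nx - 1)) * spacing[1]
  y <- (0:(ny - 1)) * spacing[2]
  z <- (0:(nz - 1)) * spacing[3]
  g <- expand.grid(x = x, y = y, z = z)
  u <- fun(g$x, g$y, g$z)       # list(UX, UY, UZ)
  m <- c(nx, ny, nz)
  new("DisplacementField", x = x, y = y, z = z,
      UX = array(u$UX, m), UY = array(u$UY, m), UZ = array(u$UZ, m),
      quality = array(1, m), valid = array(TRUE, m), voxelSize = voxel)
}

# Random trivariate polynomial displacement specification of total degree 6
# on normalized coordinates, returned as a function of micrometre coords.
randomDegree6 <- function(seed, scale = 1, center, halfwidth) {
  set.seed(seed)
  powers <- lcstrain:::monomialPowers(6L)
  cf <- matrix(rnorm(nrow(powers) * 3, sd = scale / rowSums(powers + 1)), ncol = 3)
  list(powers = powers, coef = cf,
       fun = function(x, y, z) {
         tx <- (x - center[1]) / halfwidth[1]
         ty <- (y - center[2]) / halfwidth[2]
         tz <- (z - center[3]) / halfwidth[3]
         A <- lcstrain:::vandermonde(tx, ty, tz, powers)
         u <- A %*% cf
         list(UX = u[, 1], UY = u[, 2], UZ = u[, 3])
       })
}
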