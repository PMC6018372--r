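# Subset correlation and the iterative DVC engine.

test_that("a subset correlates with itself at zero offset and unit quality", {
  ph <- smallPhantom(grid = c(64, 64, 24), seed = 21)
  sub <- intensities(ph)[17:48, 17:48, 5:20]
  r <- correlateSubset(sub, sub)
  expect_true(r$valid)
  expect_equal(r$offset, c(0, 0, 0), tolerance = 1e-8)
  expect_equal(r$quality, 1, tolerance = 1e-8)

  flat <- array(0.3, dim = c(16, 16, 16))
  rf <- correlateSubset(flat, flat)
  expect_false(rf$valid)
  expect_true(is.na(rf$quality))
})

test_that("integer offsets match a spatial-domain correlation oracle", {
  ph <- smallPhantom(grid = c(64, 64, 32), seed = 22)
  v <- intensities(ph)
  ref <- v[17:40, 17:40, 9:24]
  def <- v[17:40 - 3, 17:40 + 2, 9:24 - 1]   # content shifted by (+3, -2, +1)
  r <- correlateSubset(ref, def)
  expect_equal(round(r$offset), c(3, -2, 1))

  # oracle: direct normalized correlation over candidate integer shifts
  score <- function(s) {
    n <- dim(ref)
    ia <- list(max(1, 1 + s[1]):min(n[1], n[1] + s[1]),
               max(1, 1 + s[2]):min(n[2], n[2] + s[2]),
               max(1, 1 + s[3]):min(n[3], n[3] + s[3]))
    a <- ref[ia[[1]] - s[1], ia[[2]] - s[2], ia[[3]] - s[3]]
    b <- def[ia[[1]], ia[[2]], ia[[3]]]
    sum((a - mean(a)) * (b - mean(b))) / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  }
  cand <- as.matrix(expand.grid(x = 1:5, y = -4:0, z = -1:3))
  best <- cand[which.max(apply(cand, 1, score)), ]
  expect_equal(unname(best), c(3, -2, 1))
})

test_that("subpixel offsets are recovered within 0.1 px of an upsampled oracle", {
  ph <- smallPhantom(grid = c(64, 64, 24), seed = 23, noise = 0)
  sub <- intensities(ph)[17:48, 17:48, 5:20]
  nx <- dim(sub)[1]
  # band-limit along X, then shift by exactly 0.5 px via Fourier phase
  F <- apply(sub, c(2, 3), fft)                 # nx-length spectra per line
  kx <- c(0:(nx / 2), -((nx / 2 - 1):1))
  keep <- abs(kx) <= nx / 4
  F[!keep, , ] <- 0
  band <- apply(F, c(2, 3), function(s) Re(fft(s, inverse = TRUE)) / nx)
  shift <- apply(F * exp(-2i * pi * kx * 0.5 / nx), c(2, 3),
                 function(s) Re(fft(s, inverse = TRUE)) / nx)
  r <- correlateSubset(band, shift)
  expect_lt(abs(r$offset[1] - 0.5), 0.1)
  expect_lt(abs(r$offset[2]), 0.05)

  # oracle: dense correlation on a 10x upsampled axis (zero-padded spectra)
  up <- function(a) {
    Fa <- apply(a, c(2, 3), fft)
    pad <- array(0i, c(10 * nx, dim(a)[2], dim(a)[3]))
    pad[1:(nx / 2 + 1), , ] <- Fa[1:(nx / 2 + 1), , ]
    pad[(10 * nx - nx / 2 + 2):(10 * nx), , ] <- Fa[(nx / 2 + 2):nx, , ]
    apply(pad, c(2, 3), function(s) Re(fft(s, inverse = TRUE)) / nx)
  }
  ua <- up(band); ub <- up(shift)
  lags <- -15:15
  ncc <- sapply(lags, function(l) {
    n <- dim(ua)[1]
    ia <- (1 + max(0, l)):(n + min(0, l))
    a <- ua[ia - l, , ]; b <- ub[ia, , ]
    sum((a - mean(a)) * (b - mean(b))) / sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  })
  oracleOffset <- lags[which.max(ncc)] / 10
  expect_equal(oracleOffset, 0.5, tolerance = 0.051)
  expect_lt(abs(r$offset[1] - oracleOffset), 0.1)
})

test_that("DVC of a volume against itself yields a null field", {
  ph <- smallPhantom(seed = 24)
  f <- runFidvc(ph, ph, smallDvcConfig())
  v <- validMask(f)
  # depth-invariant ring/background windows are masked; the LC correlates
  expect_gt(mean(v), 0.8)
  u <- displacements(f)
  expect_lt(max(abs(u$UX[v]), abs(u$UY[v]), abs(u$UZ[v])), 1e-6)
  expect_gt(min(quality(f)[v]), 0.99)
})

test_that("DVC recovers integer translations (equivariance on the interior)", {
  ph <- smallPhantom(seed = 25)
  vx <- voxelSize(ph)
  d <- deformation("translation", t = c(3, -2, 1), units = "voxel", voxelSize = vx)
  f <- runFidvc(ph, warpVolume(ph, d), smallDvcConfig())
  v <- validMask(f)
  expect_gt(mean(v), 0.5)
  expect_lt(abs(mean(displacements(f)$UX[v]) / vx[1] - 3), 0.05)
  expect_lt(abs(mean(displacements(f)$UY[v]) / vx[2] + 2), 0.05)
  expect_lt(abs(mean(displacements(f)$UZ[v]) / vx[3] - 1), 0.05)
})

test_that("swapping reference and deformed negates the field", {
  ph <- smallPhantom(seed = 26)
  d <- deformation("translation", t = c(2.5, 5, 3))
  w <- warpVolume(ph, d)
  f1 <- runFidvc(ph, w, smallDvcConfig())
  f2 <- runFidvc(w, ph, smallDvcConfig())
  v <- validMask(f1) & validMask(f2)
  expect_gt(mean(v), 0.5)
  expect_equal(mean(displacements(f1)$UX[v]), -mean(displacements(f2)$UX[v]),
               tolerance = 0.15)
  expect_equal(mean(displacements(f1)$UZ[v]), -mean(displacements(f2)$UZ[v]),
               tolerance = 0.15)
})

test_that("masked fraction grows with the quality threshold and dark regions fail", {
  ph <- smallPhantom(seed = 27, patches = 2)
  d <- deformation("translation", t = c(2.5, 2.5, 0))
  w <- warpVolume(ph, d)
  f1 <- runFidvc(ph, w, smallDvcConfig(qualityThreshold = 0.2))
  f2 <- runFidvc(ph, w, smallDvcConfig(qualityThreshold = 0.6))
  expect_lte(sum(validMask(f2)), sum(validMask(f1)))
  # every node valid at the stricter threshold is valid at the looser one
  expect_true(all(validMask(f1)[validMask(f2)]))
})

test_that("focal offsets shift U_Z only and invert cleanly", {
  f <- analyticField(function(x, y, z)
    list(UX = 0.01 * x, UY = rep(0, length(x)), UZ = 0.2 + 0 * z))
  f0 <- applyFocalOffset(f, 0)
  expect_equal(displacements(f0), displacements(f))
  f12 <- applyFocalOffset(f, 12)
  expect_equal(mean(displacements(f12)$UZ) - mean(displacements(f)$UZ), 12)
  expect_equal(displacements(f12)$UX, displacements(f)$UX)
  back <- applyFocalOffset(f12, -12)
  expect_equal(displacements(back)$UZ, displacements(f)$UZ)
})

test_that("the focal-offset difference between acquisitions enters U_Z", {
  ph <- smallPhantom(seed = 28)
  ph2 <- ph
  ph2@focalOffset <- 9
  f <- runFidvc(ph, ph2, smallDvcConfig())
  v <- validMask(f)
  expect_equal(mean(displacements(f)$UZ[v]), 9, tolerance = 1e-6)
})
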