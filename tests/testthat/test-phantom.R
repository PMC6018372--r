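# Synthetic phantom generation and analytic warping.

test_that("phantom generation is deterministic and respects degenerate density", {
  spec <- phantomSpec(gridShape = c(64, 64, 16), semiAxes = c(60, 50),
                      cravRadius = 20, ppsRingWidth = 8, darkPatchCount = 1,
                      noiseSigma = 0.01, seed = 11)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(intensities(a), intensities(b))

  # beamDensity 0, no noise: ring only, interior flat at background
  spec0 <- phantomSpec(gridShape = c(64, 64, 16), semiAxes = c(60, 50),
                       cravRadius = 20, ppsRingWidth = 8, darkPatchCount = 0,
                       beamDensity = 0, noiseSigma = 0, seed = 11)
  v0 <- intensities(generatePhantom(spec0))
  xs <- (0:63) * 2.5 - 78.75; ys <- xs
  inside <- outer(xs^2 / 60^2, ys^2 / 50^2, "+") <= 0.8^2
  interior <- v0[, , 8][inside]
  expect_equal(sd(interior), 0)
  expect_equal(unique(interior), spec0$background)
  expect_equal(max(v0), 1)   # saturated scleral ring present
})

test_that("phantom spec invariants are enforced", {
  expect_error(phantomSpec(semiAxes = c(150, 150), cravRadius = 200),
               "exceed the CRAV radius")
  expect_error(phantomSpec(gridShape = c(64, 64, 16)),
               "grid too small")
  expect_error(phantomSpec(beamDensity = 1.2), "beamDensity")
})

test_that("interior texture autocorrelation length is a few voxels", {
  ph <- smallPhantom(noise = 0, seed = 3)
  v <- intensities(ph)
  # brute-force autocorrelation along X inside the LC texture
  block <- v[20:70, 20:70, 8:24]
  block <- block - mean(block)
  acf_x <- sapply(0:12, function(lag) {
    a <- block[1:(51 - lag), , ]; b <- block[(1 + lag):51, , ]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  })
  len <- which(acf_x < exp(-1))[1] - 1   # first lag below 1/e
  expect_gte(len, 2)
  expect_lte(len, 10)
})

test_that("deformations evaluate to exact analytic displacements", {
  co <- rbind(c(0, 0, 0), c(100, 50, 30), c(12.5, 400, 100))
  d <- deformation("translation", t = c(10, 10, 0), units = "voxel",
                   voxelSize = c(2.5, 2.5, 3))
  u <- evaluateDeformation(d, co)
  expect_equal(u, matrix(rep(c(25, 25, 0), each = 3), ncol = 3))

  dId <- deformation("uniformStrain", lambda = c(1, 1, 1))
  expect_equal(evaluateDeformation(dId, co), matrix(0, 3, 3))

  dz <- deformation("uniformStrain", lambda = c(1, 1, 0.95))
  expect_equal(evaluateDeformation(dz, cbind(0, 0, 100))[3], -5)

  # constant displacement gradient for uniform stretch
  ds <- deformation("uniformStrain", lambda = c(1.02, 0.99, 1), center = c(50, 50, 50))
  u2 <- evaluateDeformation(ds, co)
  expect_equal(u2[, 1], 0.02 * (co[, 1] - 50))
  expect_equal(u2[, 2], -0.01 * (co[, 2] - 50))

  expect_error(deformation("spiral"), "unknown deformation kind")
})

test_that("warping is exact for identity and integer translations", {
  ph <- smallPhantom(grid = c(64, 64, 24), seed = 5)
  v <- intensities(ph)
  wId <- warpVolume(ph, deformation("uniformStrain", lambda = c(1, 1, 1)))
  expect_equal(intensities(wId), v, tolerance = 1e-12)

  d <- deformation("translation", t = c(10, 10, 0), units = "voxel",
                   voxelSize = voxelSize(ph))
  w <- intensities(warpVolume(ph, d))
  # interior voxels equal an index-shifted copy exactly
  expect_equal(w[12:64, 12:64, ], v[2:54, 2:54, ], tolerance = 1e-12)
})

test_that("sequential warps match the composed deformation", {
  ph <- smallPhantom(grid = c(64, 64, 24), seed = 9, noise = 0)
  d1 <- deformation("uniformStrain", lambda = c(1.01, 1.005, 1),
                    center = c(78.75, 78.75, 34.5))
  d2 <- deformation("translation", t = c(5, -3, 2.5))
  w12 <- intensities(warpVolume(warpVolume(ph, d1), d2))
  wc <- intensities(warpVolume(ph, composeDeformations(d1, d2)))
  interior <- list(10:55, 10:55, 5:20)
  expect_equal(w12[interior[[1]], interior[[2]], interior[[3]]],
               wc[interior[[1]], interior[[2]], interior[[3]]],
               tolerance = 0.02)
})

test_that("volume-preserving warps preserve mean interior intensity", {
  ph <- smallPhantom(grid = c(64, 64, 24), seed = 13, noise = 0)
  # rotation-free shear-less stretch with det = 1
  d <- deformation("uniformStrain", lambda = c(1.02, 1 / 1.02, 1),
                   center = c(78.75, 78.75, 34.5))
  w <- intensities(warpVolume(ph, d))
  v <- intensities(ph)
  interior <- list(8:57, 8:57, 4:21)
  mi <- mean(v[interior[[1]], interior[[2]], interior[[3]]])
  mw <- mean(w[interior[[1]], interior[[2]], interior[[3]]])
  expect_lt(abs(mw - mi) / mi, 0.01)
})

test_that("warp rejects non-invertible mappings and flags unmapped voxels", {
  ph <- smallPhantom(grid = c(48, 48, 16), seed = 2)
  bad <- deformation("polynomial", coef = list(
    UX = list(powers = rbind(c(1, 0, 0)), coef = -1.5),  # dUX/dX = -1.5
    UY = list(powers = rbind(c(0, 0, 0)), coef = 0),
    UZ = list(powers = rbind(c(0, 0, 0)), coef = 0)))
  expect_error(warpVolume(ph, bad), "Jacobian")

  d <- deformation("translation", t = c(12.5, 0, 0))
  w <- warpVolume(ph, d)
  out <- w@meta$outsideMask
  expect_true(all(out[1:5, , ]))
  expect_false(any(out[7:48, , ]))
})
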