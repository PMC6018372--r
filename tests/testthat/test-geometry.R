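# Ellipse fitting, region segmentation and regional summaries.

ellipsePoints <- function(center, a, b, angle, th) {
  ct <- cos(angle); st <- sin(angle)
  px <- a * cos(th); py <- b * sin(th)
  cbind(center[1] + ct * px - st * py, center[2] + st * px + ct * py)
}

test_that("exact ellipse points are recovered to 1e-6 relative", {
  truth <- list(center = c(850, 620), a = 760, b = 590, angle = 0.4)
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  e <- fitEllipse(ellipsePoints(truth$center, truth$a, truth$b, truth$angle, th))
  expect_equal(e$center, truth$center, tolerance = 1e-6)
  expect_equal(e$a, truth$a, tolerance = 1e-6)
  expect_equal(e$b, truth$b, tolerance = 1e-6)
  expect_equal(e$angle, truth$angle, tolerance = 1e-5)

  # circle: both semi-axes equal the radius
  ec <- fitEllipse(ellipsePoints(c(0, 0), 300, 300, 0, th))
  expect_equal(ec$a, 300, tolerance = 1e-6)
  expect_equal(ec$b, 300, tolerance = 1e-6)

  expect_error(fitEllipse(cbind(1:10, 2 * (1:10))), "collinear")
  expect_error(fitEllipse(cbind(1:4, c(2, 1, 4, 3))), "at least 6")
})

test_that("noisy boundary picks recover the center within 10 um", {
  truth <- list(center = c(800, 640), a = 750, b = 600, angle = 0.15)
  set.seed(77)
  errs <- replicate(20, {
    th <- runif(40, 0, 2 * pi)
    pts <- ellipsePoints(truth$center, truth$a, truth$b, truth$angle, th) +
      matrix(rnorm(80, sd = 5), ncol = 2)
    e <- fitEllipse(pts)
    sqrt(sum((e$center - truth$center)^2))
  })
  expect_lt(median(errs), 10)
})

test_that("segmentation partitions the grid into the expected labels", {
  ell <- list(center = c(800, 800), a = 700, b = 600, angle = 0)
  g <- seq(0, 1600, by = 10)
  geom <- segmentRegions(ell, c(800, 800), 200, g, g)
  lab <- geom@labels
  expect_equal(length(unique(as.vector(lab))), 10)  # all labels occur
  expect_equal(sum(table(lab)), length(g)^2)        # a partition
  lev <- lcstrain:::lcRegionLevels()
  # node at the CRAV center is CRAV
  i0 <- which(g == 800)
  expect_equal(lev[lab[i0, i0]], "CRAV")
  # nasal toward +X for a right eye, superior toward +Y
  expect_equal(lev[lab[which(g == 1300), i0]], "peripheral.N")
  expect_equal(lev[lab[i0, which(g == 1300)]], "peripheral.S")
  # left eye mirrors nasal/temporal but not superior/inferior
  geomOS <- segmentRegions(ell, c(800, 800), 200, g, g, eye = "OS")
  expect_equal(lev[geomOS@labels[which(g == 1300), i0]], "peripheral.T")
  expect_equal(lev[geomOS@labels[i0, which(g == 1300)]], "peripheral.S")

  expect_error(segmentRegions(ell, c(800, 800), 650, g, g), "crosses")
})

test_that("rotating the geometry by 90 degrees permutes the quadrants", {
  ell <- list(center = c(0, 0), a = 650, b = 500, angle = 0)
  ell90 <- list(center = c(0, 0), a = 650, b = 500, angle = pi / 2)
  g <- seq(-700, 700, by = 20)
  geom <- segmentRegions(ell, c(0, 0), 200, g, g)
  geom90 <- segmentRegions(ell90, c(0, 0), 200, g, g)
  lev <- lcstrain:::lcRegionLevels()
  # the node at (x, y) in the rotated geometry matches (y, -x) in the
  # original with quadrants permuted N->S->T->I->N (90 degree rotation)
  perm <- c(background = "background", CRAV = "CRAV",
            central.N = "central.S", central.S = "central.T",
            central.T = "central.I", central.I = "central.N",
            peripheral.N = "peripheral.S", peripheral.S = "peripheral.T",
            peripheral.T = "peripheral.I", peripheral.I = "peripheral.N")
  iy <- match(0, g)
  for (xq in c(-480, -240, 240, 480)) {
    ix <- match(xq, g)
    orig <- lev[geom@labels[ix, iy]]
    rot <- lev[geom90@labels[iy, ix]]   # point rotated by +90 degrees
    expect_equal(rot, unname(perm[orig]))
  }
})

test_that("area fractions of a circular geometry match the annulus formulas", {
  R <- 600; r0 <- 200
  ell <- list(center = c(0, 0), a = R, b = R, angle = 0)
  g <- seq(-R - 5, R + 5, by = 1)      # 1 um grid
  geom <- segmentRegions(ell, c(0, 0), r0, g, g)
  lev <- lcstrain:::lcRegionLevels()
  counts <- table(factor(lev[geom@labels], levels = lev))
  mid <- (R + r0) / 2
  fCrav <- pi * r0^2
  fCentral <- pi * (mid^2 - r0^2)
  fPeripheral <- pi * (R^2 - mid^2)
  expect_equal(as.numeric(counts["CRAV"]), fCrav, tolerance = 0.005)
  expect_equal(sum(counts[grep("central", names(counts))]), fCentral,
               tolerance = 0.005)
  expect_equal(sum(counts[grep("peripheral", names(counts))]), fPeripheral,
               tolerance = 0.005)
  # spec ratio check: central/peripheral band areas
  expect_equal(sum(counts[grep("central", names(counts))]) /
               sum(counts[grep("peripheral", names(counts))]),
               ((R + r0)^2 / 4 - r0^2) / (R^2 - (R + r0)^2 / 4),
               tolerance = 0.005)
})

test_that("regional averages use magnitudes and drop empty regions", {
  ell <- list(center = c(0, 0), a = 650, b = 500, angle = 0)
  g <- seq(-700, 700, by = 20)
  geom <- segmentRegions(ell, c(0, 0), 200, g, g)
  lev <- lcstrain:::lcRegionLevels()

  m <- matrix(0.031, length(g), length(g))
  r <- regionalAverageMagnitude(m, geom)
  expect_equal(length(r), 8)
  expect_true(all(abs(r - 0.031) < 1e-12))
  r2 <- regionalAverageMagnitude(-m, geom)
  expect_equal(r2, r)

  # half +c / half -c in one region: magnitude c, signed mean 0
  m3 <- matrix(NA_real_, length(g), length(g))
  sel <- which(geom@labels == match("peripheral.N", lev))
  m3[sel[seq_along(sel) %% 2 == 0]] <- 0.02
  m3[sel[seq_along(sel) %% 2 == 1]] <- -0.02
  r3 <- regionalAverageMagnitude(m3, geom)
  expect_equal(unname(r3["peripheral.N"]), 0.02)
  expect_equal(names(r3), "peripheral.N")      # other regions empty, omitted
  expect_lt(abs(mean(m3[sel])), 0.021)         # signed mean near 0 by design

  # permutation invariance of node ordering is inherent (mean over sets)
  expect_error(regionalAverageMagnitude(matrix(NA_real_, length(g), length(g)),
                                        geom), "no region")
})
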