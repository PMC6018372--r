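# Exact signed-rank test, GEE with exchangeable correlation, paired table.

test_that("exact Wilcoxon p-values match known configurations", {
  # six same-sign differences: p = 2/64
  r <- wilcoxonSignedRankExact(c(-3, -1, -4, -2, -6, -5))
  expect_equal(r$p.value, 0.03125)
  expect_equal(format(round(r$p.value, 2)), "0.03")
  expect_equal(r$n, 6)

  # antisymmetric pair
  expect_equal(wilcoxonSignedRankExact(c(1, -1))$p.value, 1)

  # zeros dropped
  r0 <- wilcoxonSignedRankExact(c(0, 0, 2, 3, 1, 4, 5, 6))
  expect_equal(r0$n, 6)
  expect_equal(r0$p.value, 0.03125)

  expect_warning(rz <- wilcoxonSignedRankExact(c(0, 0, 0)), "zero")
  expect_equal(rz$p.value, 1)
})

test_that("exact p matches brute-force enumeration at n = 8, ties included", {
  set.seed(91)
  bruteForce <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W <- signs %*% r
    pLo <- mean(W <= v + 1e-9)
    pHi <- mean(W >= v - 1e-9)
    min(1, 2 * min(pLo, pHi))
  }
  for (k in 1:6) {
    d <- round(rnorm(8), if (k <= 3) 0 else 2)   # first cases force ties
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxonSignedRankExact(d)$p.value, bruteForce(d),
                 info = paste("case", k))
  }
})

test_that("exact p is invariant to monotone rescaling of differences", {
  d <- c(-2.3, 1.1, -0.4, -3.7, 2.2, -1.8, -0.9)
  p1 <- wilcoxonSignedRankExact(d)$p.value
  p2 <- wilcoxonSignedRankExact(1000 * d)$p.value
  p3 <- wilcoxonSignedRankExact(sign(d) * abs(d)^3)$p.value
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("GEE with rho = 0 and singleton clusters reduces to OLS", {
  set.seed(92)
  n <- 40
  d <- data.frame(y = rnorm(n), x = rnorm(n), id = seq_len(n))
  g <- fitGeeExchangeable(y ~ x, d, d$id, rho = 0)
  o <- lm(y ~ x, d)
  expect_equal(unname(g$coefficients), unname(coef(o)), tolerance = 1e-8)
})

test_that("robust standard errors match a direct matrix oracle", {
  set.seed(93)
  nc <- 12; m <- 4
  id <- rep(seq_len(nc), each = m)
  x <- rep(c(0, 1), length.out = nc)[id]   # balanced cluster-level contrast
  b <- rnorm(nc, sd = 0.5)[id]             # random cluster effects
  y <- 1 + 0.8 * x + b + rnorm(nc * m, sd = 0.3)
  d <- data.frame(y = y, x = x, id = id)
  g <- fitGeeExchangeable(y ~ x, d, d$id)

  # oracle: assemble the sandwich directly from full matrices
  X <- cbind(1, x)
  rho <- g$rho
  Bm <- matrix(0, 2, 2); Mm <- matrix(0, 2, 2)
  e <- y - X %*% g$coefficients
  for (i in seq_len(nc)) {
    ix <- which(id == i)
    Ri <- matrix(rho, m, m); diag(Ri) <- 1
    Wi <- solve(Ri)
    Xi <- X[ix, ]; ei <- e[ix]
    Bm <- Bm + t(Xi) %*% Wi %*% Xi
    s <- t(Xi) %*% Wi %*% ei
    Mm <- Mm + s %*% t(s)
  }
  Vm <- solve(Bm) %*% Mm %*% solve(Bm)
  expect_equal(unname(g$robust.se), unname(sqrt(diag(Vm))), tolerance = 1e-8)
})

test_that("GEE recovers a known slope within 3 robust SEs in >= 95% of runs", {
  set.seed(94)
  hits <- replicate(100, {
    nc <- 200; m <- 4
    id <- rep(seq_len(nc), each = m)
    x <- rnorm(nc * m)
    u <- rnorm(nc)[id]                        # exchangeable rho ~ 0.3
    y <- 0.5 * x + sqrt(0.3) * u + sqrt(0.7) * rnorm(nc * m)
    g <- fitGeeExchangeable(y ~ x, data.frame(y, x), id)
    abs(g$coefficients["x"] - 0.5) <= 3 * g$robust.se["x"]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the paired table joins states, drops unmatched regions, sorts stably", {
  regions <- lcstrain:::lcRegionLevels()[-(1:2)]
  mk <- function(specs, drop = NULL) {
    d <- expand.grid(specimen = specs, region = regions, measure = c("EXX", "EMAX"),
                     pressurePair = "5-45", stringsAsFactors = FALSE)
    d$value <- seq_len(nrow(d)) / 1000
    if (!is.null(drop)) d <- d[!(d$specimen == drop$s & d$region %in% drop$r), ]
    d
  }
  specs <- sprintf("S%d", 1:6)
  meta <- data.frame(specimen = specs,
                     ageGroup = rep(c("middle", "older"), c(2, 4)))
  full <- buildPairedTable(mk(specs), mk(specs), meta)
  expect_equal(nrow(full), 6 * 8 * 2)
  expect_equal(sum(full$measure == "EXX"), 48)

  dropped <- suppressMessages(buildPairedTable(
    mk(specs), mk(specs, drop = list(s = "S6", r = regions[1:3])), meta))
  expect_equal(sum(dropped$measure == "EXX"), 45)

  # input row order must not matter
  shuf <- mk(specs)[sample(48 * 2), ]
  reshuffled <- buildPairedTable(shuf, mk(specs), meta)
  expect_equal(reshuffled, full)

  expect_error(buildPairedTable(mk(specs[1:5]), mk(specs), meta), "differ")
  expect_true(all(full$location %in% c("central", "peripheral")))
  expect_true(all(full$quadrant %in% c("S", "I", "T", "N")))
})

test_that("the four regional GEE models run on a synthetic paired table", {
  set.seed(95)
  regions <- lcstrain:::lcRegionLevels()[-(1:2)]
  specs <- sprintf("S%d", 1:6)
  d <- expand.grid(specimen = specs, region = regions,
                   measure = "EMAX", pressurePair = "5-45",
                   stringsAsFactors = FALSE)
  d$value <- 0.03 + rnorm(nrow(d), sd = 0.004)
  after <- d
  after$value <- d$value - 0.2 * d$value + rnorm(nrow(d), sd = 0.001)
  meta <- data.frame(specimen = specs,
                     ageGroup = rep(c("middle", "older"), c(2, 4)))
  tab <- buildPairedTable(d, after, meta)
  fits <- geeStrainModels(tab, "EMAX", "5-45")
  expect_named(fits, c("change", "baseline", "location", "age"))
  expect_equal(fits$change$nClusters, 6)
  # mean change is negative and detected
  expect_lt(fits$change$coefficients[1], 0)
  expect_lt(fits$change$p.value[1], 0.05)
  # change ~ baseline slope is negative by construction (-0.2 per unit)
  expect_lt(fits$baseline$coefficients["valueBefore"], 0)
})
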