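# Paired specimen/regional statistics: exact Wilcoxon signed rank and
# GEE linear models with exchangeable working correlation.

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided exact test by full enumeration of the null distribution of the
#' positive-rank sum over all 2^n sign assignments (dynamic-programming
#' convolution over the doubled mid-ranks, equivalent to enumeration and
#' valid in the presence of ties). Zero differences are dropped, per the
#' usual convention; tied absolute differences receive mid-ranks.
#'
#' @param x numeric vector of paired differences, or first sample.
#' @param y optional second sample; differences are x - y.
#' @return list of class \code{"lcTest"}: statistic (positive-rank sum V),
#'   p.value (two-sided exact), n (nonzero differences), method.
#' @export
wilcoxonSignedRankExact <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(structure(list(statistic = NA_real_, p.value = 1, n = 0L,
                          method = "exact Wilcoxon signed rank"),
                     class = "lcTest"))
  }
  if (n > 20L) stopMsg("exact enumeration supported for n <= 20 (got %d)", n)
  r <- rank(abs(d))           # mid-ranks for ties
  r2 <- as.integer(round(2 * r))
  V <- sum(r[d > 0])
  v2 <- as.integer(round(2 * V))
  S <- sum(r2)
  # distribution of the doubled positive-rank sum under random signs
  p <- c(1, numeric(S))
  for (rr in r2) {
    shifted <- c(numeric(rr), p[seq_len(S + 1 - rr)])
    p <- (p + shifted) / 2
  }
  pLo <- sum(p[seq_len(v2 + 1L)])          # P(V <= v)
  pHi <- sum(p[(v2 + 1L):(S + 1L)])        # P(V >= v)
  structure(list(statistic = V, p.value = min(1, 2 * min(pLo, pHi)), n = n,
                 method = "exact Wilcoxon signed rank"),
            class = "lcTest")
}

#' @export
print.lcTest <- function(x, ...) {
  cat(sprintf("%s: V = %g, n = %d, two-sided P = %.4g\n",
              x$method, x$statistic, x$n, x$p.value))
  invisible(x)
}

#' GEE linear model with exchangeable working correlation
#'
#' Gaussian generalized estimating equations with identity link,
#' compound-symmetry (exchangeable) working correlation across the repeated
#' regional measurements of each cluster (eye), and robust sandwich
#' standard errors. The working correlation is estimated by the usual
#' moment estimator unless fixed via \code{rho}.
#'
#' @param formula model formula.
#' @param data data.frame of observations.
#' @param id cluster identifier: a vector, or the name of a column of
#'   \code{data}.
#' @param rho optional fixed working correlation (e.g. 0 for independence).
#' @param maxit,tol iteration controls.
#' @return list of class \code{"lcGee"}: coefficients, robust.se, vcov,
#'   rho, phi, nClusters, z, p.value, converged.
#' @export
fitGeeExchangeable <- function(formula, data, id, rho = NULL, maxit = 50,
                               tol = 1e-10) {
  if (is.character(id) && length(id) == 1L) id <- data[[id]]
  if (length(id) != nrow(data))
    stopMsg("id must have one entry per row of data")
  mf <- model.frame(formula, data)
  y <- as.numeric(model.response(mf))
  X <- model.matrix(formula, mf)
  dropped <- attr(mf, "na.action")
  if (!is.null(dropped)) id <- id[-as.integer(dropped)]
  id <- factor(id)
  if (nlevels(id) < 2L) stopMsg("GEE requires at least 2 clusters")
  if (qr(X)$rank < ncol(X)) stopMsg("design matrix is not full rank")
  idx <- split(seq_along(y), id)
  p <- ncol(X)
  N <- length(y)
  maxm <- max(lengths(idx))

  beta <- qr.coef(qr(X), y)     # OLS start
  estRho <- is.null(rho)
  rhoHat <- if (estRho) 0 else rho
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    e <- y - X %*% beta
    phi <- sum(e^2) / (N - p)
    if (estRho) {
      num <- 0; den <- 0
      for (ix in idx) {
        ei <- e[ix]; m <- length(ei)
        if (m > 1) {
          num <- num + (sum(ei)^2 - sum(ei^2))
          den <- den + m * (m - 1)
        }
      }
      rhoHat <- if (den > p) (num / phi) / (den - p) else 0
      lo <- if (maxm > 1) -1 / (maxm - 1) + 1e-6 else 0
      rhoHat <- max(lo, min(0.99, rhoHat))
    }
    A <- matrix(0, p, p); b <- numeric(p)
    for (ix in idx) {
      Xi <- X[ix, , drop = FALSE]; yi <- y[ix]; m <- length(ix)
      # closed-form inverse of the exchangeable correlation matrix
      c1 <- 1 / (1 - rhoHat)
      c2 <- -rhoHat / ((1 - rhoHat) * (1 + (m - 1) * rhoHat))
      WX <- c1 * Xi + c2 * matrix(colSums(Xi), m, p, byrow = TRUE)
      Wy <- c1 * yi + c2 * sum(yi)
      A <- A + crossprod(Xi, WX)
      b <- b + crossprod(Xi, Wy)
    }
    betaNew <- solve(A, b)
    if (max(abs(betaNew - beta)) < tol) {
      beta <- betaNew
      converged <- TRUE
      break
    }
    beta <- betaNew
  }
  if (!converged && maxit > 1)
    stopMsg("GEE did not converge after %d iterations (last max step %.3g)",
            maxit, max(abs(betaNew - beta)))
  # sandwich covariance
  e <- y - X %*% beta
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in idx) {
    Xi <- X[ix, , drop = FALSE]; ei <- e[ix]; m <- length(ix)
    c1 <- 1 / (1 - rhoHat)
    c2 <- -rhoHat / ((1 - rhoHat) * (1 + (m - 1) * rhoHat))
    WX <- c1 * Xi + c2 * matrix(colSums(Xi), m, p, byrow = TRUE)
    We <- c1 * ei + c2 * sum(ei)
    B <- B + crossprod(Xi, WX)
    s <- crossprod(Xi, We)
    M <- M + s %*% t(s)
  }
  Binv <- solve(B)
  V <- Binv %*% M %*% Binv
  se <- sqrt(diag(V))
  z <- as.numeric(beta) / se
  structure(list(coefficients = setNames(as.numeric(beta), colnames(X)),
                 robust.se = setNames(se, colnames(X)), vcov = V,
                 rho = rhoHat, phi = sum(e^2) / (N - p),
                 nClusters = length(idx), z = z,
                 p.value = setNames(2 * pnorm(-abs(z)), colnames(X)),
                 converged = converged, formula = formula),
            class = "lcGee")
}

#' @export
print.lcGee <- function(x, ...) {
  cat(sprintf("GEE (exchangeable, %d clusters, rho = %.3f)\n",
              x$nClusters, x$rho))
  print(data.frame(estimate = x$coefficients, robust.se = x$robust.se,
                   z = x$z, p = x$p.value))
  invisible(x)
}

#' Build the paired regional strain table
#'
#' Joins before- and after-treatment regional strain summaries by specimen,
#' region, measure and pressure pair; regions invalid in either state are
#' dropped (with a message), mirroring the omission of uncorrelatable
#' regions. Adds location (central/peripheral), quadrant and age-group
#' covariates.
#'
#' @param before,after data.frames with columns specimen, region, measure,
#'   pressurePair, value.
#' @param metadata data.frame with columns specimen, ageGroup.
#' @return data.frame with one row per specimen x region x measure x
#'   pressure pair: valueBefore, valueAfter, change (after - before),
#'   location, quadrant, ageGroup, canonically sorted.
#' @export
buildPairedTable <- function(before, after, metadata) {
  need <- c("specimen", "region", "measure", "pressurePair", "value")
  stopifnot(all(need %in% names(before)), all(need %in% names(after)))
  if (!setequal(unique(before$specimen), unique(after$specimen)))
    stopMsg("specimens differ between states: %s",
            paste(union(setdiff(unique(before$specimen), unique(after$specimen)),
                        setdiff(unique(after$specimen), unique(before$specimen))),
                  collapse = ", "))
  tab <- merge(before, after,
               by = c("specimen", "region", "measure", "pressurePair"),
               suffixes = c("Before", "After"))
  nBefore <- nrow(before); nJoined <- nrow(tab)
  if (nJoined < max(nBefore, nrow(after)))
    message(sprintf("dropped %d unmatched regional measures",
                    max(nBefore, nrow(after)) - nJoined))
  tab$change <- tab$valueAfter - tab$valueBefore
  parts <- strsplit(as.character(tab$region), ".", fixed = TRUE)
  tab$location <- vapply(parts, `[`, "", 1L)
  tab$quadrant <- vapply(parts, `[`, "", 2L)
  tab <- merge(tab, metadata[, c("specimen", "ageGroup")], by = "specimen")
  ord <- order(tab$measure, tab$pressurePair, tab$specimen, tab$region)
  tab <- tab[ord, c("specimen", "region", "location", "quadrant", "measure",
                    "pressurePair", "valueBefore", "valueAfter", "change",
                    "ageGroup")]
  rownames(tab) <- NULL
  tab
}

#' Fit the four regional GEE models
#'
#' For one strain measure and pressure pair, fits the four GEE linear
#' models on the regional change in average strain magnitude, clustering by
#' specimen: (1) intercept only (mean change), (2) change ~ baseline
#' magnitude, (3) change ~ location (central/peripheral), (4) change ~
#' age group.
#'
#' @param table paired table from \code{\link{buildPairedTable}}.
#' @param measure strain measure to model (e.g. "EMAX").
#' @param pressurePair pressure pair to model (e.g. "5-45").
#' @return Named list of \code{"lcGee"} fits.
#' @export
geeStrainModels <- function(table, measure, pressurePair) {
  d <- table[table$measure == measure & table$pressurePair == pressurePair, ]
  if (!nrow(d)) stopMsg("no rows for measure %s, pair %s", measure, pressurePair)
  fitIfVaries <- function(form, covariate = NULL) {
    if (!is.null(covariate) && length(unique(d[[covariate]])) < 2) return(NULL)
    fitGeeExchangeable(form, d, d$specimen)
  }
  list(change = fitIfVaries(change ~ 1),
       baseline = fitIfVaries(change ~ valueBefore),
       location = fitIfVaries(change ~ location, "location"),
       age = fitIfVaries(change ~ ageGroup, "ageGroup"))
}
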