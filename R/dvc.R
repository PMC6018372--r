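#' DVC engine configuration
#'
#' Settings for the coarse-to-fine FFT-based iterative digital volume
#' correlation. Subset sizes halve along the schedule; each level warps the
#' deformed volume by the current displacement estimate, correlates subsets
#' against the reference, and accumulates the residual offsets.
#'
#' @param subsetSchedule strictly decreasing subset edge lengths in voxels
#'   (coarse to fine; default 64, 32, 16).
#' @param overlap subset overlap fraction in [0, 1) used to place
#'   correlation windows at the coarse levels (default 0.5).
#' @param peakMethod subpixel peak localization: "gaussian" (3-point log
#'   fit per axis, default) or "parabolic".
#' @param qualityThreshold minimum peak normalized correlation coefficient
#'   for a node to be considered valid (default 0.25).
#' @param maxIterations maximum correlation passes per subset level.
#' @param tol convergence tolerance on the median residual update (voxels).
#' @param nodeStep integer(3) node spacing of the output displacement grid
#'   in voxels (default 8, 8, 4: half the finest subset in-plane, quarter
#'   axially so short stacks retain enough planes for degree-6 smoothing).
#' @param minValidFraction minimum fraction of valid nodes; below this the
#'   correlation is reported as failed.
#' @param maxOutOfFrame maximum fraction of a subset window that may come
#'   from outside the deformed volume's field of view (fill) before the
#'   node is masked invalid.
#' @param minPeakSharpness minimum per-axis drop of the correlation peak
#'   relative to its immediate neighbours; a flat peak along an axis means
#'   the texture does not constrain that displacement component (e.g.
#'   depth-invariant regions), and the node is masked.
#' @param medianFilter apply the normalized-median outlier test (residual
#'   against the 3x3x3 neighbour median, normalized by the local residual
#'   level) to the final field.
#' @param medianThreshold normalized-residual cutoff for the outlier test.
#' @return A list of class \code{"lcDvcConfig"}.
#' @export
dvcConfig <- function(subsetSchedule = c(64, 32, 16), overlap = 0.5,
                      peakMethod = c("gaussian", "parabolic"),
                      qualityThreshold = 0.25, maxIterations = 4,
                      tol = 0.02, nodeStep = c(8, 8, 4),
                      minValidFraction = 0.25, maxOutOfFrame = 0.05,
                      minPeakSharpness = 0.01, medianFilter = TRUE,
                      medianThreshold = 2) {
  peakMethod <- match.arg(peakMethod)
  if (any(diff(subsetSchedule) >= 0))
    stopMsg("subsetSchedule must be strictly decreasing")
  if (overlap < 0 || overlap >= 1) stopMsg("overlap must lie in [0, 1)")
  if (qualityThreshold <= 0 || qualityThreshold >= 1)
    stopMsg("qualityThreshold must lie in (0, 1)")
  structure(list(subsetSchedule = as.integer(subsetSchedule),
                 overlap = overlap, peakMethod = peakMethod,
                 qualityThreshold = qualityThreshold,
                 maxIterations = as.integer(maxIterations), tol = tol,
                 nodeStep = as.integer(nodeStep),
                 minValidFraction = minValidFraction,
                 maxOutOfFrame = maxOutOfFrame,
                 minPeakSharpness = minPeakSharpness,
                 medianFilter = medianFilter,
                 medianThreshold = medianThreshold),
            class = "lcDvcConfig")
}

#' Correlate two subsets by normalized FFT cross-correlation
#'
#' Computes the integer offset maximizing the (circular) normalized
#' cross-correlation between two equally sized subvolumes, refined to
#' subvoxel precision by a per-axis 3-point Gaussian (or parabolic) fit
#' around the peak. The offset is the displacement of the deformed subset's
#' content relative to the reference.
#'
#' @param refSubset,defSubset numeric 3D arrays of identical dimensions.
#' @param peakMethod "gaussian" or "parabolic".
#' @return list(offset = numeric(3) in voxels, quality = peak normalized
#'   correlation in [-1, 1], valid = logical). A zero-variance subset is
#'   flagged invalid rather than raising an error.
#' @export
correlateSubset <- function(refSubset, defSubset,
                            peakMethod = c("gaussian", "parabolic")) {
  peakMethod <- match.arg(peakMethod)
  stopifnot(identical(dim(refSubset), dim(defSubset)))
  a0 <- refSubset - mean(refSubset)
  sda <- sqrt(mean(a0^2))
  if (sda < 1e-10)
    return(list(offset = rep(NA_real_, 3), quality = NA_real_, valid = FALSE))
  corrPeak(fft(a0), sda, defSubset, dim(refSubset), peakMethod)
}

# Inner kernel shared with the engine: FA = fft of demeaned reference
# subset, sda its RMS.
corrPeak <- function(FA, sda, defSubset, dm, peakMethod) {
  b0 <- defSubset - mean(defSubset)
  sdb <- sqrt(mean(b0^2))
  if (!is.finite(sdb) || sdb < 1e-10)
    return(list(offset = rep(NA_real_, 3), quality = NA_real_, valid = FALSE))
  n <- prod(dm)
  C <- Re(fft(Conj(FA) * fft(b0), inverse = TRUE)) / n
  C <- C / (n * sda * sdb)
  pk <- arrayInd(which.max(C), dm)
  c0 <- C[pk[1], pk[2], pk[3]]
  off <- numeric(3)
  sharp <- rep(Inf, 3)
  for (ax in 1:3) {
    if (dm[ax] == 1) { off[ax] <- 0; next }
    im <- pk; ip <- pk
    im[ax] <- ((pk[ax] - 2) %% dm[ax]) + 1
    ip[ax] <- (pk[ax] %% dm[ax]) + 1
    cm <- C[im[1], im[2], im[3]]
    cp <- C[ip[1], ip[2], ip[3]]
    sharp[ax] <- c0 - max(cm, cp)
    delta <- 0
    if (peakMethod == "gaussian" && cm > 0 && cp > 0 && c0 > 0 &&
        c0 >= cm && c0 >= cp) {
      den <- log(cm) + log(cp) - 2 * log(c0)
      if (den < 0) delta <- 0.5 * (log(cm) - log(cp)) / den
    } else {
      den <- cm + cp - 2 * c0
      if (den < 0) delta <- 0.5 * (cm - cp) / den
    }
    if (!is.finite(delta) || abs(delta) > 1) delta <- 0
    s <- pk[ax] - 1
    if (s > dm[ax] / 2) s <- s - dm[ax]
    off[ax] <- s + delta
  }
  list(offset = off, quality = max(-1, min(1, c0)), valid = TRUE,
       sharpness = min(sharp))
}

# Normalized-median outlier test (3x3x3 neighbourhood): residual of each
# node against the median of its valid neighbours, normalized by the median
# neighbour residual plus a noise floor (voxels). Returns a logical array
# marking outliers.
medianOutliers <- function(UX, UY, UZ, valid, threshold = 2, eps = 0.1) {
  m <- dim(valid)
  out <- array(FALSE, m)
  for (k in seq_len(m[3])) for (j in seq_len(m[2])) for (i in seq_len(m[1])) {
    if (!valid[i, j, k]) next
    ii <- max(1, i - 1):min(m[1], i + 1)
    jj <- max(1, j - 1):min(m[2], j + 1)
    kk <- max(1, k - 1):min(m[3], k + 1)
    nb <- valid[ii, jj, kk]
    nb[which(ii == i), which(jj == j), which(kk == k)] <- FALSE
    if (sum(nb) < 3) next
    r <- 0
    for (U in list(UX, UY, UZ)) {
      un <- U[ii, jj, kk][nb]
      med <- median(un)
      rm <- median(abs(un - med))
      r <- max(r, abs(U[i, j, k] - med) / (rm + eps))
    }
    if (r > threshold) out[i, j, k] <- TRUE
  }
  out
}

#' Run fast-Fourier iterative DVC between two volumes
#'
#' Coarse-to-fine subset correlation: at each level the deformed volume is
#' warped by the current displacement estimate, subsets are correlated
#' against the reference, and the residual offsets are accumulated until the
#' median update falls below tolerance or the pass budget is exhausted. The
#' output field lives on a regular node grid in the reference frame; nodes
#' with peak correlation below \code{qualityThreshold} or zero-variance
#' (dark) subsets are masked invalid. The focal-offset difference between
#' the two acquisitions (deformed minus reference) is added to the
#' anterior-posterior displacement.
#'
#' @param ref,deformed \linkS4class{ImageVolume}s of identical shape and
#'   voxel size.
#' @param cfg an \code{"lcDvcConfig"}.
#' @param verbose print per-level progress.
#' @return A \linkS4class{DisplacementField} (micrometres).
#' @export
runFidvc <- function(ref, deformed, cfg = dvcConfig(), verbose = FALSE) {
  stopifnot(is(ref, "ImageVolume"), is(deformed, "ImageVolume"))
  if (!identical(dim(ref@data), dim(deformed@data)))
    stopMsg("reference and deformed volumes must have identical dimensions")
  if (max(abs(ref@voxelSize - deformed@voxelSize)) > 1e-9)
    stopMsg("reference and deformed volumes must share voxel size")
  R <- ref@data; D <- deformed@data
  dm <- dim(R)
  vx <- ref@voxelSize
  bg <- as.numeric(quantile(D, 0.05))

  # per-level, per-axis subset sizes (clamped to the grid, kept even)
  mkSize <- function(s) {
    sz <- pmin(s, dm)
    sz - sz %% 2L
  }
  sizes <- lapply(cfg$subsetSchedule, mkSize)
  sizes <- sizes[!duplicated(sapply(sizes, paste, collapse = "x"))]
  L <- length(sizes)
  if (any(sizes[[L]] < 4))
    stopMsg("volume too small for the finest subset")

  szf <- sizes[[L]]
  fstep <- pmin(cfg$nodeStep, pmax(1L, dm - szf + 1L))
  # keep >= 7 axial planes when the stack allows (degree-6 smoothing support)
  if (dm[3] - szf[3] >= 6)
    fstep[3] <- min(fstep[3], max(1L, (dm[3] - szf[3]) %/% 6L))
  fstarts <- lapply(1:3, function(a) seq(1L, dm[a] - szf[a] + 1L, by = fstep[a]))
  fcent0 <- lapply(1:3, function(a) fstarts[[a]] - 1 + (szf[a] - 1) / 2)
  m <- vapply(fstarts, length, 1L)
  UX <- array(0, m); UY <- array(0, m); UZ <- array(0, m)  # voxel units
  Q <- array(NA_real_, m)
  SH <- array(NA_real_, m)

  for (l in seq_len(L)) {
    sz <- sizes[[l]]
    if (l < L) {
      step <- pmax(1L, as.integer(round(sz * (1 - cfg$overlap))))
      starts <- lapply(1:3, function(a) {
        s <- seq(1L, dm[a] - sz[a] + 1L, by = step[a])
        # cover the far edge so the node span does not shrink at coarse levels
        if (s[length(s)] < dm[a] - sz[a] + 1L) s <- c(s, dm[a] - sz[a] + 1L)
        s
      })
    } else {
      step <- fstep
      starts <- fstarts
    }
    cent0 <- lapply(1:3, function(a) starts[[a]] - 1 + (sz[a] - 1) / 2)
    ml <- vapply(starts, length, 1L)

    for (it in seq_len(cfg$maxIterations)) {
      O <- NULL
      if (max(abs(UX), abs(UY), abs(UZ)) == 0) {
        W <- D
      } else {
        ux <- cpp_upsample_field(UX, fcent0[[1]][1], fcent0[[2]][1], fcent0[[3]][1],
                                 fstep[1], fstep[2], fstep[3], dm[1], dm[2], dm[3])
        uy <- cpp_upsample_field(UY, fcent0[[1]][1], fcent0[[2]][1], fcent0[[3]][1],
                                 fstep[1], fstep[2], fstep[3], dm[1], dm[2], dm[3])
        uz <- cpp_upsample_field(UZ, fcent0[[1]][1], fcent0[[2]][1], fcent0[[3]][1],
                                 fstep[1], fstep[2], fstep[3], dm[1], dm[2], dm[3])
        wres <- cpp_warp_by_field(D, ux, uy, uz, bg)
        W <- wres$values
        O <- wres$outside
      }
      dx <- array(NA_real_, ml); dy <- array(NA_real_, ml); dz <- array(NA_real_, ml)
      ql <- array(NA_real_, ml)
      sl <- array(NA_real_, ml)
      for (k in seq_len(ml[3])) {
        ks <- starts[[3]][k]; ke <- ks + sz[3] - 1L
        for (j in seq_len(ml[2])) {
          js <- starts[[2]][j]; je <- js + sz[2] - 1L
          for (i in seq_len(ml[1])) {
            is <- starts[[1]][i]; ie <- is + sz[1] - 1L
            if (l == L && !is.null(O) &&
                mean(O[is:ie, js:je, ks:ke]) > cfg$maxOutOfFrame)
              next  # window partly left the deformed field of view
            a <- R[is:ie, js:je, ks:ke]
            a0 <- a - mean(a)
            sda <- sqrt(mean(a0 * a0))
            if (sda < 1e-10) next
            res <- corrPeak(fft(a0), sda, W[is:ie, js:je, ks:ke], sz,
                            cfg$peakMethod)
            if (!res$valid) next
            if (any(abs(res$offset) > sz / 3)) next  # implausible jump
            dx[i, j, k] <- res$offset[1]
            dy[i, j, k] <- res$offset[2]
            dz[i, j, k] <- res$offset[3]
            ql[i, j, k] <- res$quality
            sl[i, j, k] <- res$sharpness
          }
        }
      }
      ok <- !is.na(dx)
      if (!any(ok))
        stopMsg("correlation failure: no correlatable subsets at level %d", l)
      upd <- median(sqrt(dx[ok]^2 + dy[ok]^2 + dz[ok]^2))
      dx[!ok] <- 0; dy[!ok] <- 0; dz[!ok] <- 0
      # interpolate the residual from the level grid onto the output grid
      addResidual <- function(res) {
        if (identical(as.integer(ml), as.integer(m))) return(res)
        q <- expand.grid(
          x = pmin(pmax((fcent0[[1]] - cent0[[1]][1]) / step[1], 0), ml[1] - 1),
          y = pmin(pmax((fcent0[[2]] - cent0[[2]][1]) / step[2], 0), ml[2] - 1),
          z = pmin(pmax((fcent0[[3]] - cent0[[3]][1]) / step[3], 0), ml[3] - 1))
        out <- cpp_interp3(res, q$x, q$y, q$z, 0, FALSE)$values
        dim(out) <- m
        out
      }
      UX <- UX + addResidual(dx)
      UY <- UY + addResidual(dy)
      UZ <- UZ + addResidual(dz)
      if (verbose)
        message(sprintf("  level %d (subset %s) pass %d: median update %.3f vox, %.0f%% correlatable",
                        l, paste(sz, collapse = "x"), it, upd, 100 * mean(ok)))
      if (l == L) { Q[] <- ql; SH[] <- sl }
      if (upd < cfg$tol) break
    }
  }

  valid <- !is.na(Q) & Q >= cfg$qualityThreshold &
    !is.na(SH) & SH >= cfg$minPeakSharpness
  if (isTRUE(cfg$medianFilter) && any(valid))
    valid <- valid & !medianOutliers(UX, UY, UZ, valid,
                                     threshold = cfg$medianThreshold)
  if (mean(valid) < cfg$minValidFraction)
    stopMsg("correlation failure: only %.0f%% of nodes valid (threshold %.0f%%)",
            100 * mean(valid), 100 * cfg$minValidFraction)
  ux <- UX * vx[1]; uy <- UY * vx[2]; uz <- UZ * vx[3]
  ux[!valid] <- NA_real_; uy[!valid] <- NA_real_; uz[!valid] <- NA_real_
  dz <- deformed@focalOffset - ref@focalOffset
  uz[valid] <- uz[valid] + dz
  new("DisplacementField",
      x = fcent0[[1]] * vx[1], y = fcent0[[2]] * vx[2], z = fcent0[[3]] * vx[3],
      UX = ux, UY = uy, UZ = uz, quality = Q,
      valid = array(valid, m), voxelSize = vx)
}

#' Add a focal-depth offset to the anterior-posterior displacements
#'
#' The recorded focal adjustment between acquisitions is added back to the
#' Z displacement component; X and Y are untouched.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param deltaFocal focal adjustment in micrometres.
#' @return The adjusted \linkS4class{DisplacementField}.
#' @export
applyFocalOffset <- function(field, deltaFocal) {
  stopifnot(is(field, "DisplacementField"))
  uz <- field@UZ
  uz[field@valid] <- uz[field@valid] + deltaFocal
  initialize(field, UZ = uz)
}
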