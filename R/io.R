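# File interchange: multi-page TIFF z-stacks with YAML sidecars, CSV node
# tables, JSON reports.

#' Write an image volume as a multi-page TIFF with YAML sidecar
#'
#' One 16-bit page per z-slice (intensities clamped to [0, 1]); the sidecar
#' (same path with extension .yaml) records voxel size, pressure, treatment,
#' focal offset, identifiers and any phantom geometry present in the
#' metadata.
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
writeImageVolume <- function(vol, path) {
  stopifnot(is(vol, "ImageVolume"))
  pages <- lapply(seq_len(dim(vol@data)[3]),
                  function(k) t(pmin(pmax(vol@data[, , k], 0), 1)))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(voxelSize = vol@voxelSize, pressure = vol@pressure,
               treatment = vol@treatment, focalOffset = vol@focalOffset,
               specimen = vol@specimen, eye = vol@eye)
  for (nm in c("ellipse", "cravCenter", "cravRadius"))
    if (!is.null(vol@meta[[nm]])) side[[nm]] <- vol@meta[[nm]]
  if (!is.null(vol@meta$boundaryPoints))
    side$boundaryPoints <- apply(vol@meta$boundaryPoints, 1, as.list)
  yaml::write_yaml(side, sidecarPath(path))
  invisible(path)
}

sidecarPath <- function(path) sub("\\.tiff?$", ".yaml", path)

#' Read an image volume written by \code{\link{writeImageVolume}}
#'
#' @param path TIFF path; the YAML sidecar is read when present.
#' @return An \linkS4class{ImageVolume}.
#' @export
readImageVolume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  v <- array(0, d)
  for (k in seq_along(pages)) v[, , k] <- t(pages[[k]])
  side <- list()
  sp <- sidecarPath(path)
  if (file.exists(sp)) side <- yaml::read_yaml(sp)
  imageVolume(v,
              voxelSize = if (!is.null(side$voxelSize)) unlist(side$voxelSize) else c(2.5, 2.5, 3),
              pressure = if (!is.null(side$pressure)) side$pressure else NA_real_,
              treatment = if (!is.null(side$treatment)) side$treatment else NA_character_,
              focalOffset = if (!is.null(side$focalOffset)) side$focalOffset else 0,
              specimen = if (!is.null(side$specimen)) side$specimen else "specimen",
              eye = if (!is.null(side$eye)) side$eye else "OD",
              meta = side[intersect(names(side),
                                    c("ellipse", "cravCenter", "cravRadius"))])
}

#' Export a displacement field as a CSV node table
#'
#' Long format: one row per node with coordinates (micrometres),
#' displacement components, correlation quality and validity.
#'
#' @param field a \linkS4class{DisplacementField}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeDisplacementField <- function(field, path) {
  stopifnot(is(field, "DisplacementField"))
  g <- expand.grid(x = field@x, y = field@y, z = field@z)
  df <- data.frame(g, UX = as.vector(field@UX), UY = as.vector(field@UY),
                   UZ = as.vector(field@UZ),
                   quality = as.vector(field@quality),
                   valid = as.vector(field@valid))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a displacement field CSV written by
#' \code{\link{writeDisplacementField}}
#'
#' @param path CSV path.
#' @param voxelSize voxel size of the source volumes (micrometres).
#' @return A \linkS4class{DisplacementField}.
#' @export
readDisplacementField <- function(path, voxelSize = c(2.5, 2.5, 3)) {
  df <- read.csv(path)
  x <- sort(unique(df$x)); y <- sort(unique(df$y)); z <- sort(unique(df$z))
  m <- c(length(x), length(y), length(z))
  ord <- order(match(df$z, z), match(df$y, y), match(df$x, x))
  df <- df[ord, ]
  mk <- function(v) array(v, m)
  new("DisplacementField", x = x, y = y, z = z,
      UX = mk(df$UX), UY = mk(df$UY), UZ = mk(df$UZ),
      quality = mk(df$quality), valid = mk(df$valid),
      voxelSize = as.numeric(voxelSize))
}

#' Export Z-averaged strain maps as CSV
#'
#' @param maps an \code{"lcStrainMaps"} from \code{\link{averageThroughZ}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeStrainMaps <- function(maps, path) {
  stopifnot(inherits(maps, "lcStrainMaps"))
  g <- expand.grid(x = maps$x, y = maps$y)
  df <- cbind(g, as.data.frame(lapply(maps$maps, as.vector)),
              nValid = as.vector(maps$nValid))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a region label map as TIFF plus JSON legend
#'
#' The TIFF stores label codes scaled to [0, 1]; the JSON legend maps codes
#' to region names and records the ellipse and CRAV parameters.
#'
#' @param geom an \linkS4class{LcGeometry}.
#' @param path output TIFF path; legend written alongside with extension
#'   .json.
#' @return \code{path}, invisibly.
#' @export
writeRegionMap <- function(geom, path) {
  stopifnot(is(geom, "LcGeometry"))
  tiff::writeTIFF(t(geom@labels / length(geom@labelLevels)), path,
                  bits.per.sample = 16L)
  legend <- list(levels = as.list(setNames(seq_along(geom@labelLevels),
                                           geom@labelLevels)),
                 scale = length(geom@labelLevels),
                 ellipse = geom@ellipse, cravCenter = geom@cravCenter,
                 cravRadius = geom@cravRadius)
  jsonlite::write_json(legend, sub("\\.tiff?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
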