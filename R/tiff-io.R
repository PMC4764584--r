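#' Read / write VolumeImage as multi-page TIFF
#'
#' Volumes are stored one z plane per page as 32-bit float samples. The
#' voxel spacing, z origin, channel label and intensity scaling are carried
#' in a JSON sidecar (\code{<path>.json}) written alongside the TIFF, so
#' spacing metadata survives a round trip; a missing sidecar falls back to
#' unit spacing.
#'
#' @param path file path of the TIFF.
#' @param vi a \linkS4class{VolumeImage}.
#' @return \code{readVolume} returns a \linkS4class{VolumeImage};
#'   \code{writeVolume} returns \code{path} invisibly.
#' @examples
#' f <- tempfile(fileext = ".tif")
#' writeVolume(VolumeImage(array(runif(64), c(4, 4, 4)), spacing = 0.3), f)
#' voxelSpacing(readVolume(f))
#' @export
writeVolume <- function(vi, path) {
  a <- imgData(vi)
  mx <- max(a); mn <- min(a)
  scale <- if (mx > mn) mx - mn else 1
  meta <- list(spacing = voxelSpacing(vi), zOrigin = vi@zOrigin,
               channel = channelName(vi), offset = mn, scale = scale)
  pages <- lapply(seq_len(dim(a)[3]), function(z)
    t((a[, , z] - mn) / scale))          # TIFF rows = y
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- list(spacing = c(1, 1, 1), zOrigin = 0, channel = "",
               offset = 0, scale = 1)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    parsed <- try(jsonlite::fromJSON(sidecar), silent = TRUE)
    if (!inherits(parsed, "try-error")) meta[names(parsed)] <- parsed
  }
  arr <- vapply(pages, function(p) t(as.matrix(p)),
                matrix(0, ncol(pages[[1]]), nrow(pages[[1]])))
  arr <- array(arr, dim = c(dim(arr)[1], dim(arr)[2], length(pages)))
  arr <- arr * meta$scale + meta$offset
  VolumeImage(arr, spacing = as.numeric(meta$spacing),
              channel = as.character(meta$channel),
              zOrigin = as.numeric(meta$zOrigin))
}
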