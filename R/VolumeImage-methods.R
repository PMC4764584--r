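#' Construct a VolumeImage
#'
#' @param data 3D numeric array (x, y, z).
#' @param spacing voxel size in µm along (x, y, z); scalar is recycled.
#' @param channel channel label.
#' @param zOrigin depth of the first plane (µm).
#' @return A \linkS4class{VolumeImage}.
#' @examples
#' vi <- VolumeImage(array(0, c(8, 8, 4)), spacing = 0.3, channel = "DAPI")
#' dim(imgData(vi))
#' @export
VolumeImage <- function(data, spacing = c(1, 1, 1), channel = "",
                        zOrigin = 0) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VolumeImage", data = data, spacing = as.numeric(spacing),
      channel = channel, zOrigin = as.numeric(zOrigin))
}

#' @rdname accessors
#' @export
setMethod("imgData", "VolumeImage", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VolumeImage", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("channelName", "VolumeImage", function(x) x@channel)

setMethod("show", "VolumeImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeImage '%s': %d x %d x %d voxels @ %.3g x %.3g x %.3g um\n",
              object@channel, d[1], d[2], d[3], object@spacing[1],
              object@spacing[2], object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g], z origin %.3g um\n",
              min(object@data), max(object@data), object@zOrigin))
})

# replace the array, keep the metadata
withData <- function(vi, data) {
  new("VolumeImage", data = data, spacing = vi@spacing, channel = vi@channel,
      zOrigin = vi@zOrigin)
}

setMethod("show", "NoiseModel", function(object) {
  if (object@failed) {
    cat("NoiseModel: calibration FAILED (degenerate input)\n")
  } else {
    cat(sprintf(
      "NoiseModel: alpha %.3g..%.3g a.u./photon over %d slab(s), beta %.3g\n",
      min(object@alpha), max(object@alpha), length(object@alpha),
      object@beta))
  }
})

setMethod("show", "ImageMetrics", function(object) {
  cat(sprintf("ImageMetrics (%s): MSE %.6g, CoC %.4f\n", object@region,
              object@mse, object@coc))
})

setMethod("show", "SurfacePair", function(object) {
  cat(sprintf("SurfacePair: %d x %d columns, refined: %s\n",
              nrow(object@ym1), ncol(object@ym1),
              if (length(object@y1)) "yes" else "no"))
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d triangles, volume %.4g um^3\n",
              nrow(object@vertices), nrow(object@triangles),
              meshVolume(object)))
})

setMethod("show", "NetworkGraph", function(object) {
  cat(sprintf("NetworkGraph: %d nodes, %d edges, total length %.4g um\n",
              nrow(object@nodes), nrow(object@edges),
              sum(object@edges$length)))
})

setMethod("show", "GroundTruthScene", function(object) {
  d <- dim(object@labels$nuclei)
  cat(sprintf(
    "GroundTruthScene: %d x %d x %d voxels @ %.3g um, %d nuclei, %d cells\n",
    d[1], d[2], d[3], object@spacing[1], nrow(object@tables$nuclei),
    nrow(object@tables$cells)))
})

#' @rdname accessors
#' @export
setMethod("sceneChannel", "GroundTruthScene", function(x, which) {
  stopifnot(which %in% names(x@labels))
  VolumeImage(x@labels[[which]] * 1.0, spacing = x@spacing, channel = which)
})
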