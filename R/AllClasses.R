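#' VolumeImage: a single-channel 3D image with voxel spacing
#'
#' Container for one channel of a confocal stack: a 3D numeric array plus the
#' voxel size in micrometres and the depth (z) of the first plane.
#'
#' @slot data 3D numeric array (x, y, z), intensities in arbitrary units.
#' @slot spacing numeric(3), voxel size in µm along (x, y, z); all > 0.
#' @slot channel character scalar channel label (e.g. "DAPI", "CD13").
#' @slot zOrigin depth of the first z plane in µm.
#' @export
setClass("VolumeImage",
  representation(data = "array", spacing = "numeric", channel = "character",
                 zOrigin = "numeric"),
  prototype(spacing = c(1, 1, 1), channel = "", zOrigin = 0))

setValidity("VolumeImage", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive values (µm)")
  TRUE
})

#' NoiseModel: depth-dependent Poisson noise calibration
#'
#' Photon-to-intensity conversion of a confocal channel, I = alpha * N + beta,
#' with the scaling factor alpha calibrated per depth slab (it grows with
#' imaging depth) and a global digitization offset beta. The variance
#' prediction is V(I) = alpha(z) * (I - beta).
#'
#' @slot alpha numeric, conversion coefficient (a.u./photon) per depth slab.
#' @slot slabCenters numeric, z centre of each slab (voxel units).
#' @slot beta numeric scalar offset (a.u.).
#' @slot slabHeight integer, z extent of the calibration slabs (voxels).
#' @slot failed logical flag: calibration failed (e.g. constant image).
#' @export
setClass("NoiseModel",
  representation(alpha = "numeric", slabCenters = "numeric", beta = "numeric",
                 slabHeight = "numeric", failed = "logical"),
  prototype(failed = FALSE))

setValidity("NoiseModel", function(object) {
  if (!object@failed && any(object@alpha <= 0))
    return("alpha values must be positive")
  if (length(object@alpha) != length(object@slabCenters))
    return("alpha and slabCenters lengths differ")
  TRUE
})

#' ImageMetrics: MSE and correlation between two volumes
#'
#' @slot mse mean squared error (>= 0).
#' @slot coc Pearson coefficient of correlation, in [-1, 1].
#' @slot region "global" or "vicinity" (metrics restricted to a mask).
#' @export
setClass("ImageMetrics",
  representation(mse = "numeric", coc = "numeric", region = "character"))

setValidity("ImageMetrics", function(object) {
  if (object@mse < 0) return("mse must be >= 0")
  if (abs(object@coc) > 1 + 1e-12) return("|coc| must be <= 1")
  TRUE
})

#' SurfacePair: measured and refined section surfaces
#'
#' Per x-y column heights (in voxel units) of the top (ym1/y1) and bottom
#' (ym2/y2) surface of a physical section. Measured fields come from
#' maximum-entropy thresholding; refined fields from the Bayesian
#' iterated-conditional-modes step.
#'
#' @slot ym1,ym2 measured top/bottom height matrices.
#' @slot y1,y2 refined top/bottom height matrices (may be empty before
#'   refinement).
#' @export
setClass("SurfacePair",
  representation(ym1 = "matrix", ym2 = "matrix", y1 = "matrix",
                 y2 = "matrix"))

setValidity("SurfacePair", function(object) {
  if (!all(dim(object@ym1) == dim(object@ym2)))
    return("ym1 and ym2 dimensions differ")
  if (length(object@y1) && any(object@y1 > object@y2))
    return("refined surfaces must satisfy y1 <= y2")
  TRUE
})

#' SurfacePrior: parameters of the section-surface posterior
#'
#' @slot s Cauchy likelihood scale (voxels), how far the true surface may sit
#'   from the measured one.
#' @slot sigma Gaussian scale of the section-thickness coupling (voxels).
#' @slot lam Laplace rate of the surface smoothness prior (1/voxel).
#' @slot tMad median absolute deviation of the section thickness (voxels).
#' @slot tMed median section thickness (voxels), the centre of the thickness
#'   coupling.
#' @slot flagged logical, TRUE when tMad had to be floored.
#' @export
setClass("SurfacePrior",
  representation(s = "numeric", sigma = "numeric", lam = "numeric",
                 tMad = "numeric", tMed = "numeric", flagged = "logical"),
  prototype(flagged = FALSE, tMed = 0))

setValidity("SurfacePrior", function(object) {
  if (object@s <= 0 || object@sigma <= 0 || object@lam <= 0)
    return("s, sigma and lam must be positive")
  TRUE
})

#' ThresholdField: local maximum-entropy threshold grid
#'
#' Kapur thresholds computed on overlapping cubes and tri-linearly
#' interpolated per voxel; at a cube centre the interpolated value equals
#' that cube's threshold.
#'
#' @slot thresholds 3D array of per-cube thresholds.
#' @slot centers list of cube-centre coordinates (voxel units) per axis.
#' @slot cube cube edge length in voxels.
#' @slot dim dimensions of the image the field was computed for.
#' @export
setClass("ThresholdField",
  representation(thresholds = "array", centers = "list", cube = "numeric",
                 dim = "integer"))

#' TriangleMesh: a closed triangle surface in physical coordinates
#'
#' @slot vertices n x 3 matrix of vertex coordinates (µm).
#' @slot triangles m x 3 integer matrix of vertex indices (1-based).
#' @slot flags named list of quality flags (e.g. borderCapped).
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", triangles = "matrix", flags = "list"),
  prototype(flags = list()))

setValidity("TriangleMesh", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@triangles) != 3L) return("triangles must be m x 3")
  if (nrow(object@triangles) &&
      max(object@triangles) > nrow(object@vertices))
    return("triangle index out of range")
  TRUE
})

#' NetworkGraph: skeletonized tubular network
#'
#' Centerline graph of a tubular structure: nodes carry positions (µm) and
#' local radii from the distance transform, edges carry polyline centerlines
#' with length and mean radius.
#'
#' @slot nodes data.frame (id, x, y, z, radius, degree).
#' @slot edges data.frame (from, to, length, meanRadius).
#' @slot polylines list of k x 3 matrices (µm), one per edge.
#' @slot graph the underlying igraph object.
#' @export
setClass("NetworkGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 polylines = "list", graph = "ANY"))

#' GroundTruthScene: synthetic 4-channel benchmark scene
#'
#' Ground-truth label volumes (bile canaliculi, sinusoids, nuclei, cell
#' borders), the cell partition, and the object tables the generator used
#' (tube centerlines and radii, nucleus centres/radii/multiplicity, cells).
#'
#' @slot labels named list of 3D arrays: bc, sinusoid (shell), sinusoidLumen,
#'   nuclei (integer labels), cells (integer labels), cellBorders.
#' @slot tables named list of data.frames: nuclei, cells; plus centerline
#'   lists for the two networks.
#' @slot spacing voxel size (µm).
#' @slot seed integer seed the scene was generated from.
#' @export
setClass("GroundTruthScene",
  representation(labels = "list", tables = "list", spacing = "numeric",
                 seed = "numeric"))

#' Ellipsoid: centre/shape-matrix form
#'
#' Ellipsoid \{p : (p - c)' E (p - c) <= 1\} with E symmetric positive
#' definite; semi-axes are 1/sqrt of the eigenvalues of E.
#'
#' @slot c centre (µm).
#' @slot E 3 x 3 symmetric positive-definite shape matrix (µm^-2).
#' @export
setClass("Ellipsoid", representation(c = "numeric", E = "matrix"))

setValidity("Ellipsoid", function(object) {
  if (length(object@c) != 3L) return("centre must be length 3")
  ev <- eigen(object@E, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return("E must be positive definite")
  TRUE
})

#' NucleusObject: a reconstructed (possibly multi-nuclear) DAPI structure
#'
#' @slot mesh TriangleMesh of the object.
#' @slot multiplicity "mono", "double" or "multi".
#' @slot dapiIntegral integral DAPI intensity inside the mesh (a.u.).
#' @slot seed position used to seed the object (µm), NA if none.
#' @export
setClass("NucleusObject",
  representation(mesh = "TriangleMesh", multiplicity = "character",
                 dapiIntegral = "numeric", seed = "numeric"),
  prototype(multiplicity = "mono", dapiIntegral = NA_real_,
            seed = c(NA_real_, NA_real_, NA_real_)))

#' BayesNet: discrete Bayesian-network classifier
#'
#' Nodes are the class variable plus equal-population-discretized features;
#' the structure is a DAG learned by the K2 algorithm and the conditional
#' probability tables use add-one smoothing.
#'
#' @slot nodes character vector of node names (class node first).
#' @slot parents named list: parents of each node.
#' @slot cpts named list of conditional probability tables.
#' @slot levels named list of discretization boundaries / class levels.
#' @export
setClass("BayesNet",
  representation(nodes = "character", parents = "list", cpts = "list",
                 levels = "list"))
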