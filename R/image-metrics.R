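#' Mean squared error and correlation between two volumes
#'
#' MSE = sum over the region Omega of (I_i - I*_i)^2 / |Omega|; CoC is the
#' Pearson correlation coefficient over the same region. Omega is the whole
#' image or an optional mask (e.g. the object vicinity).
#'
#' @param a,b \linkS4class{VolumeImage}s of identical dimensions.
#' @param mask optional logical array selecting the region Omega (non-empty).
#' @return An \linkS4class{ImageMetrics} object.
#' @examples
#' x <- VolumeImage(array(rnorm(8^3), c(8, 8, 8)))
#' imageMetrics(x, x)
#' @export
imageMetrics <- function(a, b, mask = NULL) {
  av <- imgData(a); bv <- imgData(b)
  if (!all(dim(av) == dim(bv))) stop("images must have the same shape")
  region <- "global"
  if (!is.null(mask)) {
    if (!any(mask)) stop("mask must be non-empty")
    av <- av[mask]; bv <- bv[mask]
    region <- "vicinity"
  }
  mse <- mean((as.numeric(av) - as.numeric(bv))^2)
  if (sd(av) == 0 || sd(bv) == 0)
    stop("coefficient of correlation undefined for zero-variance input")
  coc <- cor(as.numeric(av), as.numeric(bv))
  new("ImageMetrics", mse = mse, coc = coc, region = region)
}

#' Inflate a binary mask into its vicinity
#'
#' Morphological dilation by an isotropic ball of radius \code{inflate}
#' voxels; used to restrict image-quality metrics to the neighbourhood of the
#' structures of interest.
#'
#' @param labels logical (or 0/1) 3D array.
#' @param inflate dilation radius in voxels (>= 0); 0 returns the input.
#' @return logical array of the same shape.
#' @export
vicinityMask <- function(labels, inflate) {
  stopifnot(inflate >= 0)
  m <- array(as.logical(labels), dim = dim(labels))
  if (inflate == 0) return(m)
  dilateBall(m, inflate, spacing = c(1, 1, 1))
}
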