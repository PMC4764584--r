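# Internal voxel-level helpers shared across modules.

dim3 <- function(a) as.integer(dim(a))

# squared EDT to nearest TRUE voxel; spacing in µm (or voxels with spacing 1)
edtSq <- function(mask, spacing = c(1, 1, 1)) {
  d <- dim3(mask)
  array(.edt_sq(as.logical(mask), d, as.numeric(spacing)), dim = d)
}

# Euclidean distance to nearest TRUE voxel
edtDist <- function(mask, spacing = c(1, 1, 1)) sqrt(edtSq(mask, spacing))

# ball dilation/erosion; r in the units of `spacing`
dilateBall <- function(mask, r, spacing = c(1, 1, 1)) {
  if (r <= 0) return(mask)
  edtSq(mask, spacing) <= r^2 + 1e-9
}

erodeBall <- function(mask, r, spacing = c(1, 1, 1)) {
  if (r <= 0) return(mask)
  !(edtSq(!mask, spacing) <= r^2 + 1e-9)
}

openBall <- function(mask, r, spacing = c(1, 1, 1))
  dilateBall(erodeBall(mask, r, spacing), r, spacing)

closeBall <- function(mask, r, spacing = c(1, 1, 1))
  erodeBall(dilateBall(mask, r, spacing), r, spacing)

# fill interior cavities: background components not touching the border
fillHoles3d <- function(mask) {
  d <- dim3(mask)
  lab <- array(.label3d(!mask, d, 6L), dim = d)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0]
  mask | !(lab %in% c(0L, border))
}

labelComponents <- function(mask, connectivity = 26L) {
  d <- dim3(mask)
  array(.label3d(as.logical(mask), d, as.integer(connectivity)), dim = d)
}

# drop connected components smaller than minVoxels
sizeFilter <- function(mask, minVoxels, connectivity = 26L) {
  lab <- labelComponents(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab)
  keep <- which(sizes >= minVoxels)
  array(lab %in% keep, dim = dim(mask))
}

# separable Gaussian smoothing, sigma in voxels (per axis or scalar)
gaussSmooth <- function(a, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  d <- dim3(a)
  array(.gauss3d(as.numeric(a), d, as.numeric(sigma)), dim = d)
}

# voxel-centre coordinates (µm) of TRUE voxels / of indices
voxelCoords <- function(idx, dim, spacing) {
  if (is.array(idx) || is.logical(idx)) idx <- which(idx)
  co <- arrayInd(idx, dim)
  sweep(co - 1, 2, spacing, "*")
}

# trilinear sample at µm points -> voxel coords conversion included
sampleAt <- function(a, pts, spacing) {
  d <- dim3(a)
  vox <- sweep(pts, 2, spacing, "/")
  .trilinear_sample(as.numeric(a), d, vox)
}

# central-difference gradient magnitude of a volume
gradientMagnitude <- function(a, spacing = c(1, 1, 1)) {
  d <- dim(a)
  gx <- a; gy <- a; gz <- a
  gx[2:(d[1] - 1), , ] <- (a[3:d[1], , ] - a[1:(d[1] - 2), , ]) /
    (2 * spacing[1])
  gx[c(1, d[1]), , ] <- 0
  gy[, 2:(d[2] - 1), ] <- (a[, 3:d[2], ] - a[, 1:(d[2] - 2), ]) /
    (2 * spacing[2])
  gy[, c(1, d[2]), ] <- 0
  gz[, , 2:(d[3] - 1)] <- (a[, , 3:d[3]] - a[, , 1:(d[3] - 2)]) /
    (2 * spacing[3])
  gz[, , c(1, d[3])] <- 0
  sqrt(gx^2 + gy^2 + gz^2)
}

# histogram equalization to `levels` grey levels over the whole stack
equalizeHistogram <- function(a, levels = 256L) {
  r <- rank(a, ties.method = "average")
  array((r - 1) / (length(a) - 1) * (levels - 1), dim = dim(a))
}

# trilinear interpolation of a coarse grid (values at `centers`) onto 1..n
interpGridToVolume <- function(values, centers, outDim) {
  # interpolate along x, then y, then z using stats::approx with clamping
  interpAxis <- function(arr, cents, n, axis) {
    d <- dim(arr)
    xi <- seq_len(n)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    a2 <- aperm(arr, perm)
    m <- matrix(a2, nrow = d[axis])
    out <- apply(m, 2, function(v) {
      if (length(cents) == 1L) rep(v, n)
      else approx(cents, v, xout = xi, rule = 2)$y
    })
    d2 <- d[perm]; d2[1] <- n
    aperm(array(out, dim = d2), order(perm))
  }
  v <- interpAxis(values, centers[[1]], outDim[1], 1)
  v <- interpAxis(v, centers[[2]], outDim[2], 2)
  interpAxis(v, centers[[3]], outDim[3], 3)
}
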