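#' Triangle meshes from a binary segmentation
#'
#' Extracts a watertight triangle mesh per connected component of a binary
#' mask by marching tetrahedra (a tetrahedral decomposition of the marching
#' cubes grid, which avoids the ambiguous cube cases). The volume is
#' conceptually padded with background, so components touching the border are
#' capped at the border and flagged. Vertices are in physical (µm)
#' coordinates.
#'
#' @param mask logical 3D array.
#' @param spacing voxel size (µm), scalar or length 3.
#' @param minVoxels components smaller than this are skipped.
#' @param smoothIters Laplacian smoothing iterations applied to the extracted
#'   mesh (0 disables).
#' @return list of \linkS4class{TriangleMesh} (empty list for an empty mask).
#' @export
meshFromMask <- function(mask, spacing = c(1, 1, 1), minVoxels = 0L,
                         smoothIters = 2L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  d <- dim3(mask)
  if (!any(mask)) return(list())
  lab <- labelComponents(mask, 26L)
  nlab <- max(lab)
  out <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l)
    if (length(idx) < max(1L, minVoxels)) next
    co <- arrayInd(idx, d)
    lo <- pmax(apply(co, 2, min) - 2L, 1L)
    hi <- pmin(apply(co, 2, max) + 2L, d)
    sub <- array(FALSE, hi - lo + 1L)
    sub[sweep(co, 2, lo - 1L)] <- TRUE
    touches <- any(co == 1L) || any(sweep(co, 2, d, "-") == 0L)
    mt <- .march_tets(sub * 1.0, dim3(sub), 0.5)
    if (!nrow(mt$vertices)) next
    verts <- sweep(sweep(mt$vertices, 2, lo - 1L, "+"), 2, spacing, "*")
    m <- new("TriangleMesh", vertices = verts, triangles = mt$triangles,
             flags = list(borderCapped = touches, voxels = length(idx)))
    if (smoothIters > 0L) m <- smoothMesh(m, iters = smoothIters,
                                          lambda = 0.4)
    out[[length(out) + 1L]] <- m
  }
  out
}

# Taubin-style shrink-reduced Laplacian smoothing (lambda then slight inflate)
smoothMesh <- function(mesh, iters = 2L, lambda = 0.4) {
  V <- mesh@vertices
  edges <- meshEdgesDirected(mesh@triangles)
  for (i in seq_len(iters)) {
    V <- V + lambda * (neighborMean(V, edges) - V)
    V <- V - 0.38 * lambda * (neighborMean(V, edges) - V)
  }
  new("TriangleMesh", vertices = V, triangles = mesh@triangles,
      flags = mesh@flags)
}

#' @rdname accessors
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)

#' @rdname accessors
#' @export
setMethod("meshTriangles", "TriangleMesh", function(x) x@triangles)

#' @rdname accessors
#' @export
setMethod("meshVolume", "TriangleMesh", function(x)
  abs(signedMeshVolume(x@vertices, x@triangles)))

#' @rdname accessors
#' @export
setMethod("meshArea", "TriangleMesh", function(x)
  sum(triangleAreas(x@vertices, x@triangles)))

#' @rdname accessors
#' @export
setMethod("eulerCharacteristic", "TriangleMesh", function(x) {
  e <- rbind(x@triangles[, 1:2], x@triangles[, 2:3], x@triangles[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  ne <- nrow(unique(e))
  nrow(x@vertices) - ne + nrow(x@triangles)
})

#' Segment a stained structure with the local maximum-entropy field
#'
#' Thresholds a de-noised channel by the interpolated local maximum-entropy
#' threshold field and repairs staining holes by morphological closing
#' followed by opening.
#'
#' @param img de-noised \linkS4class{VolumeImage}.
#' @param field \linkS4class{ThresholdField} for this image (or a scalar
#'   threshold).
#' @param closing closing radius in voxels (0 disables).
#' @param opening opening radius in voxels (0 disables; openings thinner
#'   than the structures of interest remove speckle, but wipe out tubes
#'   thinner than the radius, so the default is off).
#' @param minVoxels minimum component size kept.
#' @return logical array mask.
#' @export
segmentStructure <- function(img, field, closing = 2, opening = 0,
                             minVoxels = 27L) {
  a <- imgData(img)
  thr <- if (is(field, "ThresholdField")) thresholdVolume(field) else field
  mask <- a > thr
  if (!any(mask)) return(mask)
  if (closing > 0) mask <- closeBall(mask, closing)
  if (opening > 0) mask <- openBall(mask, opening)
  if (minVoxels > 0L) mask <- sizeFilter(mask, minVoxels)
  mask
}

#' Tune mesh vertices to the intensity-gradient maximum
#'
#' Thresholded meshes of blurred structures are systematically swollen; the
#' true interface sits at the maximum of the intensity gradient. Each vertex
#' is moved along its normal to the gradient-magnitude maximum within
#' \code{search} µm (with parabolic sub-sample refinement), alternating with
#' Laplacian regularization to keep the mesh smooth.
#'
#' @param mesh \linkS4class{TriangleMesh} near the target interface.
#' @param img original (or de-noised) \linkS4class{VolumeImage}.
#' @param search half-width of the normal-line search (µm).
#' @param iters snap/smooth alternations.
#' @param lambda Laplacian regularization weight per iteration.
#' @param gradient optional precomputed gradient-magnitude volume (shared
#'   across many meshes of the same image).
#' @param promFactor vertices move only where the profile peak exceeds this
#'   multiple of the image's median gradient (the gradient noise floor).
#' @return the tuned \linkS4class{TriangleMesh}.
#' @export
tuneMeshToGradient <- function(mesh, img, search = 1.5, iters = 10L,
                               lambda = 0.4, gradient = NULL,
                               promFactor = 3) {
  a <- imgData(img)
  sp <- voxelSpacing(img)
  g <- if (is.null(gradient)) gradientMagnitude(a, sp) else gradient
  # vertices move only where the profile peak clears the image's gradient
  # noise floor; elsewhere the gradient carries no edge evidence
  minProm <- promFactor * median(g)
  V <- mesh@vertices
  tri <- mesh@triangles
  edges <- meshEdgesDirected(tri)
  step <- 0.25 * min(sp)
  offs <- seq(-search, search, by = step)
  maxMove <- 0.4 * min(sp)          # incremental motion avoids mesh folding
  d <- dim3(g)
  for (it in seq_len(iters)) {
    n <- vertexNormals(V, tri)
    shift <- .profile_peak(as.numeric(g), d, V, n, offs, sp, minProm)
    shift <- pmin(pmax(shift, -maxMove), maxMove)
    V <- V + shift * n
    # Taubin pair: smooth, then slightly inflate to counter shrinkage
    V <- V + lambda * (neighborMean(V, edges) - V)
    V <- V - 0.38 * lambda * (neighborMean(V, edges) - V)
    if (max(abs(shift)) < 0.02 * min(sp)) break
  }
  new("TriangleMesh", vertices = V, triangles = tri, flags = mesh@flags)
}

#' Inflate an active mesh until it reaches an intensity barrier
#'
#' Explicit active-mesh dynamics: each free vertex moves along its outward
#' normal under an inner pressure force, regularized by a uniform Laplacian
#' (rigidity). A vertex freezes when the intensity one step ahead reaches
#' \code{stopIntensity} (e.g. the actin cortex), when it would enter a
#' barrier mask, or when it would enter space claimed by a neighbouring mesh
#' (shared \code{occupancy} grid).
#'
#' @param seed starting \linkS4class{TriangleMesh} inside the target region.
#' @param img intensity \linkS4class{VolumeImage} providing the stopping
#'   cues.
#' @param pressure inner pressure (a.u.); 0 returns the seed unchanged.
#' @param rigidity Laplacian regularization weight.
#' @param barriers optional logical array of forbidden voxels.
#' @param stopIntensity absolute stopping intensity; default half the image
#'   maximum.
#' @param stepVoxels step size as a fraction of a voxel.
#' @param maxIter iteration budget.
#' @param occupancy optional environment with integer array \code{$grid}
#'   shared between meshes (claims), and \code{meshId} this mesh's id.
#' @param meshId identifier written into the occupancy grid.
#' @return the expanded \linkS4class{TriangleMesh}.
#' @export
expandActiveMesh <- function(seed, img, pressure = 1, rigidity = 0.35,
                             barriers = NULL, stopIntensity = NULL,
                             stepVoxels = 0.2, maxIter = 500L,
                             occupancy = NULL, meshId = 1L) {
  if (pressure == 0) return(seed)
  st <- activeMeshInit(seed, img, pressure, rigidity, barriers,
                       stopIntensity, stepVoxels, meshId)
  for (it in seq_len(maxIter)) {
    st <- activeMeshStep(st, occupancy)
    if (st$done) break
  }
  new("TriangleMesh", vertices = st$V, triangles = st$tri,
      flags = seed@flags)
}

# --- internal active-mesh state machine (shared with segmentCells) ---

activeMeshInit <- function(seed, img, pressure, rigidity, barriers,
                           stopIntensity, stepVoxels, meshId,
                           aNum = NULL, barNum = NULL) {
  a <- imgData(img)
  if (is.null(stopIntensity)) stopIntensity <- 0.5 * max(a)
  if (is.null(aNum)) aNum <- as.numeric(a)
  if (is.null(barNum) && !is.null(barriers)) barNum <- as.numeric(barriers)
  list(V = seed@vertices, tri = seed@triangles,
       edges = meshEdgesDirected(seed@triangles),
       frozen = rep(FALSE, nrow(seed@vertices)),
       aNum = aNum, sp = voxelSpacing(img), d = dim(a),
       barNum = barNum,
       stopIntensity = stopIntensity,
       pressure = pressure, rigidity = rigidity,
       step = stepVoxels * min(voxelSpacing(img)),
       meshId = as.integer(meshId), still = 0L, done = FALSE)
}

activeMeshStep <- function(st, occupancy = NULL) {
  V <- st$V
  n <- vertexNormals(V, st$tri)
  ahead <- V + n * st$step * 1.5
  aheadVox <- sweep(ahead, 2, st$sp, "/")
  I <- .trilinear_sample(st$aNum, st$d, aheadVox)
  newFrozen <- I >= st$stopIntensity
  if (!is.null(st$barNum))
    newFrozen <- newFrozen | (.trilinear_sample(st$barNum, st$d,
                                                aheadVox) > 0.5)
  if (!is.null(occupancy)) {
    vox <- pmin(pmax(round(sweep(ahead, 2, st$sp, "/")), 0),
                matrix(st$d - 1L, nrow(V), 3, byrow = TRUE))
    li <- 1L + vox[, 1] + st$d[1] * (vox[, 2] + st$d[2] * vox[, 3])
    occ <- occupancy$grid[li]
    newFrozen <- newFrozen | (occ != 0L & occ != st$meshId)
  }
  st$frozen <- st$frozen | newFrozen
  free <- !st$frozen
  move <- matrix(0, nrow(V), 3)
  move[free, ] <- st$pressure * st$step * n[free, , drop = FALSE]
  lap <- neighborMean(V, st$edges) - V
  lap[st$frozen, ] <- 0
  Vnew <- V + move + st$rigidity * lap
  # clamp to the volume
  lim <- (st$d - 1) * st$sp
  for (k in 1:3) Vnew[, k] <- pmin(pmax(Vnew[, k], 0), lim[k])
  if (!is.null(occupancy)) {
    vox <- pmin(pmax(round(sweep(Vnew, 2, st$sp, "/")), 0),
                matrix(st$d - 1L, nrow(V), 3, byrow = TRUE))
    li <- 1L + vox[, 1] + st$d[1] * (vox[, 2] + st$d[2] * vox[, 3])
    unclaimed <- occupancy$grid[li] == 0L
    .assign_int(occupancy$grid, as.integer(li[unclaimed]), st$meshId)
  }
  maxMove <- if (any(free)) max(abs(Vnew[free, , drop = FALSE] -
                                    V[free, , drop = FALSE])) else 0
  st$V <- Vnew
  st$still <- if (maxMove < 0.01 * min(st$sp)) st$still + 1L else 0L
  st$done <- all(st$frozen) || st$still >= 10L
  st
}
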