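#' Segment cells by active-mesh expansion from the nuclei
#'
#' One icosphere seed per nucleus (centred on the nucleus, radius matched to
#' it) is expanded simultaneously for all cells under inner pressure,
#' limited by the cell cortex (the actin maximum in the phalloidin channel),
#' by tubular structures passed as barriers, and by contact with the
#' neighbouring cells (shared occupancy grid). Because optically split
#' bi-nucleated cells are initially over-segmented, adjacent cell pairs
#' whose shared interface carries less than \code{mergeIntensityFraction} of
#' the median boundary cortex intensity AND whose nucleus-to-nucleus
#' distance is below \code{mergeDistance} are merged into one bi-nucleated
#' cell. Cells whose nucleus sits within \code{borderMargin} of the image
#' border are flagged \code{boundary} (excluded from statistics downstream).
#'
#' @param cortexImg de-noised cortex (phalloidin) \linkS4class{VolumeImage}.
#' @param nuclei list of nucleus \linkS4class{TriangleMesh}es (or
#'   \linkS4class{NucleusObject}s).
#' @param tubularMasks optional list of logical arrays (e.g. sinusoid mask)
#'   acting as barriers.
#' @param pressure,rigidity active-mesh dynamics parameters.
#' @param stopIntensity cortex stopping intensity; default half the cortex
#'   image maximum.
#' @param mergeIntensityFraction,mergeDistance bi-nucleate merge cutoffs
#'   (fraction of median boundary intensity; µm).
#' @param borderMargin boundary-cell margin (µm).
#' @param maxIter per-mesh iteration budget.
#' @return list of cell \linkS4class{TriangleMesh}es; each has flags
#'   \code{nuclei} (indices into \code{nuclei}) and \code{boundary}; the
#'   voxel partition is attached as attribute \code{"labels"} (integer
#'   array, index into the returned list).
#' @export
segmentCells <- function(cortexImg, nuclei, tubularMasks = NULL,
                         pressure = 1, rigidity = 0.35,
                         stopIntensity = NULL,
                         mergeIntensityFraction = 0.5, mergeDistance = 12,
                         borderMargin = 1, maxIter = 350L) {
  a <- imgData(cortexImg)
  sp <- voxelSpacing(cortexImg)
  d <- dim(a)
  if (is.null(stopIntensity)) {
    # adaptive: the maximum-entropy split of the cortex channel separates
    # the actin cortex from the cytoplasmic background
    stopIntensity <- tryCatch(
      kapurThresholdValues(as.numeric(a), 128L, logScale = TRUE),
      error = function(e) 0.5 * max(a))
  }
  barrier <- NULL
  if (!is.null(tubularMasks)) {
    if (is.list(tubularMasks)) {
      barrier <- Reduce(`|`, tubularMasks)
    } else barrier <- tubularMasks
  }
  meshes <- lapply(nuclei, function(n) if (is(n, "NucleusObject")) n@mesh
                   else n)
  nCell <- length(meshes)
  if (!nCell) return(list())
  ico <- icosphere(3L)
  occupancy <- new.env()
  occupancy$grid <- array(0L, d)
  states <- vector("list", nCell)
  centres <- matrix(0, nCell, 3)
  aNum <- as.numeric(a)
  barNum <- if (is.null(barrier)) NULL else as.numeric(barrier)
  for (i in seq_len(nCell)) {
    ctr <- colMeans(meshes[[i]]@vertices)
    centres[i, ] <- ctr
    r0 <- mean(sqrt(rowSums(sweep(meshes[[i]]@vertices, 2, ctr)^2)))
    seed <- new("TriangleMesh",
                vertices = sweep(ico$vertices * 0.9 * r0, 2, ctr, "+"),
                triangles = ico$triangles, flags = list())
    states[[i]] <- activeMeshInit(seed, cortexImg, pressure, rigidity,
                                  barrier, stopIntensity, 0.25, i,
                                  aNum = aNum, barNum = barNum)
  }
  active <- rep(TRUE, nCell)
  for (round in seq_len(maxIter)) {
    for (i in which(active)) {
      states[[i]] <- activeMeshStep(states[[i]], occupancy)
      if (states[[i]]$done) active[i] <- FALSE
    }
    if (!any(active)) break
  }
  finalMeshes <- lapply(states, function(st)
    new("TriangleMesh", vertices = st$V, triangles = st$tri, flags = list()))
  # voxel partition: voxelize each mesh; contested voxels go to the nearer
  # cell centre, barrier voxels stay unassigned
  lab <- array(0L, d)
  claimed <- vector("list", nCell)
  for (i in seq_len(nCell)) claimed[[i]] <- meshToMask(finalMeshes[[i]], d, sp)
  for (i in seq_len(nCell)) {
    free <- claimed[[i]] & lab == 0L
    lab[free] <- i
    overlap <- claimed[[i]] & lab != i & lab != 0L
    if (any(overlap)) {
      other <- lab[overlap]
      co <- voxelCoords(which(overlap), d, sp)
      di <- rowSums(sweep(co, 2, centres[i, ])^2)
      do <- rowSums((co - centres[other, , drop = FALSE])^2)
      win <- di < do
      lab[which(overlap)[win]] <- i
    }
  }
  if (!is.null(barrier)) lab[barrier] <- 0L
  # cells partition the whole tissue interior: the unclaimed band where
  # meshes stopped at the cortex is handed to the nearest touching cell
  gap <- lab == 0L
  if (!is.null(barrier)) gap <- gap & !barrier
  lab[gap] <- -1L
  lab <- assignGaps(lab)
  # --- bi-nucleate merging ---
  groups <- as.list(seq_len(nCell))
  boundaryIdx <- labelBoundary(lab) & lab > 0L
  medBoundary <- median(a[boundaryIdx])
  pairMerged <- TRUE
  while (pairMerged) {
    pairMerged <- FALSE
    for (i in seq_len(nCell)) for (j in seq_len(nCell)) {
      if (j <= i) next
      gi <- vapply(groups, function(g) i %in% g, TRUE)
      gj <- vapply(groups, function(g) j %in% g, TRUE)
      if (which(gi) == which(gj)) next
      dn <- sqrt(sum((centres[i, ] - centres[j, ])^2))
      if (dn >= mergeDistance) next
      iface <- interfaceVoxels(lab, i, j)
      if (length(iface) < 10L) next
      if (median(a[iface]) < mergeIntensityFraction * medBoundary) {
        groups[[which(gi)]] <- c(groups[[which(gi)]], groups[[which(gj)]])
        groups[[which(gj)]] <- NULL
        pairMerged <- TRUE
        break
      }
    }
  }
  # --- assemble output ---
  out <- list()
  outLab <- array(0L, d)
  lim <- (d - 1) * sp
  for (g in seq_along(groups)) {
    mem <- groups[[g]]
    m <- array(lab %in% mem, d)
    if (!any(m)) next
    mm <- meshFromMask(m, sp, minVoxels = 30L)
    if (!length(mm)) next
    mesh <- mm[[which.max(vapply(mm, meshVolume, 0))]]
    nearBorder <- any(vapply(mem, function(i)
      any(centres[i, ] < borderMargin | centres[i, ] > lim - borderMargin),
      TRUE))
    mesh@flags <- list(nuclei = mem, boundary = nearBorder)
    out[[length(out) + 1L]] <- mesh
    outLab[m] <- length(out)
  }
  attr(out, "labels") <- outLab
  out
}

# voxels of cell i whose 6-neighbourhood touches cell j (and vice versa)
interfaceVoxels <- function(lab, i, j) {
  d <- dim(lab)
  hits <- integer(0)
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))) {
    nb <- shiftArray(lab, sh)
    hits <- c(hits, which((lab == i & nb == j) | (lab == j & nb == i)))
  }
  unique(hits)
}
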