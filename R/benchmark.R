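#' Generate a synthetic 4-channel liver-tissue scene with ground truth
#'
#' Builds an idealized ground-truth scene of the four structures that
#' dominate high-resolution liver stacks: solid bile-canalicular (BC) tubes
#' of ~0.5 µm radius, hollow sinusoid tubes (inner ~2.5 µm, outer ~3.0 µm),
#' solid spherical nuclei with radii 3.5-5.5 µm (a configurable fraction
#' placed as touching doubles/triples, as optically merged nuclei are in real
#' tissue), and ~0.5 µm-wide cell borders of the nucleus-seeded cell
#' partition bounded by the sinusoids. Networks are grown as persistent
#' random-walk branching centerlines with branch angles around 110 degrees.
#' Everything is deterministic given \code{seed}.
#'
#' @param size volume dimensions in voxels (scalar or length 3), >= 64 each.
#' @param spacing voxel size in µm (default 0.3, the high-resolution setup).
#' @param seed integer seed.
#' @param sinusoidLength,bcLength target centerline length densities
#'   (µm per µm^3).
#' @param nucleusDensity nuclei per µm^3.
#' @param doubleFrac,tripleFrac fraction of nucleus clusters placed as
#'   touching doubles / triples.
#' @param sinusoidRadii inner/outer sinusoid radii (µm).
#' @param bcRadius BC tube radius (µm).
#' @param nucleusRadii nucleus radius range (µm).
#' @param borderWidth cell-border width (µm).
#' @return A \linkS4class{GroundTruthScene}. Zero-density requests yield
#'   empty channels and tables.
#' @export
generateScene <- function(size = c(128L, 128L, 128L), spacing = 0.3,
                          seed = 1L,
                          sinusoidLength = 4e-3, bcLength = 5e-3,
                          nucleusDensity = 3e-4,
                          doubleFrac = 0.20, tripleFrac = 0.05,
                          sinusoidRadii = c(2.5, 3.0), bcRadius = 0.5,
                          nucleusRadii = c(3.5, 5.5), borderWidth = 0.5) {
  if (length(size) == 1L) size <- rep(size, 3L)
  size <- as.integer(size)
  stopifnot(all(size >= 64L))
  set.seed(as.integer(seed %% .Machine$integer.max))
  d <- size
  sp3 <- rep(spacing, 3)
  extent <- d * spacing
  volUm3 <- prod(extent)

  sinCls <- growNetwork(extent, sinusoidLength * volUm3, step = 1.0,
                        branchProb = 0.03, angle = 110, wobble = 0.25)
  bcCls <- growNetwork(extent, bcLength * volUm3, step = 0.75,
                       branchProb = 0.05, angle = 110, wobble = 0.45)
  sinDist <- centerlineDistance(sinCls, d, sp3)
  bcDist <- centerlineDistance(bcCls, d, sp3)
  sinLumen <- sinDist <= sinusoidRadii[1]
  sinShell <- sinDist <= sinusoidRadii[2] & !sinLumen
  bcMask <- bcDist <= bcRadius & !(sinDist <= sinusoidRadii[2])

  # --- nuclei ---
  nNuc <- round(nucleusDensity * volUm3)
  nuc <- placeNuclei(nNuc, extent, nucleusRadii, doubleFrac, tripleFrac,
                     clearDist = function(p) {
                       v <- pmin(pmax(round(p / spacing), 0), d - 1L)
                       sinDist[1 + v[1] + d[1] * (v[2] + d[2] * v[3])]
                     },
                     sinOuter = sinusoidRadii[2])
  nucLab <- array(0L, d)
  if (nrow(nuc)) {
    co <- voxelCoords(seq_len(prod(d)), d, sp3)
    for (i in seq_len(nrow(nuc))) {
      dd <- sqrt((co[, 1] - nuc$x[i])^2 + (co[, 2] - nuc$y[i])^2 +
                 (co[, 3] - nuc$z[i])^2)
      sel <- dd <= nuc$radius[i]
      nucLab[sel] <- i
    }
  }

  # --- cells: influence zones of the nuclei (weighted Voronoi by distance
  # to the nucleus surface), nuclei of one cluster forming one cell,
  # bounded by the sinusoids ---
  cellLab <- array(0L, d)
  cells <- data.frame()
  if (nrow(nuc)) {
    cl <- sort(unique(nuc$cluster))
    cx <- vapply(cl, function(k) mean(nuc$x[nuc$cluster == k]), 0)
    cy <- vapply(cl, function(k) mean(nuc$y[nuc$cluster == k]), 0)
    cz <- vapply(cl, function(k) mean(nuc$z[nuc$cluster == k]), 0)
    co <- voxelCoords(seq_len(prod(d)), d, sp3)
    best <- rep(1L, nrow(co)); bestD <- rep(Inf, nrow(co))
    for (i in seq_len(nrow(nuc))) {
      dd <- sqrt((co[, 1] - nuc$x[i])^2 + (co[, 2] - nuc$y[i])^2 +
                 (co[, 3] - nuc$z[i])^2) - nuc$radius[i]
      upd <- dd < bestD
      best[upd] <- match(nuc$cluster[i], cl)
      bestD[upd] <- dd[upd]
    }
    cellLab <- array(best, d)
    cellLab[sinLumen | sinShell] <- 0L
    # a cell must be connected to its nuclei: chunks of a Voronoi cell cut
    # off by a sinusoid are reassigned to a touching neighbour cell
    for (k in seq_along(cl)) {
      comp <- labelComponents(cellLab == k, 6L)
      if (max(comp) <= 1L) next
      v <- pmin(pmax(round(c(cx[k], cy[k], cz[k]) / spacing), 0), d - 1L)
      own <- comp[1 + v[1] + d[1] * (v[2] + d[2] * v[3])]
      if (own == 0L) own <- which.max(tabulate(comp[comp > 0]))
      cellLab[comp > 0 & comp != own] <- -1L
    }
    if (any(cellLab == -1L)) cellLab <- assignGaps(cellLab)
    borderTouch <- vapply(seq_along(cl), function(k) {
      m <- cellLab == k
      any(m[c(1, d[1]), , ]) || any(m[, c(1, d[2]), ]) ||
        any(m[, , c(1, d[3])])
    }, TRUE)
    cells <- data.frame(
      cluster = cl, x = cx, y = cy, z = cz,
      nNuclei = as.integer(table(factor(nuc$cluster, levels = cl))),
      volumeUm3 = as.numeric(table(factor(as.integer(cellLab),
                                          levels = seq_along(cl)))) *
        spacing^3,
      boundary = borderTouch)
  }

  # --- cell borders: voxels whose 6-neighbourhood crosses a label change ---
  borders <- labelBoundary(cellLab)
  # thicken to the requested physical width
  halfW <- max(0, borderWidth / 2 - spacing / 2)
  if (halfW > 0) borders <- dilateBall(borders, halfW, sp3)
  borders <- borders & cellLab > 0

  new("GroundTruthScene",
      labels = list(bc = bcMask, sinusoid = sinShell,
                    sinusoidLumen = sinLumen, nuclei = nucLab,
                    cells = cellLab, cellBorders = borders),
      tables = list(nuclei = nuc, cells = cells,
                    sinusoidCenterlines = sinCls, bcCenterlines = bcCls),
      spacing = sp3, seed = as.numeric(seed))
}

# persistent random-walk branching network; returns list of polylines (µm)
growNetwork <- function(extent, totalLength, step, branchProb, angle,
                        wobble) {
  polys <- list()
  if (totalLength <= 0) return(polys)
  placed <- 0
  queue <- list()
  nSeeds <- max(2L, round(totalLength / (mean(extent) * 2)))
  for (i in seq_len(nSeeds)) {
    queue[[length(queue) + 1L]] <- list(
      p = runif(3) * extent, dir = randomUnit())
  }
  guard <- 0L
  while (placed < totalLength && guard < 10000L) {
    guard <- guard + 1L
    if (!length(queue))                       # respawn to meet the density
      queue[[1]] <- list(p = runif(3) * extent, dir = randomUnit())
    w <- queue[[1]]; queue[[1]] <- NULL
    pts <- matrix(w$p, 1, 3)
    dir <- w$dir
    len <- 0
    maxLen <- runif(1, 0.3, 1) * mean(extent)
    while (len < maxLen && placed < totalLength) {
      dir <- normalize(dir + wobble * rnorm(3))
      p2 <- pts[nrow(pts), ] + step * dir
      # reflect at the box faces
      for (k in 1:3) {
        if (p2[k] < 0) { p2[k] <- -p2[k]; dir[k] <- -dir[k] }
        if (p2[k] > extent[k]) { p2[k] <- 2 * extent[k] - p2[k]
                                 dir[k] <- -dir[k] }
      }
      pts <- rbind(pts, p2)
      len <- len + step
      placed <- placed + step
      if (runif(1) < branchProb && length(queue) < 64L) {
        queue[[length(queue) + 1L]] <- list(
          p = p2, dir = rotateAbout(dir, angle * pi / 180))
      }
    }
    if (nrow(pts) > 2L) polys[[length(polys) + 1L]] <- pts
  }
  polys
}

randomUnit <- function() normalize(rnorm(3))

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

# rotate v by theta about a random axis perpendicular to v
rotateAbout <- function(v, theta) {
  v <- normalize(v)
  a <- normalize(pracmaCross(v, randomUnit()))
  v * cos(theta) + pracmaCross(a, v) * sin(theta)
}

pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# distance (µm) from every voxel to the nearest centerline sample
centerlineDistance <- function(polys, d, sp3) {
  mask <- array(FALSE, d)
  if (length(polys)) {
    pts <- do.call(rbind, lapply(polys, densifyPolyline,
                                 maxStep = min(sp3) / 2))
    vox <- sweep(pts, 2, sp3, "/")
    mask <- array(.stamp_points(mask, d, vox), d)
  }
  if (!any(mask)) return(array(Inf, d))
  edtDist(mask, sp3)
}

densifyPolyline <- function(pts, maxStep) {
  out <- list()
  for (i in seq_len(nrow(pts) - 1L)) {
    seg <- pts[i + 1L, ] - pts[i, ]
    L <- sqrt(sum(seg^2))
    n <- max(1L, ceiling(L / maxStep))
    tt <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    out[[i]] <- cbind(pts[i, 1] + tt * seg[1], pts[i, 2] + tt * seg[2],
                      pts[i, 3] + tt * seg[3])
  }
  rbind(do.call(rbind, out), pts[nrow(pts), , drop = FALSE])
}

# place nuclei as singles/doubles/triples without overlaps; returns table
placeNuclei <- function(n, extent, radii, doubleFrac, tripleFrac,
                        clearDist, sinOuter) {
  nuc <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    radius = numeric(0), cluster = integer(0),
                    multiplicity = integer(0))
  if (n <= 0) return(nuc)
  cluster <- 0L
  attempts <- 0L
  while (nrow(nuc) < n && attempts < 2000L) {
    attempts <- attempts + 1L
    u <- runif(1)
    mult <- if (u < tripleFrac) 3L else if (u < tripleFrac + doubleFrac) 2L
            else 1L
    r1 <- runif(1, radii[1], radii[2])
    p <- radii[2] + runif(3) * (extent - 2 * radii[2])
    if (clearDist(p) < sinOuter + r1) next
    ok <- !nrow(nuc) ||
      all(sqrt((nuc$x - p[1])^2 + (nuc$y - p[2])^2 + (nuc$z - p[3])^2) >
          nuc$radius + r1 + 0.3)
    if (!ok) next
    cluster <- cluster + 1L
    members <- list(c(p, r1))
    for (m in seq_len(mult - 1L)) {
      for (try in 1:20) {
        r2 <- runif(1, radii[1], radii[2])
        prev <- members[[length(members)]]
        dir <- randomUnit()
        dist <- runif(1, 0.75, 0.95) * (prev[4] + r2)
        q <- prev[1:3] + dir * dist
        if (any(q < r2) || any(q > extent - r2)) next
        if (clearDist(q) < sinOuter + r2) next
        othersOk <- !nrow(nuc) ||
          all(sqrt((nuc$x - q[1])^2 + (nuc$y - q[2])^2 +
                   (nuc$z - q[3])^2) > nuc$radius + r2 + 0.3)
        if (othersOk) { members[[length(members) + 1L]] <- c(q, r2); break }
      }
    }
    for (mm in members) {
      nuc <- rbind(nuc, data.frame(x = mm[1], y = mm[2], z = mm[3],
                                   radius = mm[4], cluster = cluster,
                                   multiplicity = length(members)))
    }
  }
  nuc
}

# iteratively hand voxels marked -1 to any 6-neighbouring positive label
assignGaps <- function(lab) {
  d <- dim(lab)
  repeat {
    todo <- lab == -1L
    if (!any(todo)) break
    filled <- FALSE
    for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      nb <- shiftArray(lab, sh)
      can <- todo & nb > 0
      if (any(can)) { lab[can] <- nb[can]; todo[can] <- FALSE; filled <- TRUE }
    }
    if (!filled) { lab[lab == -1L] <- 0L; break }
  }
  lab
}

# shift a 3D array by (dx,dy,dz), zero-padding
shiftArray <- function(a, sh) {
  d <- dim(a)
  out <- array(0L, d)
  sx <- seq_len(d[1]) - sh[1]; sy <- seq_len(d[2]) - sh[2]
  sz <- seq_len(d[3]) - sh[3]
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
  okz <- sz >= 1 & sz <= d[3]
  out[okx, oky, okz] <- a[sx[okx], sy[oky], sz[okz]]
  out
}

# voxels whose 6-neighbourhood crosses a cell-label change (both sides)
labelBoundary <- function(lab) {
  d <- dim(lab)
  b <- array(FALSE, d)
  cmp <- function(a, b) a != b
  b[-d[1], , ] <- b[-d[1], , ] | cmp(lab[-d[1], , ], lab[-1, , ])
  b[-1, , ] <- b[-1, , ] | cmp(lab[-1, , ], lab[-d[1], , ])
  b[, -d[2], ] <- b[, -d[2], ] | cmp(lab[, -d[2], ], lab[, -1, ])
  b[, -1, ] <- b[, -1, ] | cmp(lab[, -1, ], lab[, -d[2], ])
  b[, , -d[3]] <- b[, , -d[3]] | cmp(lab[, , -d[3]], lab[, , -1])
  b[, , -1] <- b[, , -1] | cmp(lab[, , -1], lab[, , -d[3]])
  b
}

#' Impose uneven staining and a homogeneous background on a ground truth
#'
#' A 6x6x6-binned coarse random intensity field is drawn log-normally (mean
#' 1000 a.u., log-sd \code{sd1}), refined per voxel log-normally around the
#' coarse value (log-sd \code{sd2}) and masked by the structure; a uniform
#' background is added so that the foreground-mean : background ratio equals
#' \code{snr}.
#'
#' @param channel logical/0-1 3D array (ground-truth structure mask) or
#'   \linkS4class{VolumeImage}.
#' @param snr signal-to-noise ratio (> 1), e.g. 10, 4 or 2.
#' @param meanIntensity mean staining intensity (a.u.).
#' @param sd1,sd2 log-sd of the coarse and fine log-normal draws.
#' @param bin coarse binning factor (voxels).
#' @param spacing voxel spacing for the returned image.
#' @param seed integer seed.
#' @return \linkS4class{VolumeImage} with uneven staining plus background.
#' @export
applyUnevenStaining <- function(channel, snr = 10, meanIntensity = 1000,
                                sd1 = 0.5, sd2 = 0.2, bin = 6L,
                                spacing = 0.3, seed = 1L) {
  stopifnot(snr > 1)
  if (is(channel, "VolumeImage")) {
    spacing <- voxelSpacing(channel)
    channel <- imgData(channel) > 0
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  d <- dim3(channel)
  cd <- pmax(1L, ceiling(d / bin))
  coarse <- array(rlnorm(prod(cd), meanlog = log(meanIntensity) - sd1^2 / 2,
                         sdlog = sd1), cd)
  # unbin: nearest coarse cell per voxel
  ix <- pmin((seq_len(d[1]) - 1L) %/% bin + 1L, cd[1])
  iy <- pmin((seq_len(d[2]) - 1L) %/% bin + 1L, cd[2])
  iz <- pmin((seq_len(d[3]) - 1L) %/% bin + 1L, cd[3])
  up <- coarse[ix, iy, iz]
  fine <- array(rlnorm(prod(d), meanlog = log(up) - sd2^2 / 2, sdlog = sd2),
                d)
  bg <- meanIntensity / (snr - 1)
  out <- fine * channel + bg
  VolumeImage(out, spacing = spacing, channel = "stained")
}

#' Blur a volume with a confocal point-spread function
#'
#' Gaussian approximation of the confocal PSF, axially elongated: lateral
#' sigma 0.225 lambda / NA, axial sigma 0.78 n lambda / NA^2 (n = 1.515,
#' oil). The kernel is normalized, so total intensity is conserved.
#'
#' @param img \linkS4class{VolumeImage}.
#' @param wavelength emission wavelength in nm (> 0).
#' @param na numerical aperture (default 1.3, the 63x/1.3 objective).
#' @param refIndex immersion refractive index.
#' @return blurred \linkS4class{VolumeImage}.
#' @export
psfConvolve <- function(img, wavelength, na = 1.3, refIndex = 1.515) {
  stopifnot(wavelength > 0)
  lam <- wavelength / 1000              # µm
  sigLat <- 0.225 * lam / na
  sigAx <- 0.78 * refIndex * lam / na^2
  sp <- voxelSpacing(img)
  sig <- c(sigLat, sigLat, sigAx) / sp
  withData(img, gaussSmooth(imgData(img), sig))
}

#' Add depth-dependent Poisson noise
#'
#' Emulates photon-limited acquisition with depth-increasing gain: per voxel,
#' I_out = alpha(z) * Poisson(I_in / alpha(z)) + beta, with alpha linear in
#' depth.
#'
#' @param img \linkS4class{VolumeImage}.
#' @param alpha0 conversion coefficient (a.u./photon) at the first plane.
#' @param alphaSlope increase of alpha per µm of depth (>= 0).
#' @param beta digitization offset (a.u.).
#' @param seed integer seed.
#' @return noisy \linkS4class{VolumeImage}.
#' @export
addDepthNoise <- function(img, alpha0 = 1, alphaSlope = 0.05, beta = 100,
                          seed = 1L) {
  a <- imgData(img)
  d <- dim(a)
  sp <- voxelSpacing(img)
  zUm <- (seq_len(d[3]) - 1) * sp[3]
  alpha <- alpha0 + alphaSlope * zUm
  stopifnot(all(alpha > 0))
  set.seed(as.integer(seed %% .Machine$integer.max))
  out <- a
  for (z in seq_len(d[3])) {
    lam <- a[, , z] / alpha[z]
    out[, , z] <- alpha[z] * array(rpois(length(lam), as.numeric(lam)),
                                   dim(lam)) + beta
  }
  withData(img, out)
}

#' Score a reconstruction against the ground truth
#'
#' Voxel-wise precision PR = TP/(TP+FP), sensitivity SN = TP/(TP+FN) and
#' F-score 2 PR SN / (PR + SN) per structure; mean tube radii from the
#' skeletonized masks; per-cell volume errors 100 |Vs - Vgt| / Vgt for
#' ground-truth cells not touching the image boundary, matched to the
#' predicted cell with the largest overlap.
#'
#' @param pred named list with any of: \code{bc}, \code{sinusoid},
#'   \code{nuclei} (logical masks) and \code{cells} (integer label array).
#' @param gt a \linkS4class{GroundTruthScene} on the same grid.
#' @return list of per-structure statistics.
#' @export
evaluateReconstruction <- function(pred, gt) {
  out <- list()
  for (ch in c("bc", "sinusoid", "nuclei")) {
    if (is.null(pred[[ch]])) next
    gtm <- switch(ch,
      nuclei = gt@labels$nuclei > 0,
      # sinusoids are scored as filled tubes (shell plus lumen)
      sinusoid = gt@labels$sinusoid | gt@labels$sinusoidLumen,
      gt@labels[[ch]])
    if (!all(dim(pred[[ch]]) == dim(gtm))) stop("grid mismatch")
    out[[ch]] <- confusionStats(pred[[ch]], gtm)
  }
  if (!is.null(pred$cells)) {
    gl <- gt@labels$cells
    if (!all(dim(pred$cells) == dim(gl))) stop("grid mismatch")
    interior <- gt@tables$cells$cluster[!gt@tables$cells$boundary]
    perCellF <- numeric(0); volErr <- numeric(0)
    for (k in interior) {
      gm <- gl == k
      ov <- tabulate(pred$cells[gm])
      if (!length(ov) || max(ov) == 0) { perCellF <- c(perCellF, 0); next }
      pk <- which.max(ov)
      pm <- pred$cells == pk
      st <- confusionStats(pm, gm)
      perCellF <- c(perCellF, st$F)
      volErr <- c(volErr, 100 * abs(sum(pm) - sum(gm)) / sum(gm))
    }
    out$cells <- list(F = mean(perCellF), perCellF = perCellF,
                      volumeErrorPct = mean(volErr), perCellVolErr = volErr)
  }
  out
}

confusionStats <- function(pred, gtm) {
  pred <- as.logical(pred); gtm <- as.logical(gtm)
  tp <- sum(pred & gtm); fp <- sum(pred & !gtm)
  fn <- sum(!pred & gtm); tn <- sum(!pred & !gtm)
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  sn <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (pr + sn > 0) 2 * pr * sn / (pr + sn) else 0
  list(TP = tp, FP = fp, TN = tn, FN = fn, PR = pr, SN = sn, F = f)
}
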