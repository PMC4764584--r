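#' De-noise, segment and split all nuclei of a DAPI channel
#'
#' Segments the (de-noised) DAPI channel with the local maximum-entropy
#' field, meshes every connected object, approximates each by single and
#' double overlapping ellipsoids, classifies objects into mono / double /
#' multi by the two-Gaussian mixture of ln(MSE), and splits doubles by their
#' ellipsoid pair and multis by LoGMP-seeded expansion.
#'
#' @param dapi de-noised DAPI \linkS4class{VolumeImage}.
#' @param mask optional precomputed nucleus mask; by default the channel is
#'   thresholded with \code{\link{lmeThresholdField}}.
#' @param minVoxels minimum object size (voxels).
#' @param sigmaRange LoG scale range (µm) for multi-nucleus seeds.
#' @param tune tune object meshes to the intensity gradient before the
#'   ellipsoid analysis (corrects the thresholding swell).
#' @return list: \code{objects} (final \linkS4class{NucleusObject}s),
#'   \code{labels} (integer array of final nuclei), \code{table}
#'   (per-initial-object multiplicity bookkeeping), \code{threshold}
#'   (ln-MSE split threshold).
#' @export
splitNuclei <- function(dapi, mask = NULL, minVoxels = 500L,
                        sigmaRange = c(3.5, 5.5) / sqrt(2), tune = TRUE) {
  sp <- voxelSpacing(dapi)
  if (is.null(mask)) {
    field <- lmeThresholdField(dapi, cube = min(dim(imgData(dapi))),
                               overlap = 0.5, logHist = TRUE,
                               fgRange = c(0.02, 0.5))
    mask <- segmentStructure(dapi, field, closing = 2)
  }
  mask <- fillHoles3d(mask)
  mask <- sizeFilter(mask, minVoxels)
  d <- dim(mask)
  lab <- labelComponents(mask, 26L)
  nObj <- max(lab)
  if (nObj == 0L)
    return(list(objects = list(), labels = array(0L, d),
                table = data.frame(), threshold = NA_real_))
  smImg <- NULL; smGrad <- NULL
  if (tune) {
    smImg <- withData(dapi, gaussSmooth(imgData(dapi), 1.0))
    smGrad <- gradientMagnitude(imgData(smImg), sp)
  }
  bbs <- objectBBoxes(lab, margin = 5L)
  meshes <- vector("list", nObj)
  lnMse <- rep(NA_real_, nObj)
  bestModel <- rep("mono", nObj)
  labT <- array(0L, d)                  # labels after mesh tuning
  for (i in seq_len(nObj)) {
    bb <- bbs[[i]]
    if (is.null(bb)) next
    sub <- lab[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
               bb$lo[3]:bb$hi[3], drop = FALSE] == i
    if (sum(sub) < 20L) next
    mesh <- meshFromCrop(sub, bb$lo, sp)
    if (is.null(mesh)) next
    if (tune) {
      mesh <- tuneMeshToGradient(mesh, smImg, search = 1.0, iters = 8L,
                                 gradient = smGrad)
      tcrop <- meshToCrop(mesh, bb$lo, bb$hi, sp)
      tgt <- labT[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
                  bb$lo[3]:bb$hi[3], drop = FALSE]
      tgt[tcrop & tgt == 0L] <- i
      labT[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
           bb$lo[3]:bb$hi[3]] <- tgt
    } else {
      labT[lab == i] <- i
    }
    meshes[[i]] <- mesh
    mseS <- tryCatch({
      e1 <- fitMinVolumeEllipsoid(mesh@vertices)
      ellipsoidFitMSE(mesh, e1)
    }, error = function(e) NA_real_)
    mseD <- tryCatch({
      mdl <- fitDoubleEllipsoid(mesh)
      if (is.null(mdl)) NA_real_ else ellipsoidFitMSE(mesh, mdl)
    }, error = function(e) NA_real_)
    if (is.na(mseS) && is.na(mseD)) next
    if (is.na(mseD) || (!is.na(mseS) && mseS <= mseD)) {
      bestModel[i] <- "mono"; lnMse[i] <- log(max(mseS, 1e-12))
    } else {
      bestModel[i] <- "double"; lnMse[i] <- log(max(mseD, 1e-12))
    }
  }
  ok <- which(!is.na(lnMse))
  cls <- classifyMultiplicity(lnMse[ok], bestModel[ok])
  multiplicity <- rep("mono", nObj)
  multiplicity[ok] <- cls$multiplicity
  objects <- list()
  outLab <- array(0L, d)
  parent <- integer(0)
  for (i in seq_len(nObj)) {
    if (is.null(meshes[[i]])) next
    bb <- bbs[[i]]
    crop <- labT[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
                 bb$lo[3]:bb$hi[3], drop = FALSE] == i
    if (!any(crop)) next
    objMask <- array(FALSE, d)
    objMask[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2],
            bb$lo[3]:bb$hi[3]] <- crop
    obj <- new("NucleusObject", mesh = meshes[[i]],
               multiplicity = multiplicity[i],
               dapiIntegral = NA_real_,
               seed = colMeans(meshes[[i]]@vertices))
    pieces <- splitMultinucleus(obj, dapi, objMask,
                                sigmaRange = sigmaRange,
                                seedOverride = TRUE)
    for (p in pieces) {
      if (is.na(p@dapiIntegral))
        p@dapiIntegral <- dapiIntegralCrop(p@mesh, dapi)
      objects[[length(objects) + 1L]] <- p
      parent <- c(parent, i)
      vox <- sweep(p@mesh@vertices, 2, sp, "/")
      lo <- pmax(floor(apply(vox, 2, min)) - 1L, 1L)
      hi <- pmin(ceiling(apply(vox, 2, max)) + 1L, d)
      pm <- meshToCrop(p@mesh, as.integer(lo), as.integer(hi), sp)
      tgt <- outLab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
      tgt[pm & tgt == 0L] <- length(objects)
      outLab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- tgt
    }
  }
  tab <- data.frame(object = seq_len(nObj), lnMse = lnMse,
                    bestModel = bestModel, multiplicity = multiplicity)
  list(objects = objects, labels = outLab, table = tab,
       threshold = cls$threshold, parent = parent)
}

#' Degrade a ground-truth scene into realistic benchmark images
#'
#' Applies the fixed degradation stack (uneven staining -> background ->
#' PSF -> depth-dependent Poisson noise) to the four channels, with the
#' per-structure emission wavelengths (BC 568, sinusoids 647, nuclei 780,
#' cell borders 488 nm). Stages can be bypassed for ablation.
#'
#' @param scene a \linkS4class{GroundTruthScene}.
#' @param snr signal-to-noise ratio.
#' @param seed integer seed.
#' @param stain,psf,noise logical switches for the three stages.
#' @return named list of four noisy \linkS4class{VolumeImage}s (bc,
#'   sinusoid, nuclei, cellBorders).
#' @export
benchmarkDegrade <- function(scene, snr, seed = 1L, stain = TRUE,
                             psf = TRUE, noise = TRUE) {
  sp <- scene@spacing
  waves <- c(bc = 568, sinusoid = 647, nuclei = 780, cellBorders = 488)
  out <- list()
  for (ch in names(waves)) {
    gtm <- if (ch == "nuclei") scene@labels$nuclei > 0 else scene@labels[[ch]]
    if (stain) {
      vi <- applyUnevenStaining(gtm, snr = snr, spacing = sp[1],
                                seed = seed + 13 * match(ch, names(waves)))
    } else {
      vi <- VolumeImage(gtm * 1000 + 1000 / (snr - 1), spacing = sp,
                        channel = ch)
    }
    if (psf) vi <- psfConvolve(vi, waves[[ch]])
    if (noise) vi <- addDepthNoise(vi, seed = seed + 131 *
                                     match(ch, names(waves)))
    vi@channel <- ch
    out[[ch]] <- vi
  }
  out
}

#' De-noise a benchmark channel with its self-calibrated noise model
#'
#' @param vi noisy \linkS4class{VolumeImage}.
#' @param slabHeight calibration slab height (voxels).
#' @return de-noised \linkS4class{VolumeImage}.
#' @export
denoiseChannel <- function(vi, slabHeight = 32L) {
  nm <- estimateNoiseModel(vi, slabHeight = slabHeight)
  if (nm@failed) return(vi)
  bfbdDenoise(vi, nm)
}

#' Reconstruct a degraded benchmark scene and score it
#'
#' Runs the full reconstruction pipeline on the four degraded channels:
#' BFBD de-noising, local maximum-entropy segmentation, mesh extraction and
#' gradient tuning for the tubular networks, nucleus segmentation with
#' multiplicity splitting, and active-mesh cell segmentation seeded by the
#' nuclei with the sinusoids as barriers; then scores every structure
#' against the ground truth.
#'
#' @param scene the \linkS4class{GroundTruthScene}.
#' @param images degraded channels from \code{\link{benchmarkDegrade}}.
#' @param withCells run the (slower) cell segmentation.
#' @return list with \code{masks}, \code{score}
#'   (\code{\link{evaluateReconstruction}} output) and tuned mean radii
#'   \code{radius} (µm) for the two networks.
#' @export
reconstructScene <- function(scene, images, withCells = TRUE) {
  sp <- scene@spacing
  masks <- list(); radius <- list()
  den <- lapply(images, denoiseChannel)
  # --- tubular networks (reconstructed and scored as filled tubes) ---
  for (ch in c("bc", "sinusoid")) {
    vi <- den[[ch]]
    # the benchmark has no macroscopic illumination trend, so the threshold
    # field is computed at its global limit (one cube spanning the image);
    # the foreground-fraction prior reflects the physiological volume share
    # of each structure (sinusoids ~10%, bile canaliculi ~1%)
    cube <- min(dim(imgData(vi)))
    field <- lmeThresholdField(vi, cube = cube, overlap = 0.5,
                               logHist = TRUE,
                               fgRange = if (ch == "bc") c(0.002, 0.3)
                                         else c(0.02, 0.5))
    m <- segmentStructure(vi, field, closing = 1, minVoxels = 50L)
    if (ch == "sinusoid") m <- closeBall(m, 2.7, sp)   # fill the lumen
    m <- sizeFilter(m, 500L)
    meshes <- meshFromMask(m, sp, minVoxels = 500L, smoothIters = 2L)
    # gradient search range and smoothing both scale with the structure
    # radius (smoothing suppresses staining texture but must stay below
    # the structure scale)
    smWidth <- if (ch == "bc") 0.5 else 1.0
    smImg <- withData(vi, gaussSmooth(imgData(vi), smWidth))
    tuned <- lapply(meshes, tuneMeshToGradient, img = smImg,
                    search = if (ch == "bc") 0.3 else 1.0, iters = 8L)
    tm <- array(FALSE, dim(m))
    for (mm in tuned) tm <- tm | meshToMask(mm, dim(m), sp)
    masks[[ch]] <- tm
    radius[[ch]] <- tubeMeanRadius(tm, sp,
                                   openRadius = if (ch == "sinusoid") 1.5
                                                else 0)
  }
  # --- nuclei ---
  nuc <- splitNuclei(den$nuclei)
  masks$nuclei <- nuc$labels > 0L
  # --- cells ---
  if (withCells && length(nuc$objects)) {
    cells <- segmentCells(den$cellBorders, nuc$objects,
                          tubularMasks = masks$sinusoid)
    masks$cells <- attr(cells, "labels")
    masks$cellMeshes <- cells
  }
  score <- evaluateReconstruction(masks, scene)
  list(masks = masks, score = score, radius = radius, nuclei = nuc)
}

# mean tube radius: optionally open away sub-scale debris (openRadius, µm),
# close the lumen if requested, thin to the centerline and average the
# distance transform over the skeleton voxels
tubeMeanRadius <- function(mask, sp, fillRadius = 0, openRadius = 0) {
  if (openRadius > 0) mask <- openBall(mask, openRadius, sp)
  filled <- if (fillRadius > 0) closeBall(mask, fillRadius, sp) else mask
  if (!any(filled)) return(NA_real_)
  d <- dim3(filled)
  ed <- edtSq(!filled, sp)
  skel <- array(.thin3d(as.logical(filled), d, as.numeric(ed)), d)
  if (!any(skel)) return(NA_real_)
  mean(sqrt(ed[skel]))
}

#' Synthetic benchmark of the nuclei-splitting algorithm
#'
#' Generates a 3D field of \code{n} nuclei with radii 5-7 µm containing
#' single, double- and triple-nucleated structures at varying overlap, adds
#' 10% background, Gaussian blur and salt-and-pepper noise, runs
#' segmentation plus multiplicity splitting and scores every initially
#' segmented structure: TP = correctly split, FP = over-split, TN =
#' correctly not split, FN = under-split.
#'
#' @param n number of nuclei.
#' @param seed integer seed.
#' @param spacing voxel size (µm).
#' @param doubleFrac,tripleFrac cluster-type fractions.
#' @return list with the confusion counts, \code{accuracy} and the
#'   per-structure table.
#' @export
nucleiSplittingBenchmark <- function(n = 150L, seed = 1L, spacing = 0.6,
                                     doubleFrac = 0.25, tripleFrac = 0.1) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  radii <- c(5, 7)
  # box sized for ~8% packing density
  vol <- n * (4 / 3) * pi * 6^3 / 0.08
  ext <- rep(vol^(1 / 3), 3)
  d <- as.integer(ceiling(ext / spacing))
  nuc <- placeNuclei(n, ext, radii, doubleFrac, tripleFrac,
                     clearDist = function(p) Inf, sinOuter = 0)
  sp3 <- rep(spacing, 3)
  lab <- array(0L, d)
  co <- voxelCoords(seq_len(prod(d)), d, sp3)
  for (i in seq_len(nrow(nuc))) {
    dd <- sqrt((co[, 1] - nuc$x[i])^2 + (co[, 2] - nuc$y[i])^2 +
               (co[, 3] - nuc$z[i])^2)
    lab[dd <= nuc$radius[i]] <- i
  }
  img <- (lab > 0) * 1000 + 100                      # 10% background
  img <- gaussSmooth(img, 0.9 / spacing)             # blur
  saltIdx <- sample(prod(d), round(0.01 * prod(d)))  # salt and pepper
  img[saltIdx] <- ifelse(runif(length(saltIdx)) < 0.5, 0, 1100)
  vi <- VolumeImage(img, spacing = sp3, channel = "DAPI")
  split <- splitNuclei(vi, mask = imgData(vi) > 550, minVoxels = 200L,
                       sigmaRange = c(5, 7) / sqrt(2))
  # ground-truth structures = clusters of touching nuclei
  initLab <- labelComponents(lab > 0, 26L)
  nStruct <- max(initLab)
  tp <- fp <- tn <- fn <- 0L
  rows <- list()
  centres <- cbind(nuc$x, nuc$y, nuc$z)
  vox <- pmin(pmax(round(sweep(centres, 2, sp3[1], "/")), 0),
              matrix(d - 1L, nrow(nuc), 3, byrow = TRUE))
  li <- 1 + vox[, 1] + d[1] * (vox[, 2] + d[2] * vox[, 3])
  structOf <- initLab[li]
  finalCentres <- t(vapply(split$objects, function(o)
    colMeans(o@mesh@vertices), numeric(3)))
  finalStruct <- if (length(split$objects)) {
    fv <- pmin(pmax(round(finalCentres / sp3[1]), 0),
               matrix(d - 1L, nrow(finalCentres), 3, byrow = TRUE))
    initLab[1 + fv[, 1] + d[1] * (fv[, 2] + d[2] * fv[, 3])]
  } else integer(0)
  for (s in seq_len(nStruct)) {
    nTrue <- sum(structOf == s)
    if (!nTrue) next
    nPred <- sum(finalStruct == s)
    if (!nPred) next                       # structure missed by segmentation
    dec <- if (nTrue == 1L && nPred == 1L) "TN"
      else if (nTrue >= 2L && nPred == nTrue) "TP"
      else if (nPred > nTrue) "FP"
      else "FN"
    switch(dec, TN = tn <- tn + 1L, TP = tp <- tp + 1L,
           FP = fp <- fp + 1L, FN = fn <- fn + 1L)
    rows[[length(rows) + 1L]] <- data.frame(structure = s, nTrue = nTrue,
                                            nPred = nPred, decision = dec)
  }
  acc <- (tp + tn) / max(1L, tp + tn + fp + fn)
  list(TP = tp, FP = fp, TN = tn, FN = fn, accuracy = acc,
       table = do.call(rbind, rows), nuclei = nuc)
}
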