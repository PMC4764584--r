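# The 74 nuclear parameters used for marker-less cell-type classification:
# geometry of the nucleus mesh, DAPI/Flk1 intensity statistics, 3D Haralick
# texture, fractal dimensions, gliding-box lacunarity, the DAPI surface
# gradient, and phalloidin/Flk1 shell intensities around the nucleus.

featureNames74 <- function() {
  c("Volume", "Surface area", "a/b", "a/c", "b/c", "Sphericity",
    "Mean radius", "Radius variance", "Shape index", "CVM",
    "DAPI mean", "DAPI Sd", "DAPI SKEW", "DAPI KURT",
    "FLK1 mean", "FLK1 Sd", "FLK1 SKEW", "FLK1 KURT",
    paste0("HF", 1:13),
    "BC Frac Dim", "MB Frac Dim",
    paste("Lacunarity", 1:5),
    paste("Norm lac", 2:5),
    paste("Log lac", 1:5),
    paste("Log norm lac", 2:5),
    "DAPI gradient surface",
    paste("Phallo surface intensity", 0:10, "vx"),
    paste("FLK1 surface intensity", 0:10, "vx"))
}

#' Extract the 74 nuclear parameters of a reconstructed nucleus
#'
#' Computes the nuclear feature profile used for cell-type classification:
#' mesh geometry (volume, area, minimum-volume-ellipsoid axis ratios,
#' sphericity, radius statistics, shape index and curvature variation
#' measure), DAPI and Flk1 intensity moments inside the nucleus, 13 Haralick
#' features from the grey-level co-occurrence matrix accumulated over all 13
#' 3D directions and distances 1-5 at 256 grey levels, box-counting and
#' Minkowski-Bouligand fractal dimensions, gliding-box lacunarity (box
#' lengths 1-5 with normalized and log variants), the area-weighted DAPI
#' gradient on the mesh surface, and phalloidin/Flk1 mean intensities in
#' one-voxel shells 0-10 voxels from the nucleus surface. Channels are
#' histogram-equalized (256 levels, whole stack) before extraction.
#'
#' @param nucleus a \linkS4class{NucleusObject} or \linkS4class{TriangleMesh}.
#' @param channels named list of \linkS4class{VolumeImage}s: \code{dapi},
#'   \code{flk1}, \code{phalloidin}.
#' @param equalize logical, apply histogram equalization first.
#' @return named numeric vector of the 74 features, with attribute
#'   \code{"unreliable"} TRUE when the nucleus touches the image border.
#' @export
extractFeatures <- function(nucleus, channels, equalize = TRUE) {
  mesh <- if (is(nucleus, "NucleusObject")) nucleus@mesh else nucleus
  dapi <- channels$dapi
  sp <- voxelSpacing(dapi)
  d <- dim(imgData(dapi))
  eq <- function(vi) {
    a <- imgData(vi)
    if (equalize) equalizeHistogram(a, 256L) else a
  }
  aD <- eq(channels$dapi)
  aF <- eq(channels$flk1)
  aP <- eq(channels$phalloidin)
  mask <- meshToMask(mesh, d, sp)
  out <- setNames(numeric(74), featureNames74())
  unreliable <- isTRUE(mesh@flags$borderCapped) ||
    any(mask[c(1, d[1]), , ]) || any(mask[, c(1, d[2]), ]) ||
    any(mask[, , c(1, d[3])])

  # --- geometry ---
  V <- meshVolume(mesh); A <- meshArea(mesh)
  out["Volume"] <- V
  out["Surface area"] <- A
  ax <- c(1, 1, 1)
  mve <- try(fitMinVolumeEllipsoid(mesh@vertices), silent = TRUE)
  if (!inherits(mve, "try-error")) ax <- semiAxes(mve)
  out["a/b"] <- ax[1] / ax[2]
  out["a/c"] <- ax[1] / ax[3]
  out["b/c"] <- ax[2] / ax[3]
  out["Sphericity"] <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  ctr <- colMeans(mesh@vertices)
  rr <- sqrt(rowSums(sweep(mesh@vertices, 2, ctr)^2))
  out["Mean radius"] <- mean(rr)
  out["Radius variance"] <- var(rr)
  cv <- meshCurvatures(mesh)
  out["Shape index"] <- cv$shapeIndex
  out["CVM"] <- cv$cvm

  # --- intensity moments ---
  mD <- aD[mask]; mF <- aF[mask]
  mom <- function(v) {
    m <- mean(v); s <- sd(v)
    if (!is.finite(s) || s < 1e-12)
      return(c(m, 0, 0, 0))
    c(m, s, mean((v - m)^3) / s^3, mean((v - m)^4) / s^4 - 3)
  }
  out[c("DAPI mean", "DAPI Sd", "DAPI SKEW", "DAPI KURT")] <- mom(mD)
  out[c("FLK1 mean", "FLK1 Sd", "FLK1 SKEW", "FLK1 KURT")] <- mom(mF)

  # --- Haralick (13 features, 65 co-occurrence matrices averaged) ---
  out[paste0("HF", 1:13)] <- haralick3d(aD, mask, levels = 256L,
                                        distances = 1:5)

  # --- fractal dimensions and lacunarity on DAPI inside the nucleus ---
  bb <- maskBoundingBox(mask)
  sub <- aD[bb$x, bb$y, bb$z] * mask[bb$x, bb$y, bb$z]
  subMask <- mask[bb$x, bb$y, bb$z]
  out["BC Frac Dim"] <- boxCountingDimension(sub)
  out["MB Frac Dim"] <- minkowskiDimension(sub)
  lac <- glidingBoxLacunarity(sub, subMask, 1:5)
  out[paste("Lacunarity", 1:5)] <- lac
  out[paste("Norm lac", 2:5)] <- lac[2:5] / lac[1]
  out[paste("Log lac", 1:5)] <- log(lac)
  out[paste("Log norm lac", 2:5)] <- log(lac[2:5] / lac[1])

  # --- DAPI surface gradient (area-weighted over triangle centres) ---
  g <- gradientMagnitude(aD, sp)
  tc <- (mesh@vertices[mesh@triangles[, 1], ] +
         mesh@vertices[mesh@triangles[, 2], ] +
         mesh@vertices[mesh@triangles[, 3], ]) / 3
  ar <- triangleAreas(mesh@vertices, mesh@triangles)
  out["DAPI gradient surface"] <- weighted.mean(sampleAt(g, tc, sp), ar)

  # --- shell intensities (per one-voxel ring from the surface) ---
  dOut <- sqrt(edtSq(mask, c(1, 1, 1)))        # voxel units, 0 inside
  ring0 <- mask & (shiftAny6(!mask))
  for (k in 0:10) {
    ring <- if (k == 0) ring0 else (dOut >= k - 0.5) & (dOut < k + 0.5)
    out[paste("Phallo surface intensity", k, "vx")] <-
      if (any(ring)) mean(aP[ring]) else 0
    out[paste("FLK1 surface intensity", k, "vx")] <-
      if (any(ring)) mean(aF[ring]) else 0
  }
  attr(out, "unreliable") <- unreliable
  out
}

shiftAny6 <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1)))
    out <- out | shiftArray(m, sh) > 0
  out
}

maskBoundingBox <- function(mask) {
  co <- which(mask, arr.ind = TRUE)
  list(x = min(co[, 1]):max(co[, 1]), y = min(co[, 2]):max(co[, 2]),
       z = min(co[, 3]):max(co[, 3]))
}

# area-weighted shape index and curvature variation measure from discrete
# principal curvatures (cotangent mean curvature + angle-deficit Gaussian)
meshCurvatures <- function(mesh) {
  V <- mesh@vertices; tri <- mesh@triangles
  nv <- nrow(V)
  # mixed area per vertex (1/3 of incident triangle areas)
  ar <- triangleAreas(V, tri)
  Amix <- numeric(nv)
  for (k in 1:3) {
    acc <- rowsum(ar / 3, tri[, k])
    Amix[as.integer(rownames(acc))] <- Amix[as.integer(rownames(acc))] + acc
  }
  # angle deficit -> Gaussian curvature
  ang <- matrix(0, nrow(tri), 3)
  for (k in 1:3) {
    a <- V[tri[, k], ]; b <- V[tri[, k %% 3 + 1], ]; cc <- V[tri[, (k + 1) %% 3 + 1], ]
    u <- b - a; w <- cc - a
    cs <- rowSums(u * w) / (sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)))
    ang[, k] <- acos(pmin(pmax(cs, -1), 1))
  }
  defect <- rep(2 * pi, nv)
  for (k in 1:3) {
    acc <- rowsum(ang[, k], tri[, k])
    defect[as.integer(rownames(acc))] <- defect[as.integer(rownames(acc))] - acc
  }
  K <- defect / pmax(Amix, 1e-12)
  # mean curvature magnitude from the uniform Laplacian along the normal
  edges <- meshEdgesDirected(tri)
  n <- vertexNormals(V, tri)
  lap <- neighborMean(V, edges) - V
  H <- -rowSums(lap * n) / pmax(Amix, 1e-12) * 0.5
  disc <- pmax(H^2 - K, 0)
  k1 <- H + sqrt(disc); k2 <- H - sqrt(disc)
  si <- (2 / pi) * atan((k2 + k1) / pmax(abs(k2 - k1), 1e-9))
  curvedness <- sqrt((k1^2 + k2^2) / 2)
  w <- Amix / sum(Amix)
  cw <- sum(w * curvedness)
  list(shapeIndex = sum(w * si),
       cvm = sqrt(sum(w * (curvedness - cw)^2)) / max(cw, 1e-12))
}

# the 13 unique displacement directions of the 26-neighbourhood
haralickDirections <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[rowSums(abs(o)) > 0, ]
  keep <- o[, 3] > 0 | (o[, 3] == 0 & (o[, 2] > 0 | (o[, 2] == 0 & o[, 1] > 0)))
  o[keep, , drop = FALSE]
}

#' 13 Haralick features from a 3D grey-level co-occurrence matrix
#'
#' Accumulates co-occurrence counts over the 13 unique 3D directions at the
#' given distances (65 matrices), symmetrized and normalized into one GLCM,
#' and evaluates Haralick's 13 classic statistics.
#'
#' @param a 3D numeric array with grey values in [0, levels).
#' @param mask logical array restricting pairs to the object.
#' @param levels number of grey levels.
#' @param distances displacement multiples.
#' @return numeric vector HF1..HF13.
#' @export
haralick3d <- function(a, mask, levels = 256L, distances = 1:5) {
  q <- array(as.integer(pmin(floor(a), levels - 1L)), dim(a))
  q[!mask] <- -1L
  dirs <- haralickDirections()
  offsets <- do.call(rbind, lapply(distances, function(dd) dirs * dd))
  counts <- .glcm3d(as.integer(q), dim3(a), levels, offsets)
  if (sum(counts) == 0) return(rep(0, 13))
  haralickFromGlcm(counts / sum(counts))
}

# Haralick's f1..f13 from a normalized symmetric GLCM
haralickFromGlcm <- function(p) {
  n <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)
  sg <- sqrt(sum((i - mu)^2 * p))
  # p_{x+y} and p_{x-y}
  sums <- tapply(as.numeric(p), as.numeric(i + j), sum)
  diffs <- tapply(as.numeric(p), as.numeric(abs(i - j)), sum)
  kSum <- as.numeric(names(sums)); kDif <- as.numeric(names(diffs))
  eps <- 1e-12
  f1 <- sum(p^2)
  f2 <- sum((i - j)^2 * p)
  f3 <- if (sg > eps) sum((i - mu) * (j - mu) * p) / sg^2 else 0
  f4 <- sum((i - mu)^2 * p)
  f5 <- sum(p / (1 + (i - j)^2))
  f6 <- sum(kSum * sums)
  f7 <- sum((kSum - f6)^2 * sums)
  f8 <- -sum(sums * log(sums + eps))
  f9 <- -sum(p * log(p + eps))
  mD <- sum(kDif * diffs)
  f10 <- sum((kDif - mD)^2 * diffs)
  f11 <- -sum(diffs * log(diffs + eps))
  pxj <- matrix(px, n, n); pyi <- t(pxj)
  hxy1 <- -sum(p * log(pxj * pyi + eps))
  hxy2 <- -sum(as.numeric(pxj * pyi) * log(as.numeric(pxj * pyi) + eps))
  hx <- -sum(px * log(px + eps))
  f12 <- if (max(hx, f9) > eps) (f9 - hxy1) / max(hx, f9) else 0
  arg <- 1 - exp(-2 * (hxy2 - f9))
  f13 <- sqrt(max(arg, 0))
  c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13)
}

# differential box counting (aligned grid) on a non-negative intensity block
boxCountingDimension <- function(a, sizes = 1:5) {
  d <- dim(a)
  G <- max(a) + 1
  ns <- numeric(0); ss <- numeric(0)
  for (s in sizes) {
    if (any(d < s)) next
    nb <- d %/% s
    h <- s * G / min(d)
    tot <- 0
    sub <- a[seq_len(nb[1] * s), seq_len(nb[2] * s), seq_len(nb[3] * s),
             drop = FALSE]
    dim(sub) <- c(s, nb[1], s, nb[2], s, nb[3])
    mx <- apply(sub, c(2, 4, 6), max)
    mn <- apply(sub, c(2, 4, 6), min)
    occupied <- mx > 0
    nr <- ceiling((mx + 1) / h) - ceiling(pmax(mn, 0) / h) + 1
    tot <- sum(nr[occupied])
    if (tot > 0) { ns <- c(ns, tot); ss <- c(ss, s) }
  }
  if (length(ns) < 2L) return(0)
  -coef(lm(log(ns) ~ log(ss)))[2]
}

# Minkowski-Bouligand dimension via the blanket (dilation/erosion) method
minkowskiDimension <- function(a, radii = 1:5) {
  up <- a; lo <- a
  vols <- numeric(length(radii))
  for (r in seq_along(radii)) {
    up <- greyDilate6(up); lo <- greyErode6(lo)
    vols[r] <- sum(up - lo)
  }
  A <- vols / (2 * radii)
  ok <- A > 0
  if (sum(ok) < 2L) return(0)
  3 - coef(lm(log(A[ok]) ~ log(radii[ok])))[2]
}

greyDilate6 <- function(a) {
  out <- a
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1)))
    out <- pmax(out, shiftArrayNum(a, sh))
  out
}

greyErode6 <- function(a) {
  out <- a
  for (sh in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1)))
    out <- pmin(out, shiftArrayNum(a, sh, pad = Inf))
  out
}

shiftArrayNum <- function(a, sh, pad = 0) {
  d <- dim(a)
  out <- array(pad, d)
  sx <- seq_len(d[1]) - sh[1]; sy <- seq_len(d[2]) - sh[2]
  sz <- seq_len(d[3]) - sh[3]
  okx <- sx >= 1 & sx <= d[1]; oky <- sy >= 1 & sy <= d[2]
  okz <- sz >= 1 & sz <= d[3]
  out[okx, oky, okz] <- a[sx[okx], sy[oky], sz[okz]]
  out
}

# gliding-box lacunarity Lambda(b) = <m^2>/<m>^2 over box masses m, using
# only boxes fully inside the object mask
glidingBoxLacunarity <- function(a, mask, sizes = 1:5) {
  ii <- integralImage3d(a)
  im <- integralImage3d(mask * 1)
  vapply(sizes, function(b) {
    d <- dim(a)
    if (any(d < b)) return(NA_real_)
    m <- boxSums(ii, b)
    inside <- boxSums(im, b) >= b^3 - 1e-9
    m <- m[inside]
    if (!length(m) || mean(m) <= 0) return(1)
    mean(m^2) / mean(m)^2
  }, 0)
}

integralImage3d <- function(a) {
  s <- apply(a, c(2, 3), cumsum)
  s <- aperm(apply(s, c(1, 3), cumsum), c(2, 1, 3))
  aperm(apply(s, c(1, 2), cumsum), c(2, 3, 1))
}

boxSums <- function(ii, b) {
  d <- dim(ii)
  pad <- array(0, d + 1L)
  pad[-1, -1, -1] <- ii
  x0 <- 1:(d[1] - b + 1L); y0 <- 1:(d[2] - b + 1L); z0 <- 1:(d[3] - b + 1L)
  S <- function(x, y, z) pad[x, y, z, drop = FALSE]
  out <- S(x0 + b, y0 + b, z0 + b) - S(x0, y0 + b, z0 + b) -
    S(x0 + b, y0, z0 + b) - S(x0 + b, y0 + b, z0) +
    S(x0, y0, z0 + b) + S(x0, y0 + b, z0) + S(x0 + b, y0, z0) -
    S(x0, y0, z0)
  out
}
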