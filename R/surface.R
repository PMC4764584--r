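#' Maximum-entropy (Kapur) threshold of an intensity histogram
#'
#' Chooses the threshold that maximizes the sum of the Shannon entropies of
#' the background and foreground histogram partitions. Ties are broken
#' towards the lowest bin. Invariant under scaling of the counts.
#'
#' @param hist either an object with \code{$counts} and \code{$mids} (as
#'   returned by \code{\link[graphics]{hist}}) or a numeric vector of counts
#'   (bin mids default to the bin index).
#' @param fgMin,fgMax optional plausibility constraint on the foreground
#'   mass fraction the split induces; candidates outside the range are
#'   excluded (the unconstrained criterion is bistable on histograms with a
#'   narrow background peak and a broad foreground tail).
#' @return the threshold intensity (upper edge of the background partition);
#'   voxels strictly above it are foreground.
#' @examples
#' x <- c(rnorm(500, 10, 1), rnorm(500, 30, 2))
#' h <- hist(x, breaks = 64, plot = FALSE)
#' maxEntropyThreshold(h)
#' @export
maxEntropyThreshold <- function(hist, fgMin = 0, fgMax = 1) {
  if (is.list(hist)) {
    counts <- hist$counts; mids <- hist$mids
  } else {
    counts <- as.numeric(hist); mids <- seq_along(counts)
  }
  occ <- counts > 0
  if (sum(occ) < 2L) stop("histogram must have at least 2 occupied bins")
  p <- counts / sum(counts)
  n <- length(p)
  cp <- cumsum(p)
  cH <- cumsum(ifelse(p > 0, -p * log(p), 0))   # partial entropies
  totH <- cH[n]
  # candidate t splits bins 1..t | (t+1)..n; both sides must be occupied
  t <- seq_len(n - 1L)
  Pb <- cp[t]
  Pf <- 1 - Pb
  valid <- Pb > 0 & Pf > 0 & Pf >= fgMin & Pf <= fgMax
  if (!any(valid)) valid <- Pb > 0 & Pf > 0
  Hb <- ifelse(valid, cH[t] / Pb + log(Pb), -Inf)
  Hf <- ifelse(valid, (totH - cH[t]) / Pf + log(Pf), -Inf)
  crit <- Hb + Hf
  best <- which(crit >= max(crit) - 1e-12)[1]   # lowest tying bin
  if (best < n) (mids[best] + mids[best + 1]) / 2 else mids[best]
}

# Kapur threshold of a numeric vector with a fixed bin count; logScale bins
# in log intensity (fluorescence intensities are multiplicative), returning
# the threshold on the linear scale
kapurThresholdValues <- function(x, nbins = 128L, logScale = FALSE,
                                 fgRange = NULL) {
  if (logScale) x <- log1p(pmax(x, 0))
  rng <- range(x)
  if (diff(rng) <= 0) stop("constant input")
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  cnt <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  thr <- if (is.null(fgRange))
    maxEntropyThreshold(list(counts = cnt, mids = mids))
  else maxEntropyThreshold(list(counts = cnt, mids = mids),
                           fgMin = fgRange[1], fgMax = fgRange[2])
  if (logScale) expm1(thr) else thr
}

#' Measure section surfaces by maximum-entropy thresholding
#'
#' Per x-y column, the measured top (ym1) and bottom (ym2) surface heights
#' are the first and last z indices above the global maximum-entropy
#' threshold, after light lateral smoothing. Empty columns are marked and
#' inpainted from their neighbours. These measured surfaces dip into
#' unstained vessels touching the surface; the Bayesian refinement corrects
#' that.
#'
#' @param img section \linkS4class{VolumeImage}.
#' @param smoothSigma lateral Gaussian sigma (voxels) before thresholding.
#' @return \linkS4class{SurfacePair} with measured fields only.
#' @export
measureSurfaces <- function(img, smoothSigma = 1) {
  a <- imgData(img)
  d <- dim(a)
  if (smoothSigma > 0) a <- gaussSmooth(a, c(smoothSigma, smoothSigma, 0))
  thr <- kapurThresholdValues(as.numeric(a), 128L)
  above <- a > thr
  zIdx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  zTop <- zIdx; zTop[!above] <- NA
  zBot <- zIdx; zBot[!above] <- NA
  ym1 <- apply(zTop, c(1, 2), function(v) suppressWarnings(min(v, na.rm = TRUE)))
  ym2 <- apply(zBot, c(1, 2), function(v) suppressWarnings(max(v, na.rm = TRUE)))
  ym1[!is.finite(ym1)] <- NA
  ym2[!is.finite(ym2)] <- NA
  ym1 <- inpaintNA(ym1)
  ym2 <- inpaintNA(ym2)
  new("SurfacePair", ym1 = ym1, ym2 = ym2,
      y1 = matrix(numeric(0), 0, 0), y2 = matrix(numeric(0), 0, 0))
}

# fill NA cells of a matrix from neighbour means, iteratively
inpaintNA <- function(m) {
  while (anyNA(m)) {
    na <- which(is.na(m), arr.ind = TRUE)
    filled <- FALSE
    for (i in seq_len(nrow(na))) {
      r <- na[i, 1]; cc <- na[i, 2]
      nb <- m[max(1, r - 1):min(nrow(m), r + 1),
              max(1, cc - 1):min(ncol(m), cc + 1)]
      if (any(!is.na(nb))) { m[r, cc] <- mean(nb, na.rm = TRUE); filled <- TRUE }
    }
    if (!filled) { m[is.na(m)] <- mean(m, na.rm = TRUE); break }
  }
  m
}

#' Estimate the surface-posterior parameters from measured surfaces
#'
#' The median absolute deviation t_MAD of the measured section thickness
#' |ym2 - ym1| approximates both the Cauchy likelihood scale and the
#' thickness-coupling sigma (scaled by pi/2); the Laplace smoothness rate is
#' the maximum-likelihood estimate 1/mean|dy| on the neighbour height
#' differences of the measured surfaces.
#'
#' @param sp \linkS4class{SurfacePair} with measured fields.
#' @return \linkS4class{SurfacePrior}; a zero t_MAD is floored at 1 voxel and
#'   flagged.
#' @export
estimatePrior <- function(sp) {
  th <- sp@ym2 - sp@ym1
  tMad <- median(abs(th - median(th)))
  flagged <- FALSE
  if (tMad <= 0) { tMad <- 1; flagged <- TRUE }
  # Laplace MLE on the direct-neighbour height differences of both
  # measured surfaces: lambda = 1 / mean|dy|
  dy <- c(abs(diff(sp@ym1)), abs(t(diff(t(sp@ym1)))),
          abs(diff(sp@ym2)), abs(t(diff(t(sp@ym2)))))
  mDy <- mean(dy)
  lam <- if (mDy > 0) 1 / mDy else 10
  new("SurfacePrior", s = pi / 2 * tMad, sigma = pi / 2 * tMad, lam = lam,
      tMad = tMad, tMed = median(th), flagged = flagged)
}

#' Negative log posterior of a surface configuration
#'
#' Sum over columns of the Cauchy data terms for the top and bottom surface,
#' the Gaussian thickness coupling (centred at the median measured
#' thickness), and the Laplace smoothness of the top surface over the eight
#' lateral neighbours (each ordered pair counted once per direction, as in
#' the defining product).
#'
#' @param sp \linkS4class{SurfacePair} with measured fields and candidate
#'   refined fields in \code{y1}, \code{y2} (defaults to the measured fields
#'   when unset).
#' @param prior \linkS4class{SurfacePrior}.
#' @return scalar energy (lower is better).
#' @export
surfaceEnergy <- function(sp, prior) {
  y1 <- if (length(sp@y1)) sp@y1 else sp@ym1
  y2 <- if (length(sp@y2)) sp@y2 else sp@ym2
  s <- prior@s; sg <- prior@sigma; lam <- prior@lam
  e <- sum(log(pi * s) + log1p(((y1 - sp@ym1) / s)^2)) +
       sum(log(pi * s) + log1p(((y2 - sp@ym2) / s)^2)) +
       sum(log(sqrt(2 * pi) * sg) +
           ((y2 - y1 - prior@tMed)^2) / (2 * sg^2))
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    sh <- shiftMatrix(y1, dx, dy)
    ok <- !is.na(sh)
    e <- e + sum(lam * abs(y1[ok] - sh[ok])) - sum(ok) * log(lam)
  }
  e
}

# shift a matrix by (dx, dy), NA-padding
shiftMatrix <- function(m, dx, dy) {
  n <- matrix(NA_real_, nrow(m), ncol(m))
  xs <- seq_len(nrow(m)) - dx
  ys <- seq_len(ncol(m)) - dy
  okx <- xs >= 1 & xs <= nrow(m)
  oky <- ys >= 1 & ys <= ncol(m)
  n[okx, oky] <- m[xs[okx], ys[oky]]
  n
}

#' Refine section surfaces by iterated conditional modes
#'
#' Coordinate-wise minimization of \code{\link{surfaceEnergy}}: every column
#' in turn is set to the integer height (within ±3 t_MAD of its current
#' value) that minimizes the local energy given its neighbours, until a sweep
#' changes no column. Columns are updated in a 2x2 colouring so that
#' simultaneously updated columns are never lateral neighbours, which keeps
#' every sweep non-increasing in energy.
#'
#' @param sp measured \linkS4class{SurfacePair}.
#' @param prior \linkS4class{SurfacePrior}.
#' @param maxSweeps sweep budget; non-convergence returns the best
#'   configuration found, with a warning.
#' @return \linkS4class{SurfacePair} with refined \code{y1}, \code{y2}.
#' @export
refineSurfacesICM <- function(sp, prior, maxSweeps = 40L) {
  y1 <- pmin(sp@ym1, sp@ym2)
  y2 <- pmax(sp@ym1, sp@ym2)
  s <- prior@s; sg <- prior@sigma; lam <- prior@lam
  halo <- max(2L, ceiling(3 * prior@tMad))
  cand <- -halo:halo
  nbh <- expand.grid(dx = -1:1, dy = -1:1)
  nbh <- nbh[!(nbh$dx == 0 & nbh$dy == 0), ]
  colorOf <- function(m) {
    outer(seq_len(nrow(m)) %% 2, seq_len(ncol(m)) %% 2,
          function(a, b) 1 + a + 2 * b)
  }
  colors <- colorOf(y1)
  converged <- FALSE
  for (sweep in seq_len(maxSweeps)) {
    changed <- 0L
    for (col in 1:4) {
      sel <- colors == col
      # --- top surface ---
      nbSum <- function(yy, val) {
        acc <- 0
        for (i in seq_len(nrow(nbh))) {
          sh <- shiftMatrix(yy, nbh$dx[i], nbh$dy[i])
          acc <- acc + abs(ifelse(is.na(sh), val, sh) - val)[sel]
        }
        acc
      }
      base1 <- y1[sel]
      bestE <- rep(Inf, sum(sel)); bestY <- base1
      for (dc in cand) {
        yc <- base1 + dc
        yc <- pmin(yc, y2[sel])          # keep y1 <= y2
        eloc <- log1p(((yc - sp@ym1[sel]) / s)^2) +
          ((y2[sel] - yc - prior@tMed)^2) / (2 * sg^2)
        acc <- 0
        for (i in seq_len(nrow(nbh))) {
          sh <- shiftMatrix(y1, nbh$dx[i], nbh$dy[i])[sel]
          acc <- acc + abs(ifelse(is.na(sh), yc, sh) - yc)
        }
        eloc <- eloc + 2 * lam * acc     # each clique appears twice globally
        upd <- eloc < bestE - 1e-12
        bestE[upd] <- eloc[upd]; bestY[upd] <- yc[upd]
      }
      changed <- changed + sum(bestY != base1)
      y1[sel] <- bestY
      # --- bottom surface (data + thickness terms only) ---
      base2 <- y2[sel]
      bestE <- rep(Inf, sum(sel)); bestY <- base2
      for (dc in cand) {
        yc <- base2 + dc
        yc <- pmax(yc, y1[sel])
        eloc <- log1p(((yc - sp@ym2[sel]) / s)^2) +
          ((yc - y1[sel] - prior@tMed)^2) / (2 * sg^2)
        upd <- eloc < bestE - 1e-12
        bestE[upd] <- eloc[upd]; bestY[upd] <- yc[upd]
      }
      changed <- changed + sum(bestY != base2)
      y2[sel] <- bestY
    }
    if (changed == 0L) { converged <- TRUE; break }
  }
  if (!converged)
    warning("ICM did not converge within the sweep budget; ",
            "returning the best configuration so far")
  new("SurfacePair", ym1 = sp@ym1, ym2 = sp@ym2, y1 = y1, y2 = y2)
}

#' Unbend a section so both surfaces become planes
#'
#' Fits tensor-product quadratic B-spline height surfaces to the refined top
#' and bottom fields and remaps every column linearly in z so that the
#' fitted surfaces land on their mean planes. In-plane coordinates are
#' untouched; intensities are linearly interpolated along z.
#'
#' @param img section \linkS4class{VolumeImage}.
#' @param sp refined \linkS4class{SurfacePair}.
#' @param df spline degrees of freedom per axis.
#' @return flattened \linkS4class{VolumeImage}; the z remap is attached as
#'   attribute \code{"flattenMap"} for \code{\link{unflattenSection}}.
#' @export
flattenSection <- function(img, sp, df = 8L) {
  if (!length(sp@y1)) stop("refined surfaces required")
  if (any(sp@y1 > sp@y2)) stop("surfaces cross")
  a <- imgData(img)
  d <- dim(a)
  fit1 <- fitSplineSurface(sp@y1, df)
  fit2 <- fitSplineSurface(sp@y2, df)
  if (any(fit2 - fit1 < 1)) stop("fitted surfaces cross or touch")
  z1t <- mean(fit1); z2t <- mean(fit2)
  out <- remapZ(a, fit1, fit2, z1t, z2t)
  vi <- withData(img, out)
  attr(vi, "flattenMap") <- list(y1 = fit1, y2 = fit2, z1 = z1t, z2 = z2t)
  vi
}

#' @rdname flattenSection
#' @param flat flattened image produced by \code{flattenSection}.
#' @param map the \code{"flattenMap"} attribute of the flattened image.
#' @export
unflattenSection <- function(flat, map = attr(flat, "flattenMap")) {
  a <- imgData(flat)
  # inverse: source planes z1..z2 now live at fitted heights
  out <- remapZ(a, matrix(map$z1, nrow(map$y1), ncol(map$y1)),
                matrix(map$z2, nrow(map$y1), ncol(map$y1)),
                0, 0, invTo = list(map$y1, map$y2))
  withData(flat, out)
}

fitSplineSurface <- function(m, df = 8L) {
  x <- rep(seq_len(nrow(m)), ncol(m))
  y <- rep(seq_len(ncol(m)), each = nrow(m))
  df <- min(df, nrow(m) - 1L, ncol(m) - 1L)
  if (df < 3L) {             # tiny grids: plane fit
    fit <- lm(as.numeric(m) ~ x + y)
    return(matrix(fit$fitted.values, nrow(m), ncol(m)))
  }
  bx <- splines::bs(x, df = df, degree = 2)
  by <- splines::bs(y, df = df, degree = 2)
  X <- matrix(0, length(x), ncol(bx) * ncol(by))
  k <- 1L
  for (i in seq_len(ncol(bx))) for (j in seq_len(ncol(by))) {
    X[, k] <- bx[, i] * by[, j]; k <- k + 1L
  }
  # marginal terms are needed alongside the tensor products because the
  # no-intercept B-spline bases do not sum to one
  D <- cbind(1, bx, by, X)
  fit <- lm.fit(D, as.numeric(m))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  matrix(D %*% cf, nrow(m), ncol(m))
}

# per-column linear z remap: source heights (h1,h2) -> targets (t1,t2)
remapZ <- function(a, h1, h2, t1, t2, invTo = NULL) {
  d <- dim(a)
  nz <- d[3]
  prof <- matrix(a, ncol = nz)        # rows = columns of the image
  out <- matrix(0, nrow(prof), nz)
  h1v <- as.numeric(h1); h2v <- as.numeric(h2)
  for (z in seq_len(nz)) {
    # which source z lands on output plane z?
    if (is.null(invTo)) {
      src <- h1v + (z - t1) * (h2v - h1v) / (t2 - t1)
    } else {
      y1v <- as.numeric(invTo[[1]]); y2v <- as.numeric(invTo[[2]])
      src <- h1v + (z - y1v) * (h2v - h1v) / (y2v - y1v)
    }
    lo <- floor(src)
    fr <- src - lo
    lo <- pmin(pmax(lo, 1), nz)
    hi <- pmin(lo + 1, nz)
    out[, z] <- prof[cbind(seq_len(nrow(prof)), lo)] * (1 - fr) +
      prof[cbind(seq_len(nrow(prof)), hi)] * fr
  }
  array(out, dim = d)
}

#' Local maximum-entropy threshold field
#'
#' Splits the image into a regular grid of overlapping cubes, computes the
#' Kapur threshold within each and interpolates the per-cube thresholds
#' tri-linearly over the whole image. Degenerate cubes (effectively constant)
#' inherit the nearest valid neighbour's threshold.
#'
#' @param img \linkS4class{VolumeImage}.
#' @param cube cube edge length in voxels (>= 16).
#' @param overlap fractional overlap between neighbouring cubes in [0, 0.75].
#' @param mask optional logical array restricting the histogram (e.g. the
#'   in-tissue region).
#' @param minSeparation bimodality sanity check: a cube threshold is valid
#'   only when the foreground/background class means it induces are at least
#'   this many background standard deviations apart (otherwise the cube is
#'   treated as structure-free and inherits a neighbour's threshold).
#' @param logHist compute the per-cube histograms in log intensity (suited
#'   to multiplicative staining variation).
#' @param fgRange plausibility bounds on the per-cube foreground fraction
#'   passed to the entropy criterion (stained structures occupy neither a
#'   vanishing nor a dominant share of a cube).
#' @return a \linkS4class{ThresholdField}.
#' @export
lmeThresholdField <- function(img, cube = 32L, overlap = 0.5, mask = NULL,
                              minSeparation = 4, logHist = FALSE,
                              fgRange = c(0.001, 0.75)) {
  stopifnot(cube >= 16L, overlap >= 0, overlap <= 0.75)
  a <- imgData(img)
  d <- dim(a)
  stride <- max(1L, as.integer(round(cube * (1 - overlap))))
  gridStarts <- function(n) {
    s <- seq(1L, max(1L, n - cube + 1L), by = stride)
    if (s[length(s)] + cube - 1L < n) s <- c(s, n - cube + 1L)
    unique(pmax(s, 1L))
  }
  sx <- gridStarts(d[1]); sy <- gridStarts(d[2]); sz <- gridStarts(d[3])
  th <- array(NA_real_, c(length(sx), length(sy), length(sz)))
  for (k in seq_along(sz)) for (j in seq_along(sy)) for (i in seq_along(sx)) {
    xs <- sx[i]:min(d[1], sx[i] + cube - 1L)
    ys <- sy[j]:min(d[2], sy[j] + cube - 1L)
    zs <- sz[k]:min(d[3], sz[k] + cube - 1L)
    v <- a[xs, ys, zs]
    if (!is.null(mask)) v <- v[mask[xs, ys, zs]]
    if (length(v) < 8L || diff(range(v)) <= 0) next
    t0 <- tryCatch(kapurThresholdValues(as.numeric(v), 128L,
                                        logScale = logHist,
                                        fgRange = fgRange),
                   error = function(e) NA_real_)
    if (!is.na(t0) && minSeparation > 0) {
      fg <- v > t0
      if (!any(fg) || all(fg)) { t0 <- NA_real_ }
      else {
        sb <- sd(v[!fg])
        if (!is.finite(sb) || sb < 1e-12) sb <- 1e-12
        if ((mean(v[fg]) - mean(v[!fg])) / sb < minSeparation)
          t0 <- NA_real_
      }
    }
    th[i, j, k] <- t0
  }
  if (all(is.na(th))) stop("no cube produced a valid threshold")
  th <- inpaintNA3d(th)
  centers <- list(sx + (pmin(cube, d[1]) - 1) / 2,
                  sy + (pmin(cube, d[2]) - 1) / 2,
                  sz + (pmin(cube, d[3]) - 1) / 2)
  new("ThresholdField", thresholds = th, centers = centers,
      cube = as.numeric(cube), dim = as.integer(d))
}

inpaintNA3d <- function(a) {
  if (!anyNA(a)) return(a)
  d <- dim(a)
  na <- is.na(a)
  valid <- which(!na)
  vc <- arrayInd(valid, d)
  for (i in which(na)) {
    ic <- arrayInd(i, d)
    dd <- (vc[, 1] - ic[1])^2 + (vc[, 2] - ic[2])^2 + (vc[, 3] - ic[3])^2
    a[i] <- a[valid[which.min(dd)]]
  }
  a
}

#' Interpolate a ThresholdField to a per-voxel threshold volume
#'
#' Tri-linear interpolation anchored at cube centres (the interpolated value
#' at a cube centre equals that cube's threshold), clamped beyond the border
#' cubes.
#'
#' @param field a \linkS4class{ThresholdField}.
#' @return 3D numeric array of per-voxel thresholds.
#' @export
thresholdVolume <- function(field) {
  interpGridToVolume(field@thresholds,
                     lapply(field@centers, function(x) x),
                     field@dim)
}

#' Segment unstained large vessels inside the tissue slab
#'
#' Large vessels carry no stain and appear as empty volume. Voxels below the
#' local threshold field that lie between the refined surfaces are collected
#' into connected components; components above the size filter are the
#' vessel mask. The out-of-field region (outside the surfaces) is excluded.
#'
#' @param section \linkS4class{VolumeImage} of the section.
#' @param sp refined \linkS4class{SurfacePair}.
#' @param field \linkS4class{ThresholdField} (or scalar threshold).
#' @param minVoxels vessel size filter (voxels).
#' @return logical vessel mask.
#' @export
segmentVessels <- function(section, sp, field, minVoxels = 500L) {
  a <- imgData(section)
  d <- dim(a)
  thr <- if (is(field, "ThresholdField")) thresholdVolume(field) else field
  y1 <- if (length(sp@y1)) sp@y1 else sp@ym1
  y2 <- if (length(sp@y2)) sp@y2 else sp@ym2
  zIdx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  inSlab <- zIdx >= array(rep(y1, d[3]), d) & zIdx <= array(rep(y2, d[3]), d)
  low <- (a < thr) & inSlab
  if (!any(low)) return(low)
  sizeFilter(low, minVoxels, 6L)
}

#' Bridge a vessel across the gap between two physical sections
#'
#' Cutting removes tissue between consecutive sections. The vessel mask is
#' continued across the gap by interpolating the signed distance fields of
#' the two facing cross-sections linearly along z and thresholding at the
#' zero level, so a circular vessel offset between the faces is carried
#' across with a linearly moving centroid.
#'
#' @param maskA,maskB logical end-face cross-sections (2D matrices): the last
#'   slice of the upper section and the first slice of the lower one.
#' @param gap number of missing z planes to synthesize.
#' @return logical array (dim(maskA) x gap); all-FALSE with a warning when
#'   the dilated faces do not overlap (disjoint vessels are not bridged).
#' @export
interpolateVesselGap <- function(maskA, maskB, gap) {
  stopifnot(all(dim(maskA) == dim(maskB)), gap >= 1)
  d2 <- dim(maskA)
  out <- array(FALSE, c(d2, gap))
  dilA <- edtSq2d(maskA) <= 4 + 1e-9
  dilB <- edtSq2d(maskB) <= 4 + 1e-9
  if (!any(dilA & dilB)) {
    warning("end faces do not overlap after dilation; gap left unbridged")
    return(out)
  }
  sdf <- function(m) sqrt(edtSq2d(!m)) - sqrt(edtSq2d(m))
  sa <- sdf(maskA); sb <- sdf(maskB)
  for (g in seq_len(gap)) {
    t <- g / (gap + 1)
    out[, , g] <- ((1 - t) * sa + t * sb) > 0
  }
  out
}

# 2D squared EDT to nearest TRUE cell (via the 3D kernel)
edtSq2d <- function(m) {
  a <- array(m, c(dim(m), 1L))
  edtSq(a)[, , 1]
}
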