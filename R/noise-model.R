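#' Calibrate the depth-dependent Poisson noise model of a confocal channel
#'
#' Confocal images are photon-limited: intensities follow I = alpha * N +
#' beta for a Poisson photon count N, so the intensity variance is linear in
#' the intensity, V(I) = alpha * (I - beta). Deep in a thick sample, laser
#' power and gain are increased, so alpha grows with depth; the model is
#' therefore calibrated per depth slab. Within each slab the variance of the
#' intensity between sequential z sections is computed per pixel, binned by
#' intensity, averaged per bin and fitted by a straight line with the
#' outlier-tolerant estimator.
#'
#' @param img a \linkS4class{VolumeImage} with at least 3 z planes.
#' @param nBins number of equal-width intensity bins (>= 2); bins holding
#'   fewer than \code{minBinCount} samples are dropped from the fit.
#' @param slabHeight z extent of each calibration slab in voxels; the default
#'   uses the whole stack as a single slab.
#' @param minBinCount minimum samples per retained bin.
#' @return A \linkS4class{NoiseModel}. When all bin variances vanish (e.g. a
#'   constant, noise-free image), the model is returned with
#'   \code{@failed = TRUE}.
#' @examples
#' set.seed(1)
#' n <- array(rpois(32^3, 50), c(32, 32, 32))
#' vi <- VolumeImage(2 * n + 100, spacing = 0.3)
#' estimateNoiseModel(vi)
#' @export
estimateNoiseModel <- function(img, nBins = 32L, slabHeight = NULL,
                               minBinCount = 50L) {
  a <- imgData(img)
  d <- dim(a)
  stopifnot(d[3] >= 3L, nBins >= 2L)
  if (is.null(slabHeight)) slabHeight <- d[3]
  slabHeight <- max(3L, as.integer(slabHeight))
  starts <- seq(1L, d[3], by = slabHeight)
  # merge a short trailing slab into the previous one
  if (length(starts) > 1L && d[3] - starts[length(starts)] + 1L < 3L)
    starts <- starts[-length(starts)]
  alpha <- numeric(0); beta <- numeric(0); centers <- numeric(0)
  for (s in starts) {
    e <- min(d[3], s + slabHeight - 1L)
    slab <- a[, , s:e, drop = FALSE]
    nz <- dim(slab)[3]
    dif <- slab[, , 2:nz, drop = FALSE] - slab[, , 1:(nz - 1), drop = FALSE]
    mid <- (slab[, , 2:nz, drop = FALSE] + slab[, , 1:(nz - 1),
                                                drop = FALSE]) / 2
    v <- as.numeric(dif)^2 / 2       # unbiased per-pair variance estimate
    i <- as.numeric(mid)
    rng <- range(i)
    if (diff(rng) <= 0) next
    br <- seq(rng[1], rng[2], length.out = nBins + 1L)
    bin <- findInterval(i, br, rightmost.closed = TRUE)
    cnt <- tabulate(bin, nBins)
    keep <- which(cnt >= minBinCount)
    if (length(keep) < 3L) next
    mv <- vapply(keep, function(b) mean(v[bin == b]), 0)
    mi <- vapply(keep, function(b) mean(i[bin == b]), 0)
    if (all(mv < 1e-12)) next        # noise-free slab
    fit <- fitLineOutlierTolerant(mv, x = mi)
    if (fit$slope <= 0) next
    alpha <- c(alpha, fit$slope)
    beta <- c(beta, -fit$intercept / fit$slope)
    centers <- c(centers, (s + e) / 2)
  }
  if (!length(alpha)) {
    return(new("NoiseModel", alpha = numeric(0), slabCenters = numeric(0),
               beta = NA_real_, slabHeight = slabHeight, failed = TRUE))
  }
  new("NoiseModel", alpha = alpha, slabCenters = centers,
      beta = median(beta), slabHeight = slabHeight, failed = FALSE)
}

#' Outlier-tolerant straight-line fit
#'
#' Iteratively re-weighted least squares under a heavy-tailed (Cauchy-like)
#' loss. A minority of large positive spikes (foreground structures crossing
#' a background profile) barely influence the line, so its prediction serves
#' as a background estimate.
#'
#' @param profile ordered response values (length >= 3).
#' @param variances optional per-point variances used to scale the loss;
#'   defaults to a MAD-based global scale re-estimated per iteration.
#' @param x abscissae (defaults to the sample index).
#' @param tol convergence tolerance on the parameters.
#' @param maxIter maximum IRLS iterations.
#' @return list with \code{slope}, \code{intercept}, \code{inliers} (logical:
#'   residual within 3 scale units) and \code{fitted}.
#' @examples
#' y <- 2 + 0.5 * (1:20); y[c(4, 9)] <- y[c(4, 9)] + 50
#' fitLineOutlierTolerant(y)$slope
#' @export
fitLineOutlierTolerant <- function(profile, variances = NULL,
                                   x = seq_along(profile), tol = 1e-6,
                                   maxIter = 100L) {
  y <- as.numeric(profile)
  n <- length(y)
  if (n < 3L) stop("profile must hold at least 3 points")
  w <- rep(1, n)
  b <- c(0, 0)
  for (it in seq_len(maxIter)) {
    sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
    sxx <- sum(w * x * x); sxy <- sum(w * x * y)
    det <- sw * sxx - sx^2
    if (abs(det) < 1e-300) break
    slope <- (sw * sxy - sx * sy) / det
    inter <- (sy * sxx - sx * sxy) / det
    r <- y - inter - slope * x
    if (is.null(variances)) {
      sc <- mad(r)
      if (sc < 1e-12) sc <- max(sd(r), 1e-12)
    } else {
      sc <- sqrt(pmax(variances, 1e-12))
    }
    w <- 1 / (1 + (r / (2.385 * sc))^2)
    if (max(abs(c(slope, inter) - b)) < tol * (1 + max(abs(b)))) {
      b <- c(slope, inter); break
    }
    b <- c(slope, inter)
  }
  r <- y - b[2] - b[1] * x
  sc <- if (is.null(variances)) max(mad(r), 1e-12)
        else sqrt(pmax(variances, 1e-12))
  list(slope = b[1], intercept = b[2], inliers = abs(r) <= 3 * sc,
       fitted = b[2] + b[1] * x)
}

# alpha(z): piecewise-linear over slab centres, clamped at the end slabs
alphaAt <- function(model, z) {
  if (model@failed) stop("noise model calibration failed")
  if (length(model@alpha) == 1L) return(rep(model@alpha, length(z)))
  approx(model@slabCenters, model@alpha, xout = z, rule = 2)$y
}

# predicted variance at intensity I and depth z (voxel index)
noiseVariance <- function(model, intensity, z) {
  pmax(alphaAt(model, z) * (intensity - model@beta), 0)
}

#' Bayesian foreground/background de-noising (BFBD)
#'
#' Exploits the axial elongation of the confocal point spread function: for
#' every x-y pixel the z profile of the background is locally linear. A
#' sliding-window outlier-tolerant line fit along z estimates the background;
#' the residual above \code{threshold} noise units (sqrt of the predicted
#' Poisson variance) is retained as foreground; background and foreground are
#' independently smoothed and summed.
#'
#' @param img de-noising target, a \linkS4class{VolumeImage}.
#' @param model calibrated \linkS4class{NoiseModel} for this channel.
#' @param window sliding-window length (z pixels) for the background fit.
#' @param threshold foreground acceptance threshold in noise-sigma units.
#' @param smoothSigma Gaussian sigma (voxels) applied independently to the
#'   separated background and foreground.
#' @return the de-noised \linkS4class{VolumeImage} (non-negative).
#' @export
bfbdDenoise <- function(img, model, window = 5L, threshold = 1.25,
                        smoothSigma = 0.5) {
  if (model@failed) stop("noise model is not calibrated")
  a <- imgData(img)
  d <- dim(a)
  nz <- d[3]
  window <- max(3L, as.integer(window))
  ncol3 <- d[1] * d[2]
  prof <- matrix(a, nrow = ncol3, ncol = nz)   # columns of constant z
  alphaZ <- alphaAt(model, seq_len(nz))
  bg <- matrix(.bfbd_background(as.numeric(a), d, window, alphaZ,
                                model@beta, 8L), ncol3, nz)
  fgRes <- prof - bg
  V <- noiseVariance(model, prof, matrix(rep(seq_len(nz), each = ncol3),
                                         ncol3, nz))
  fg <- ifelse(fgRes > threshold * sqrt(pmax(V, 1e-12)), fgRes, 0)
  bgArr <- array(bg, dim = d)
  fgArr <- array(fg, dim = d)
  out <- gaussSmooth(bgArr, smoothSigma) + gaussSmooth(fgArr, smoothSigma)
  out[out < 0] <- 0
  withData(img, out)
}
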