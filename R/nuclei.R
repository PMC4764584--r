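#' Minimum-volume enclosing ellipsoid of a point cloud
#'
#' Khachiyan's iterative barycentric scheme for the minimum-volume ellipsoid
#' \{p : (p - c)' E (p - c) <= 1\} enclosing the points within the stated
#' tolerance.
#'
#' @param points n x 3 matrix of coordinates (µm), n >= 10, not coplanar.
#' @param tol enclosure tolerance.
#' @param maxIter iteration cap.
#' @param maxPoints dense clouds are subsampled (deterministic stride) to
#'   this size before fitting; the enclosing ellipsoid of a dense surface
#'   sample is unaffected in practice.
#' @return an \linkS4class{Ellipsoid}.
#' @export
fitMinVolumeEllipsoid <- function(points, tol = 1e-3, maxIter = 1000L,
                                  maxPoints = 600L) {
  P <- as.matrix(points)
  n <- nrow(P)
  if (n < 10L) stop("need at least 10 points")
  if (n > maxPoints) {
    P <- P[unique(round(seq(1, n, length.out = maxPoints))), , drop = FALSE]
    n <- nrow(P)
  }
  if (qr(sweep(P, 2, colMeans(P)))$rank < 3L) stop("points are coplanar")
  Q <- t(cbind(P, 1))                    # 4 x n
  u <- rep(1 / n, n)
  for (it in seq_len(maxIter)) {
    X <- Q %*% (u * t(Q))                # 4 x 4
    M <- colSums(Q * (solve(X) %*% Q))   # Mahalanobis distances
    j <- which.max(M)
    mx <- M[j]
    step <- (mx - 4) / (4 * (mx - 1))
    if (mx <= 4 * (1 + tol)) break
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  ctr <- as.numeric(t(P) %*% u)
  S <- t(P) %*% (u * P) - ctr %*% t(ctr)
  E <- solve(S) / 3
  E <- (E + t(E)) / 2
  ell <- new("Ellipsoid", c = ctr, E = E)
  # rescale so the enclosure constraint holds exactly at the farthest point
  mx <- max(ellipsoidQF(ell, P))
  if (mx > 1) ell@E <- E / mx
  ell
}

#' @rdname accessors
#' @export
setMethod("semiAxes", "Ellipsoid", function(x) {
  ev <- eigen(x@E, symmetric = TRUE, only.values = TRUE)$values
  sort(1 / sqrt(ev), decreasing = TRUE)
})

setMethod("show", "Ellipsoid", function(object) {
  ax <- semiAxes(object)
  cat(sprintf("Ellipsoid: centre (%.2f, %.2f, %.2f), semi-axes %.2f/%.2f/%.2f um\n",
              object@c[1], object@c[2], object@c[3], ax[1], ax[2], ax[3]))
})

# ellipsoid quadratic form values for points
ellipsoidQF <- function(ell, P) {
  D <- sweep(as.matrix(P), 2, ell@c)
  rowSums((D %*% ell@E) * D)
}

#' Mean square error of an ellipsoid model on mesh vertices
#'
#' MSE = 1/(n - 9) * sum_i ((p_i - c)' E (p_i - c) - 1)^2, the 9 accounting
#' for the ellipsoid parameters. For a double model each vertex is scored
#' against the nearer of the two ellipsoids (smaller |QF - 1|).
#'
#' @param mesh \linkS4class{TriangleMesh} whose vertices are scored (n > 9).
#' @param model an \linkS4class{Ellipsoid} or a list of two.
#' @return scalar MSE.
#' @export
ellipsoidFitMSE <- function(mesh, model) {
  P <- mesh@vertices
  n <- nrow(P)
  if (n <= 9L) stop("need more than 9 vertices")
  if (is(model, "Ellipsoid")) model <- list(model)
  devs <- vapply(model, function(e) (ellipsoidQF(e, P) - 1)^2, numeric(n))
  sum(apply(as.matrix(devs), 1, min)) / (n - 9)
}

# fit the two-ellipsoid model: split the vertex cloud symmetrically by the
# plane through the centroid normal to the principal axis and fit each half.
# No nearest-ellipsoid reassignment is applied: with reassignment the two
# ellipsoids hug the two hemispheres of a genuine single nucleus and the
# double model spuriously wins the model selection.
fitDoubleEllipsoid <- function(mesh) {
  P <- mesh@vertices
  ctr <- colMeans(P)
  pc <- eigen(cov(P), symmetric = TRUE)$vectors[, 1]
  side <- as.numeric(sweep(P, 2, ctr) %*% pc) > 0
  if (sum(side) < 10L || sum(!side) < 10L) return(NULL)
  a <- try(fitMinVolumeEllipsoid(P[side, , drop = FALSE]), silent = TRUE)
  b <- try(fitMinVolumeEllipsoid(P[!side, , drop = FALSE]), silent = TRUE)
  if (inherits(a, "try-error") || inherits(b, "try-error")) return(NULL)
  list(a, b)
}

#' Classify nucleus objects as mono-, double- or multi-nuclear
#'
#' The natural logarithms of the per-object best-model MSEs (single vs
#' double ellipsoid) are fitted by a two-component Gaussian mixture; the
#' split threshold is the upper 95% confidence limit (mean + 1.96 sd) of the
#' low-MSE component. Objects below the threshold keep their best-model
#' label (mono or double); objects above are multi-nuclear.
#'
#' @param lnMse numeric vector of ln(MSE) for all objects (>= 30 for a
#'   stable mixture fit).
#' @param bestModel character vector, "mono"/"double", same length.
#' @return list with \code{threshold}, \code{multiplicity} (character
#'   vector), \code{fallback} (logical: degenerate mixture, single-Gaussian
#'   quantile rule used).
#' @export
classifyMultiplicity <- function(lnMse, bestModel = NULL) {
  x <- as.numeric(lnMse)
  if (is.null(bestModel)) bestModel <- rep("mono", length(x))
  fit <- gaussianMixture1d(x, k = 2L)
  fallback <- FALSE
  if (length(x) < 4L) {
    # too few objects for any distributional rule: keep best-model labels
    return(list(threshold = max(x), multiplicity = bestModel,
                fallback = TRUE))
  }
  if (is.null(fit) || min(fit$weight) < 0.02 || any(!is.finite(fit$sd)) ||
      any(fit$sd < 1e-8)) {
    fallback <- TRUE
    thr <- mean(x) + 1.96 * max(sd(x), 1e-8)
  } else {
    first <- which.min(fit$mean)
    thr <- fit$mean[first] + 1.96 * fit$sd[first]
  }
  mult <- ifelse(x <= thr, bestModel, "multi")
  list(threshold = thr, multiplicity = mult, fallback = fallback)
}

# small deterministic 1-D EM for a k-component Gaussian mixture
gaussianMixture1d <- function(x, k = 2L, maxIter = 200L, tol = 1e-8) {
  n <- length(x)
  if (n < 2L * k || sd(x) < 1e-12) return(NULL)
  qs <- quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  mu <- qs
  sg <- rep(sd(x) / k, k)
  w <- rep(1 / k, k)
  ll0 <- -Inf
  for (it in seq_len(maxIter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * dnorm(x, mu[j], pmax(sg[j], 1e-8)),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    r <- dens / tot
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sg <- sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk)
    ll <- sum(log(tot))
    if (abs(ll - ll0) < tol * (1 + abs(ll))) break
    ll0 <- ll
  }
  list(mean = mu, sd = sg, weight = w, loglik = ll0)
}

#' Nuclei seeds from the Laplacian-of-Gaussian scale-space maximum projection
#'
#' LoGMP(x) = max over sigma in [sigmaMin, sigmaMax] of the scale-normalized
#' negative Laplacian-of-Gaussian response; local maxima above a relative
#' threshold are seeds. Blob radius r and scale relate as r = sqrt(2) sigma,
#' so the sigma range is set from the expected nucleus radii.
#'
#' @param img DAPI \linkS4class{VolumeImage} (de-noised).
#' @param sigmaMin,sigmaMax scale range in µm (sigmaMin < sigmaMax).
#' @param nScales number of logarithmically spaced scales.
#' @param relThreshold seeds must exceed this fraction of the global LoGMP
#'   maximum.
#' @param mask optional logical array restricting seeds.
#' @return matrix of seed positions (µm), zero rows when none.
#' @export
logmpSeeds <- function(img, sigmaMin, sigmaMax, nScales = 5L,
                       relThreshold = 0.1, mask = NULL) {
  if (sigmaMin >= sigmaMax) stop("sigmaMin must be below sigmaMax")
  a <- imgData(img)
  sp <- voxelSpacing(img)
  d <- dim(a)
  sigmas <- exp(seq(log(sigmaMin), log(sigmaMax), length.out = nScales))
  logmp <- array(-Inf, d)
  for (s in sigmas) {
    sm <- gaussSmooth(a, s / sp)
    lap <- discreteLaplacian(sm, sp)
    resp <- -s^2 * lap                  # scale-normalized, bright blobs > 0
    logmp <- pmax(logmp, resp)
  }
  # light smoothing of the scale-space projection removes the plateau
  # multi-maxima that sharp-edged blobs produce
  logmp <- gaussSmooth(logmp, sigmaMin / (3 * sp))
  mx <- max(logmp)
  if (!is.finite(mx) || mx <= 0) return(matrix(numeric(0), 0, 3))
  lm <- array(.local_maxima3d(as.numeric(logmp), d, relThreshold * mx), d)
  if (!is.null(mask)) lm <- lm & mask
  if (!any(lm)) return(matrix(numeric(0), 0, 3))
  pts <- voxelCoords(lm, d, sp)
  resp <- logmp[lm]
  # non-maximum suppression: one seed per blob of the smallest scale
  ord <- order(resp, decreasing = TRUE)
  keep <- integer(0)
  minDist <- 1.2 * sqrt(2) * sigmaMin
  for (i in ord) {
    if (!length(keep) ||
        all(sqrt(rowSums(sweep(pts[keep, , drop = FALSE], 2,
                               pts[i, ])^2)) > minDist))
      keep <- c(keep, i)
  }
  pts[keep, , drop = FALSE]
}

discreteLaplacian <- function(a, sp) {
  d <- dim(a)
  l <- array(0, d)
  ax <- function(arr, axis, h) {
    out <- array(0, dim(arr))
    idx <- seq_len(dim(arr)[axis])
    n <- length(idx)
    if (axis == 1) out[2:(n - 1), , ] <-
        (arr[3:n, , ] - 2 * arr[2:(n - 1), , ] + arr[1:(n - 2), , ]) / h^2
    if (axis == 2) out[, 2:(n - 1), ] <-
        (arr[, 3:n, ] - 2 * arr[, 2:(n - 1), ] + arr[, 1:(n - 2), ]) / h^2
    if (axis == 3) out[, , 2:(n - 1)] <-
        (arr[, , 3:n] - 2 * arr[, , 2:(n - 1)] + arr[, , 1:(n - 2)]) / h^2
    out
  }
  ax(a, 1, sp[1]) + ax(a, 2, sp[2]) + ax(a, 3, sp[3])
}

#' Split a double- or multi-nuclear object into individual nuclei
#'
#' Doubles are split by their fitted two-ellipsoid model (each voxel of the
#' object goes to the nearer ellipsoid); multis are seeded by LoGMP maxima
#' inside the object and split by nearest-seed assignment of the object
#' voxels, equivalent to a simultaneous active-mesh expansion from the seeds
#' limited by the object border and by the meshes meeting each other. Mono
#' objects are returned unchanged.
#'
#' @param obj a \linkS4class{NucleusObject}.
#' @param dapi the DAPI \linkS4class{VolumeImage} the object was segmented
#'   from.
#' @param objMask logical array of the object's voxels.
#' @param sigmaRange LoG scale range (µm) for multi-nucleus seeding; default
#'   derives from nucleus radii 3.5-5.5 µm via sigma = r/sqrt(2).
#' @param seedOverride when TRUE, a mono-labelled object containing two or
#'   more scale-matched LoGMP maxima is split anyway (blur can fill the
#'   neck between touching nuclei so thoroughly that the ellipsoid model
#'   selection reads the pair as one nucleus); off by default, enabled by
#'   the \code{\link{splitNuclei}} pipeline.
#' @return list of \linkS4class{NucleusObject}s (the input when mono); an
#'   attribute \code{"flagged"} marks splits with fewer seeds than expected.
#' @export
splitMultinucleus <- function(obj, dapi, objMask,
                              sigmaRange = c(3.5, 5.5) / sqrt(2),
                              seedOverride = FALSE) {
  sp <- voxelSpacing(dapi)
  d <- dim(objMask)
  idx <- which(objMask)
  co <- voxelCoords(idx, d, sp)
  parts <- NULL
  flagged <- FALSE
  # LoGMP seeds within the object's bounding box (plus margin)
  bb <- maskBoundingBox(objMask)
  mar <- 4L
  xs <- max(1, min(bb$x) - mar):min(d[1], max(bb$x) + mar)
  ys <- max(1, min(bb$y) - mar):min(d[2], max(bb$y) + mar)
  zs <- max(1, min(bb$z) - mar):min(d[3], max(bb$z) + mar)
  subImg <- VolumeImage(imgData(dapi)[xs, ys, zs], spacing = sp)
  seeds <- logmpSeeds(subImg, sigmaRange[1], sigmaRange[2],
                      mask = objMask[xs, ys, zs])
  if (nrow(seeds))
    seeds <- sweep(seeds, 2, (c(xs[1], ys[1], zs[1]) - 1) * sp, "+")
  mult <- obj@multiplicity
  # blur can fill the neck between touching nuclei so thoroughly that the
  # ellipsoid model selection reads the pair as one nucleus; two or more
  # scale-matched LoGMP maxima inside one object override that call
  if (mult == "mono") {
    if (!seedOverride || nrow(seeds) < 2L) return(list(obj))
    mult <- if (nrow(seeds) == 2L) "double" else "multi"
  }
  if (mult == "double" && nrow(seeds) <= 2L) {
    # a "double" that seeds three or more blobs is treated as multi
    mdl <- fitDoubleEllipsoid(obj@mesh)
    if (!is.null(mdl)) {
      da <- mahalanobisRatio(mdl[[1]], co)
      db <- mahalanobisRatio(mdl[[2]], co)
      parts <- ifelse(da <= db, 1L, 2L)
      if (length(unique(parts)) < 2L) parts <- NULL
    }
  }
  if (is.null(parts)) {                 # multi (or failed double model)
    if (nrow(seeds) < 2L) {
      flagged <- TRUE
      out <- list(obj)
      attr(out, "flagged") <- TRUE
      return(out)
    }
    dd <- vapply(seq_len(nrow(seeds)), function(s)
      (co[, 1] - seeds[s, 1])^2 + (co[, 2] - seeds[s, 2])^2 +
        (co[, 3] - seeds[s, 3])^2, numeric(nrow(co)))
    parts <- max.col(-dd)
  }
  out <- list()
  ci <- arrayInd(idx, d)
  for (p in sort(unique(parts))) {
    sel <- parts == p
    if (sum(sel) < 20L) next
    lo <- pmax(apply(ci[sel, , drop = FALSE], 2, min) - 2L, 1L)
    hi <- pmin(apply(ci[sel, , drop = FALSE], 2, max) + 2L, d)
    sub <- array(FALSE, hi - lo + 1L)
    sub[sweep(ci[sel, , drop = FALSE], 2, lo - 1L)] <- TRUE
    # keep the largest connected piece
    sublab <- labelComponents(sub, 26L)
    if (max(sublab) > 1L)
      sub <- sublab == which.max(tabulate(sublab))
    mesh <- meshFromCrop(sub, lo, sp)
    if (is.null(mesh)) next
    out[[length(out) + 1L]] <- new("NucleusObject", mesh = mesh,
                                   multiplicity = "mono",
                                   dapiIntegral = dapiIntegralCrop(mesh,
                                                                   dapi),
                                   seed = colMeans(co[sel, , drop = FALSE]))
  }
  attr(out, "flagged") <- flagged
  out
}

# integral intensity inside a mesh, evaluated on the mesh's bounding crop
dapiIntegralCrop <- function(mesh, dapi) {
  a <- imgData(dapi)
  sp <- voxelSpacing(dapi)
  d <- dim(a)
  vox <- sweep(mesh@vertices, 2, sp, "/")
  lo <- pmax(floor(apply(vox, 2, min)) - 1L, 1L)
  hi <- pmin(ceiling(apply(vox, 2, max)) + 1L, d)
  m <- meshToCrop(mesh, as.integer(lo), as.integer(hi), sp)
  sum(a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]][m])
}

# relative Mahalanobis distance to an ellipsoid (QF value; <=1 is inside)
mahalanobisRatio <- function(ell, P) ellipsoidQF(ell, P)

#' Integral DAPI intensity inside a mesh
#'
#' Sum of the intensities of the voxels whose centres lie inside the closed
#' mesh; proportional to the DNA content of the nucleus.
#'
#' @param mesh closed \linkS4class{TriangleMesh}.
#' @param dapi DAPI \linkS4class{VolumeImage}.
#' @return scalar intensity sum (a.u.).
#' @export
dapiIntegral <- function(mesh, dapi) {
  if (nrow(mesh@triangles) < 4L) stop("mesh is not closed")
  a <- imgData(dapi)
  m <- meshToMask(mesh, dim(a), voxelSpacing(dapi))
  sum(a[m])
}

#' Align a DAPI-integral histogram onto a reference by axis stretching
#'
#' Finds the scale factor s that minimizes the quadratic mismatch between
#' the reference histogram f0(x) and the stretched sample histogram fj(s x)
#' (grid search refined by golden-section optimization). Used to make DAPI
#' integrals comparable across samples.
#'
#' @param referenceHist,sampleHist objects with \code{$mids} and
#'   \code{$counts} (densities are formed internally), e.g. from
#'   \code{\link[graphics]{hist}}.
#' @param sRange search interval for the scale factor.
#' @return the scale factor s mapping sample intensities onto the reference
#'   axis (sample x reference-equivalent = x / s).
#' @export
normalizeDapi <- function(referenceHist, sampleHist, sRange = c(0.5, 2)) {
  f0 <- referenceHist$counts / sum(referenceHist$counts)
  x0 <- referenceHist$mids
  fj <- sampleHist$counts / sum(sampleHist$counts)
  xj <- sampleHist$mids
  mismatch <- function(s) {
    fs <- approx(xj / s, fj, xout = x0, rule = 1)$y
    if (all(is.na(fs))) return(NA_real_)
    fs[is.na(fs)] <- 0
    sum((f0 - fs)^2)
  }
  grid <- seq(sRange[1], sRange[2], length.out = 151L)
  vals <- vapply(grid, mismatch, 0)
  if (all(is.na(vals))) stop("histogram supports never overlap")
  g0 <- grid[which.min(vals)]
  lo <- max(sRange[1], g0 - 0.02); hi <- min(sRange[2], g0 + 0.02)
  optimize(mismatch, c(lo, hi))$minimum
}
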