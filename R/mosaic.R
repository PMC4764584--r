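#' Normalized cross-correlation shift between two volumes
#'
#' Direct search over integer shifts: for every candidate shift of \code{b}
#' relative to \code{a}, the Pearson correlation of the overlap is computed;
#' overlaps smaller than 8^3 voxels are invalid.
#'
#' @param a,b \linkS4class{VolumeImage}s (or 3D arrays).
#' @param search shift search half-width per axis (scalar or length 3).
#' @param center search centre (offset of b in a), default the origin.
#' @return list with \code{shift} (the offset of b maximizing the NCC),
#'   \code{peak} correlation, and \code{map} (the correlation array).
#' @export
nccShift <- function(a, b, search = 8L, center = c(0L, 0L, 0L)) {
  av <- if (is(a, "VolumeImage")) imgData(a) else a
  bv <- if (is(b, "VolumeImage")) imgData(b) else b
  if (length(search) == 1L) search <- rep(search, 3L)
  sx <- center[1] + (-search[1]:search[1])
  sy <- center[2] + (-search[2]:search[2])
  sz <- center[3] + (-search[3]:search[3])
  v <- .ncc_search(as.numeric(av), dim3(av), as.numeric(bv), dim3(bv),
                   as.integer(sx), as.integer(sy), as.integer(sz), 512)
  map <- array(v, c(length(sx), length(sy), length(sz)))
  if (all(is.na(map))) stop("no candidate shift leaves an overlap of 8^3")
  best <- which.max(ifelse(is.na(map), -Inf, map))
  bi <- arrayInd(best, dim(map))
  list(shift = c(sx[bi[1]], sy[bi[2]], sz[bi[3]]), peak = map[best],
       map = map)
}

#' Create a tile-grid object for mosaicking
#'
#' @param tiles an N x M list-matrix (or list of lists) of
#'   \linkS4class{VolumeImage}s.
#' @param nominalOverlap declared fractional overlap between neighbouring
#'   tiles (about 0.10).
#' @return a \code{tileGrid} list with nominal tile positions.
#' @export
tileGrid <- function(tiles, nominalOverlap = 0.10) {
  if (!is.matrix(tiles)) tiles <- matrix(tiles, nrow = length(tiles))
  d <- dim3(imgData(tiles[[1, 1]]))
  nomPos <- array(0, c(nrow(tiles), ncol(tiles), 3))
  for (i in seq_len(nrow(tiles))) for (j in seq_len(ncol(tiles))) {
    nomPos[i, j, ] <- c(round((i - 1) * d[1] * (1 - nominalOverlap)),
                        round((j - 1) * d[2] * (1 - nominalOverlap)), 0)
  }
  structure(list(tiles = tiles, nominalOverlap = nominalOverlap,
                 positions = nomPos), class = "tileGrid")
}

#' Optimize tile positions by maximizing the summed neighbour correlations
#'
#' Greedy block-coordinate ascent on the global metric G (the sum of the
#' normalized cross-correlations of all neighbouring tile pairs at their
#' relative shifts), seeded at the nominal overlap positions; the first tile
#' is anchored at the origin. Convergence when no tile move improves G.
#'
#' @param grid a \code{\link{tileGrid}}.
#' @param search per-axis search half-width (voxels) around the current
#'   position per sweep.
#' @param maxSweeps sweep budget.
#' @return the grid with optimized \code{$positions} and the achieved
#'   \code{$G}.
#' @export
optimizeTileShifts <- function(grid, search = 6L, maxSweeps = 10L) {
  tiles <- grid$tiles
  N <- nrow(tiles); M <- ncol(tiles)
  pos <- grid$positions
  if (N * M == 1L) { grid$positions[1, 1, ] <- 0; grid$G <- 0; return(grid) }
  neighbors <- function(i, j) {
    nb <- list()
    for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      i2 <- i + dd[1]; j2 <- j + dd[2]
      if (i2 >= 1 && i2 <= N && j2 >= 1 && j2 <= M)
        nb[[length(nb) + 1L]] <- c(i2, j2)
    }
    nb
  }
  pairNcc <- function(i, j, i2, j2, p) {
    rel <- round(pos[i2, j2, ] - p)
    r <- try(nccShift(tiles[[i, j]], tiles[[i2, j2]], search = 0L,
                      center = rel), silent = TRUE)
    if (inherits(r, "try-error")) NA_real_ else r$peak
  }
  tileScore <- function(i, j, p) {
    s <- vapply(neighbors(i, j), function(nb)
      pairNcc(i, j, nb[1], nb[2], p), 0)
    if (all(is.na(s))) stop(sprintf("tile (%d,%d) has no valid neighbour correlation",
                                    i, j))
    sum(s, na.rm = TRUE)
  }
  for (sweep in seq_len(maxSweeps)) {
    moved <- FALSE
    for (i in seq_len(N)) for (j in seq_len(M)) {
      if (i == 1L && j == 1L) next                  # anchor
      cur <- pos[i, j, ]
      best <- tileScore(i, j, cur); bestP <- cur
      for (dx in -search:search) for (dy in -search:search)
        for (dz in -1:1) {
          p <- cur + c(dx, dy, dz)
          sc <- tryCatch(tileScore(i, j, p), error = function(e) -Inf)
          if (sc > best + 1e-9) { best <- sc; bestP <- p }
        }
      if (any(bestP != cur)) { pos[i, j, ] <- bestP; moved <- TRUE }
    }
    if (!moved) break
  }
  grid$positions <- pos
  # global metric over unique neighbour pairs
  G <- 0
  for (i in seq_len(N)) for (j in seq_len(M)) {
    for (dd in list(c(1, 0), c(0, 1))) {
      i2 <- i + dd[1]; j2 <- j + dd[2]
      if (i2 > N || j2 > M) next
      v <- pairNcc(i2, j2, i, j, pos[i2, j2, ])
      if (!is.na(v)) G <- G + v
    }
  }
  grid$G <- G
  grid
}

#' Blend a positioned tile grid into one mosaic
#'
#' Multi-band blending: each tile is decomposed into frequency bands
#' (differences of Gaussians) and the bands are combined with
#' correspondingly smoothed linear feathering weights, restricted to each
#' tile's footprint, so low frequencies blend over wide seams and high
#' frequencies over narrow ones. Voxels covered by a single tile are
#' preserved exactly.
#'
#' @param grid an optimized \code{\link{tileGrid}}.
#' @param bands number of frequency bands.
#' @return mosaic \linkS4class{VolumeImage}.
#' @export
blendMosaic <- function(grid, bands = 4L) {
  tiles <- grid$tiles
  pos <- round(grid$positions)
  if (min(pos) < 0) pos <- sweep(pos, 3, apply(pos, 3, min))
  d1 <- dim3(imgData(tiles[[1, 1]]))
  ext <- c(0, 0, 0)
  for (i in seq_len(nrow(tiles))) for (j in seq_len(ncol(tiles)))
    ext <- pmax(ext, pos[i, j, ] + dim3(imgData(tiles[[i, j]])))
  sig <- 2^(seq_len(bands - 1L) - 1L)            # 1, 2, 4 ...
  num <- array(0, ext); den <- array(0, ext)
  acc <- vector("list", bands)
  for (k in seq_len(bands)) acc[[k]] <- list(num = array(0, ext),
                                             den = array(0, ext))
  for (i in seq_len(nrow(tiles))) for (j in seq_len(ncol(tiles))) {
    a <- imgData(tiles[[i, j]])
    dt <- dim3(a)
    w <- feather3d(dt)
    # band decomposition
    sm <- list(a)
    for (k in seq_along(sig)) sm[[k + 1L]] <- gaussSmooth(a, sig[k])
    bandsT <- list()
    for (k in seq_len(bands - 1L)) bandsT[[k]] <- sm[[k]] - sm[[k + 1L]]
    bandsT[[bands]] <- sm[[bands]]
    wS <- list(w)
    for (k in seq_along(sig)) wS[[k + 1L]] <- gaussSmooth(w, sig[k])
    sl <- lapply(seq_len(3), function(ax)
      (pos[i, j, ax] + 1):(pos[i, j, ax] + dt[ax]))
    for (k in seq_len(bands)) {
      wk <- wS[[min(k, length(wS))]]
      acc[[k]]$num[sl[[1]], sl[[2]], sl[[3]]] <-
        acc[[k]]$num[sl[[1]], sl[[2]], sl[[3]]] + wk * bandsT[[k]]
      acc[[k]]$den[sl[[1]], sl[[2]], sl[[3]]] <-
        acc[[k]]$den[sl[[1]], sl[[2]], sl[[3]]] + wk
    }
  }
  out <- array(0, ext)
  for (k in seq_len(bands)) {
    dk <- acc[[k]]$den
    add <- acc[[k]]$num / ifelse(dk > 1e-12, dk, 1)
    add[dk <= 1e-12] <- 0
    out <- out + add
  }
  VolumeImage(out, spacing = voxelSpacing(tiles[[1, 1]]),
              channel = channelName(tiles[[1, 1]]))
}

# separable linear feather ramp (1 at the centre, ~0 at the faces)
feather3d <- function(d) {
  ramp <- function(n) {
    x <- seq_len(n)
    pmin(x, n + 1 - x) / ((n + 1) / 2)
  }
  outer(outer(ramp(d[1]), ramp(d[2])), ramp(d[3]))
}

#' Rigid registration of a high-resolution image into its context
#'
#' Registers \code{moving} inside \code{fixed} by a z-axis rotation plus a
#' 3D shift, using a three-level scale pyramid (factors 0.25, 0.50, 1):
#' a coarse rotation sweep (within ±\code{rotRange} degrees) initializes r,
#' then shift-by-NCC and rotation-by-polar-NCC refinements alternate up the
#' pyramid.
#'
#' @param moving,fixed \linkS4class{VolumeImage}s on the same voxel grid
#'   scale.
#' @param rotRange initial rotation bracket (degrees).
#' @param floor minimum acceptable peak correlation; below it a no-match
#'   error is raised.
#' @param iters refinement iterations per pyramid level.
#' @return list with \code{rotation} (degrees about z), \code{translation}
#'   (voxels of the fixed grid) and \code{score} (peak NCC).
#' @export
registerRigidPolar <- function(moving, fixed, rotRange = 15, floor = 0.25,
                               iters = 3L) {
  mv <- imgData(moving); fx <- imgData(fixed)
  lvls <- c(4L, 2L, 1L)
  rot <- 0
  shift <- c(0, 0, 0)
  score <- NA_real_
  first <- TRUE
  for (f in lvls) {
    m <- downsampleVolume(mv, f)
    x <- downsampleVolume(fx, f)
    if (first) {
      best <- -Inf
      for (r in seq(-rotRange, rotRange, by = 2.5)) {
        mr <- rotateVolumeZ(m, r)
        sc <- try(nccShift(x, mr, search = max(4L, dim(x)[1] %/% 4)),
                  silent = TRUE)
        if (inherits(sc, "try-error")) next
        if (sc$peak > best) { best <- sc$peak; rot <- r
                              shift <- sc$shift * f }
      }
      first <- FALSE
    }
    for (it in seq_len(iters)) {
      mr <- rotateVolumeZ(m, rot)
      sc <- try(nccShift(x, mr, search = 4L,
                         center = round(shift / f)), silent = TRUE)
      if (!inherits(sc, "try-error")) {
        shift <- sc$shift * f
        score <- sc$peak
      }
      dRot <- polarRotationUpdate(x, mr, round(shift / f))
      rot <- rot + dRot
      if (abs(dRot) < 0.1) break
    }
  }
  if (is.na(score) || score < floor)
    stop(sprintf("no match: peak correlation %.3f below floor %.2f",
                 ifelse(is.na(score), 0, score), floor))
  list(rotation = rot, translation = shift, score = score)
}

downsampleVolume <- function(a, f) {
  if (f == 1L) return(a)
  d <- dim(a)
  nd <- d %/% f
  a <- a[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f),
         drop = FALSE]
  # block mean
  dim(a) <- c(f, nd[1], f, nd[2], f, nd[3])
  out <- apply(a, c(2, 4, 6), mean)
  out
}

# rotate each z slice about the volume centre by `deg` (bilinear)
rotateVolumeZ <- function(a, deg) {
  d <- dim(a)
  th <- deg * pi / 180
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  xg <- matrix(seq_len(d[1]), d[1], d[2])
  yg <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  xs <- cx + cos(th) * (xg - cx) - sin(th) * (yg - cy)
  ys <- cy + sin(th) * (xg - cx) + cos(th) * (yg - cy)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 1 & x0 < d[1] & y0 >= 1 & y0 < d[2]
  out <- array(0, d)
  for (z in seq_len(d[3])) {
    sl <- a[, , z]
    g <- function(ix, iy) sl[cbind(as.numeric(pmin(pmax(ix, 1), d[1])),
                                   as.numeric(pmin(pmax(iy, 1), d[2])))]
    v <- g(x0, y0) * (1 - fx) * (1 - fy) + g(x0 + 1, y0) * fx * (1 - fy) +
      g(x0, y0 + 1) * (1 - fx) * fy + g(x0 + 1, y0 + 1) * fx * fy
    v[!ok] <- 0
    out[, , z] <- v
  }
  out
}

# rotation update from the angular NCC of polar-transformed z projections
polarRotationUpdate <- function(fixed, moving, shift) {
  d <- dim(fixed)
  # overlap crop after shift
  x0 <- max(0, shift[1]); x1 <- min(d[1], dim(moving)[1] + shift[1])
  y0 <- max(0, shift[2]); y1 <- min(d[2], dim(moving)[2] + shift[2])
  if (x1 - x0 < 8 || y1 - y0 < 8) return(0)
  fSl <- apply(fixed[(x0 + 1):x1, (y0 + 1):y1, , drop = FALSE], c(1, 2), sum)
  mSl <- apply(moving[(x0 + 1 - shift[1]):(x1 - shift[1]),
                      (y0 + 1 - shift[2]):(y1 - shift[2]), , drop = FALSE],
               c(1, 2), sum)
  nTheta <- 360L
  pf <- polarProfile(fSl, nTheta)
  pm <- polarProfile(mSl, nTheta)
  # circular cross-correlation over theta
  best <- 0L; bestV <- -Inf
  for (s in -30:30) {
    v <- sum(pf * rotVec(pm, s))
    if (v > bestV) { bestV <- v; best <- s }
  }
  -best * 360 / nTheta
}

polarProfile <- function(m, nTheta) {
  d <- dim(m)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  rmax <- min(cx, cy) - 1
  rs <- seq(2, rmax, length.out = 24L)
  th <- seq(0, 2 * pi, length.out = nTheta + 1L)[-(nTheta + 1L)]
  prof <- numeric(nTheta)
  for (i in seq_along(th)) {
    xs <- cx + rs * cos(th[i]); ys <- cy + rs * sin(th[i])
    x0 <- pmin(pmax(round(xs), 1), d[1]); y0 <- pmin(pmax(round(ys), 1), d[2])
    prof[i] <- sum(m[cbind(x0, y0)] * rs)
  }
  prof <- prof - mean(prof)
  n <- sqrt(sum(prof^2))
  if (n > 0) prof / n else prof
}

rotVec <- function(v, s) {
  n <- length(v)
  v[((seq_len(n) - 1 + s) %% n) + 1]
}
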