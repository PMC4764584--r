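#' Morphometric statistics of a tubular network
#'
#' Volume fraction (from the cylinder approximation of the edges), length
#' density, mean radius, branch angles (between unit tangents of the edges
#' incident at each node, averaged over the first \code{tangentLength} µm
#' from the node), node-cardinality histogram and node density.
#'
#' @param graph a \linkS4class{NetworkGraph}.
#' @param tissueVolume reference tissue volume in mm^3.
#' @param tangentLength polyline length (µm) over which edge tangents are
#'   averaged.
#' @return list with \code{Ls} (mm/mm^3), \code{rs} (mm), \code{Vs}
#'   (dimensionless, cylinder approximation), \code{branchAngles} (degrees),
#'   \code{cardinality} (table), \code{nodeDensity} (mm^-3),
#'   \code{totalLength} (µm).
#' @export
networkStats <- function(graph, tissueVolume, tangentLength = 5) {
  e <- graphEdges(graph)
  n <- graphNodes(graph)
  if (!nrow(e)) {
    return(list(Ls = 0, rs = 0, Vs = 0, branchAngles = numeric(0),
                cardinality = table(integer(0)), nodeDensity = 0,
                totalLength = 0))
  }
  totalLengthUm <- sum(e$length)
  LsMm <- totalLengthUm / 1000                  # mm
  Ls <- LsMm / tissueVolume                     # mm / mm^3
  rs <- weighted.mean(e$meanRadius, e$length) / 1000   # mm
  Vs <- pi * rs^2 * Ls
  branch <- n$id[n$degree >= 3L]
  angles <- numeric(0)
  for (k in branch) {
    origin <- as.numeric(n[match(k, n$id), c("x", "y", "z")])
    tangents <- list()
    for (i in seq_len(nrow(e))) {
      if (e$from[i] != k && e$to[i] != k) next
      p <- orientPolyline(graph@polylines[[i]], n, k, NA)
      tangents[[length(tangents) + 1L]] <-
        edgeTangent(p, tangentLength, origin,
                    skip = n$radius[match(k, n$id)])
    }
    if (length(tangents) < 2L) next
    for (a in seq_len(length(tangents) - 1L))
      for (b in (a + 1L):length(tangents)) {
        cs <- sum(tangents[[a]] * tangents[[b]])
        cs <- min(1, max(-1, cs))
        angles <- c(angles, acos(cs) * 180 / pi)
      }
  }
  card <- table(n$degree[n$degree >= 3L])
  list(Ls = Ls, rs = rs, Vs = Vs, branchAngles = angles,
       cardinality = card, nodeDensity = length(branch) / tissueVolume,
       totalLength = totalLengthUm)
}

# unit tangent of an edge leaving a node: chord over the first `len` µm of
# the polyline, skipping the junction zone (within `skip` µm of the node)
# where thinning distorts the centerline
edgeTangent <- function(p, len, origin = p[1, ], skip = 0) {
  if (nrow(p) < 2L) return(c(1, 0, 0))
  seg <- diff(p)
  cum <- c(0, cumsum(sqrt(rowSums(seg^2))))
  k0 <- which(cum >= skip)[1]
  if (is.na(k0)) k0 <- 1L
  k1 <- which(cum >= skip + len)[1]
  if (is.na(k1)) k1 <- nrow(p)
  start <- if (k0 == 1L) origin else p[k0, ]
  normalize(p[k1, ] - start)
}

#' Cylinder-consistency check of network morphometry
#'
#' Approximating the tubular network by cylinders predicts the volume
#' fraction V_c = pi r_s^2 L_s from the independently measured length
#' density and mean radius; the ratio V_c / V_s against the measured volume
#' fraction is close to 1 for internally consistent data.
#'
#' @param Vs measured volume fraction (> 0).
#' @param Ls length density (mm/mm^3).
#' @param rs mean radius (mm).
#' @return list with \code{Vc} and \code{ratio} = Vc/Vs.
#' @examples
#' cylinderConsistency(Vs = 0.16, Ls = 2853.4, rs = 4.05e-3)
#' @export
cylinderConsistency <- function(Vs, Ls, rs) {
  stopifnot(Vs > 0, Ls >= 0, rs >= 0)
  Vc <- pi * rs^2 * Ls
  list(Vc = Vc, ratio = Vc / Vs)
}

#' Central-to-portal vein coordinate
#'
#' chi = 50 * ((|D - d_pv| - |D - d_cv|) / D + 1), clamped to [0, 100]:
#' 0 on the central-vein surface, 100 on the portal-vein surface, 50 midway.
#'
#' @param dCv,dPv distances to the nearest central / portal vein (µm, >= 0).
#' @param D the CV-PV distance (µm, > 0).
#' @return chi in [0, 100] (vectorized).
#' @examples
#' chiCoordinate(0, 100, 100)    # 0   (at the CV)
#' chiCoordinate(100, 0, 100)    # 100 (at the PV)
#' @export
chiCoordinate <- function(dCv, dPv, D) {
  if (any(D <= 0)) stop("D must be positive")
  stopifnot(all(dCv >= 0), all(dPv >= 0))
  chi <- 50 * ((abs(D - dPv) - abs(D - dCv)) / D + 1)
  pmin(pmax(chi, 0), 100)
}

#' Zonation profile: relative population density along the lobule axis
#'
#' Bins cells by their chi coordinate and reports, per population, the
#' population share within the bin divided by the population's overall
#' share, so a uniformly distributed population profiles flat at 1.
#' Boundary-flagged cells are excluded; empty bins are NA (missing), not 0.
#'
#' @param cells data.frame with columns \code{chi}, \code{population} and
#'   optionally \code{boundary}.
#' @param bins number of chi bins over [0, 100].
#' @return matrix (bins x populations) of relative densities, with bin
#'   centres as rownames.
#' @export
zonationProfile <- function(cells, bins = 10L) {
  if (!is.null(cells$boundary)) cells <- cells[!cells$boundary, ]
  br <- seq(0, 100, length.out = bins + 1L)
  bin <- cut(cells$chi, br, include.lowest = TRUE)
  pops <- sort(unique(as.character(cells$population)))
  overall <- table(factor(cells$population, levels = pops)) / nrow(cells)
  out <- matrix(NA_real_, bins, length(pops),
                dimnames = list(sprintf("%.0f", (br[-1] + br[-length(br)]) / 2),
                                pops))
  for (b in seq_len(bins)) {
    sel <- as.integer(bin) == b
    nTot <- sum(sel)
    if (!nTot) next                      # empty bin stays missing
    share <- table(factor(cells$population[sel], levels = pops)) / nTot
    out[b, ] <- as.numeric(share) / as.numeric(overall)
  }
  out
}

#' Cluster hepatocytes into ploidy populations
#'
#' Agglomerative clustering (Ward linkage on the standardized Euclidean
#' distance) of cells on (volume, DAPI integral), separately for mono- and
#' bi-nucleated cells: 4 clusters for mono-nucleated (2n, 4n, 8n, 16n) and 3
#' for bi-nucleated (2x2n, 2x4n, 2x8n), labelled in order of ascending DAPI
#' integral.
#'
#' @param cells data.frame with columns \code{volume}, \code{dapi},
#'   \code{nNuclei} (1 or 2).
#' @param kMono,kBi number of clusters per nuclearity group.
#' @return the input with a \code{population} column added; clustering
#'   quality flagged via attribute \code{"silhouette"} per group.
#' @export
ploidyCluster <- function(cells, kMono = 4L, kBi = 3L) {
  labsMono <- c("2n", "4n", "8n", "16n")
  labsBi <- c("2x2n", "2x4n", "2x8n")
  cells$population <- NA_character_
  sil <- c(mono = NA_real_, bi = NA_real_)
  for (grp in c("mono", "bi")) {
    sel <- if (grp == "mono") cells$nNuclei == 1L else cells$nNuclei == 2L
    k <- if (grp == "mono") kMono else kBi
    labs <- if (grp == "mono") labsMono[seq_len(kMono)]
            else labsBi[seq_len(kBi)]
    n <- sum(sel)
    if (!n) next
    if (n < max(50L, k)) stop("fewer cells than required for clustering")
    X <- scale(cbind(cells$volume[sel], cells$dapi[sel]))
    hc <- hclust(dist(X), method = "ward.D2")
    cl <- cutree(hc, k = k)
    ord <- order(tapply(cells$dapi[sel], cl, mean))
    relab <- match(cl, ord)
    cells$population[sel] <- labs[relab]
    sil[if (grp == "mono") "mono" else "bi"] <- meanSilhouette(X, cl)
  }
  attr(cells, "silhouette") <- sil
  cells
}

meanSilhouette <- function(X, cl) {
  D <- as.matrix(dist(X))
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cl == cl[i]; own[i] <- FALSE
    a <- if (any(own)) mean(D[i, own]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(k) mean(D[i, cl == k]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Fit a log-normal mixture to volumes or intensities
#'
#' Expectation-maximization of a k-component Gaussian mixture in log space
#' (k-means initialization, deterministic given the seed); components are
#' reported sorted by their linear-space mean.
#'
#' @param values positive observations (n >= 10 k).
#' @param k number of components.
#' @param seed seed for the k-means initialization.
#' @return data.frame with per-component \code{meanlog}, \code{sdlog},
#'   \code{weight} and linear-space \code{mean}.
#' @export
fitLognormalMixture <- function(values, k = 2L, seed = 1L) {
  if (any(values <= 0)) stop("values must be positive")
  x <- log(as.numeric(values))
  stopifnot(length(x) >= 10L * k)
  if (k == 1L) {
    fit <- data.frame(meanlog = mean(x), sdlog = sqrt(mean((x - mean(x))^2)),
                      weight = 1)
  } else {
    set.seed(as.integer(seed %% .Machine$integer.max))
    km <- kmeans(x, centers = k, nstart = 5L)
    mu <- as.numeric(km$centers)
    sg <- vapply(seq_len(k), function(j)
      max(sd(x[km$cluster == j]), 1e-4), 0)
    w <- as.numeric(table(factor(km$cluster, seq_len(k)))) / length(x)
    fit <- emGauss1d(x, mu, sg, w)
  }
  fit$mean <- exp(fit$meanlog + fit$sdlog^2 / 2)
  fit[order(fit$mean), , drop = FALSE]
}

emGauss1d <- function(x, mu, sg, w, maxIter = 500L, tol = 1e-9) {
  n <- length(x); k <- length(mu)
  ll0 <- -Inf
  for (it in seq_len(maxIter)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sg[j]),
                   numeric(n))
    tot <- rowSums(dens); tot[tot < 1e-300] <- 1e-300
    r <- dens / tot
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sg <- pmax(sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk), 1e-6)
    ll <- sum(log(tot))
    if (abs(ll - ll0) < tol * (1 + abs(ll))) break
    ll0 <- ll
  }
  data.frame(meanlog = mu, sdlog = sg, weight = w)
}
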