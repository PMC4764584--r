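# Maximum-entropy thresholding, surface detection, Bayesian refinement,
# unbending, the local threshold field, vessels and gap bridging.

test_that("Kapur threshold equals a brute-force entropy scan", {
  set.seed(21)
  x <- c(rnorm(3000, 20, 2), rnorm(3000, 60, 2))
  h <- hist(x, breaks = 64, plot = FALSE)
  thr <- maxEntropyThreshold(h)
  # the threshold separates the two modes (ties across the empty valley
  # break to the lowest bin)
  expect_gt(thr, 25); expect_lt(thr, 55)
  # brute-force oracle over all split points
  p <- h$counts / sum(h$counts)
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  crit <- vapply(seq_len(length(p) - 1), function(t) {
    Pb <- sum(p[1:t]); Pf <- 1 - Pb
    if (Pb <= 0 || Pf <= 0) return(-Inf)
    H(p[1:t] / Pb) + H(p[-(1:t)] / Pf)
  }, 0)
  best <- which.max(crit)
  expect_equal(thr, (h$mids[best] + h$mids[best + 1]) / 2)
  # scale invariance in the counts
  expect_equal(maxEntropyThreshold(list(counts = 5 * h$counts,
                                        mids = h$mids)), thr)
  # uniform histogram splits at mid-range
  u <- list(counts = rep(10, 10), mids = 1:10)
  expect_equal(maxEntropyThreshold(u), 5.5)
  expect_error(maxEntropyThreshold(list(counts = c(0, 7, 0), mids = 1:3)),
               "2 occupied")
})

test_that("measured surfaces find a slab and dip into surface vessels", {
  a <- bentSlab(nx = 32, ny = 32, nz = 80, z1 = 10, z2 = 60)
  sp <- measureSurfaces(VolumeImage(a))
  expect_lt(max(abs(sp@ym1 - 10)), 1.5)
  expect_lt(max(abs(sp@ym2 - 60)), 1.5)
  # an empty sphere breaking the top surface drags ym1 downwards there
  ah <- bentSlab(nx = 32, ny = 32, nz = 80, z1 = 10, z2 = 60,
                 holes = list(c(16, 16, 10, 6)))
  sph <- measureSurfaces(VolumeImage(ah))
  expect_gt(sph@ym1[16, 16], 13)
  # sub-threshold additive noise leaves the measured surface within 1 voxel
  set.seed(22)
  an <- a + array(rnorm(length(a), 0, 5), dim(a))
  spn <- measureSurfaces(VolumeImage(an))
  expect_lt(median(abs(spn@ym1 - 10)), 1.1)
})

test_that("prior estimation follows the stated statistics", {
  ym1 <- matrix(10, 2, 2)
  ym2 <- ym1 + matrix(c(48, 50, 50, 52), 2, 2)
  sp <- new("SurfacePair", ym1 = ym1, ym2 = ym2,
            y1 = matrix(numeric(0), 0, 0), y2 = matrix(numeric(0), 0, 0))
  pr <- estimatePrior(sp)
  expect_equal(pr@tMad, median(abs(c(48, 50, 50, 52) - 50)))
  expect_equal(pr@s, pi / 2 * pr@tMad)
  expect_equal(pr@sigma, pi / 2 * pr@tMad)
  expect_false(pr@flagged)
  # constant thickness floors t_MAD at 1 voxel with a flag
  spc <- new("SurfacePair", ym1 = ym1, ym2 = ym1 + 50,
             y1 = matrix(numeric(0), 0, 0), y2 = matrix(numeric(0), 0, 0))
  prc <- estimatePrior(spc)
  expect_true(prc@flagged)
  expect_equal(prc@tMad, 1)
  # Laplace rate recovered from Laplace-distributed height increments
  # along a 1-column strip, where every direct difference is one increment
  set.seed(23)
  n <- 10001
  steps <- rexp(n - 1, rate = 0.5) * sample(c(-1, 1), n - 1, TRUE)
  ym <- matrix(cumsum(c(0, steps)), ncol = 1)
  spl <- new("SurfacePair", ym1 = ym, ym2 = ym + 50,
             y1 = matrix(numeric(0), 0, 0), y2 = matrix(numeric(0), 0, 0))
  prl <- estimatePrior(spl)
  expect_rel_equal(prl@lam, 0.5, 0.1)
})

test_that("surface energy matches hand evaluation and is locally convex", {
  ym1 <- matrix(c(10, 11, 12, 10), 2, 2)
  ym2 <- matrix(c(60, 62, 61, 60), 2, 2)
  pr <- new("SurfacePrior", s = 2, sigma = 3, lam = 0.4, tMad = 2,
            tMed = 50, flagged = FALSE)
  y1 <- ym1 + c(1, 0, -1, 0)
  y2 <- ym2
  sp <- new("SurfacePair", ym1 = ym1, ym2 = ym2, y1 = y1, y2 = y2)
  # term-by-term oracle
  e <- sum(log(pi * 2) + log1p(((y1 - ym1) / 2)^2)) +
    sum(log(pi * 2) + log1p(((y2 - ym2) / 2)^2)) +
    sum(log(sqrt(2 * pi) * 3) + (y2 - y1 - 50)^2 / (2 * 9))
  for (i in 1:2) for (j in 1:2)
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      i2 <- i + dx; j2 <- j + dy
      if (i2 < 1 || i2 > 2 || j2 < 1 || j2 > 2) next
      e <- e + 0.4 * abs(y1[i2, j2] - y1[i, j]) - log(0.4)
    }
  expect_equal(surfaceEnergy(sp, pr), e, tolerance = 1e-10)
  # flat configuration at the measured surfaces attains the data-term floor
  flat <- new("SurfacePair", ym1 = matrix(10, 3, 3),
              ym2 = matrix(60, 3, 3), y1 = matrix(10, 3, 3),
              y2 = matrix(60, 3, 3))
  prf <- new("SurfacePrior", s = 2, sigma = 3, lam = 0.4, tMad = 2,
             tMed = 50, flagged = FALSE)
  nPairs <- sum(vapply(1:3, function(i) sum(vapply(1:3, function(j) {
    sum(!(outer(i + (-1:1), 1, "+") < 1))
  }, 0)), 0))
  eFlat <- surfaceEnergy(flat, prf)
  # analytic floor: data and thickness terms at their maxima, smoothness 0
  nb <- 0
  for (i in 1:3) for (j in 1:3) for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    if (i + dx >= 1 && i + dx <= 3 && j + dy >= 1 && j + dy <= 3)
      nb <- nb + 1
  }
  expect_equal(eFlat, 9 * (2 * log(pi * 2) + log(sqrt(2 * pi) * 3)) -
                 nb * log(0.4), tolerance = 1e-10)
  # displacing one column strictly increases the energy with displacement
  es <- vapply(0:4, function(k) {
    y1k <- flat@y1; y1k[2, 2] <- y1k[2, 2] + k
    surfaceEnergy(new("SurfacePair", ym1 = flat@ym1, ym2 = flat@ym2,
                      y1 = y1k, y2 = flat@y2), prf)
  }, 0)
  expect_true(all(diff(es) > 0))
})

test_that("ICM refinement repairs vessel dips and never increases energy", {
  set.seed(24)
  nx <- 40; ny <- 40
  bend <- outer(seq_len(nx), seq_len(ny),
                function(i, j) 6 * sin(i / 8) * cos(j / 9))
  a <- bentSlab(nx, ny, 90, z1 = 20, z2 = 65, bend = bend,
                holes = list(c(10, 10, 20 + 6 * sin(10 / 8) * cos(10 / 9), 7),
                             c(30, 28, 65 + 6 * sin(30 / 8) * cos(28 / 9), 7)))
  img <- VolumeImage(a)
  spm <- measureSurfaces(img)
  pr <- estimatePrior(spm)
  ref <- refineSurfacesICM(spm, pr)
  true1 <- 20 + bend; true2 <- 65 + bend
  madMeas <- mean(abs(spm@ym1 - true1) + abs(spm@ym2 - true2)) / 2
  madRef <- mean(abs(ref@y1 - true1) + abs(ref@y2 - true2)) / 2
  expect_lt(madRef, madMeas)
  expect_lt(madRef, 5)
  # descent property
  e0 <- surfaceEnergy(new("SurfacePair", ym1 = spm@ym1, ym2 = spm@ym2,
                          y1 = pmin(spm@ym1, spm@ym2),
                          y2 = pmax(spm@ym1, spm@ym2)), pr)
  expect_lte(surfaceEnergy(ref, pr), e0)
  # already-optimal flat surfaces are a fixed point
  flat <- new("SurfacePair", ym1 = matrix(20, 10, 10),
              ym2 = matrix(70, 10, 10), y1 = matrix(numeric(0), 0, 0),
              y2 = matrix(numeric(0), 0, 0))
  prf <- estimatePrior(flat)
  reff <- refineSurfacesICM(flat, prf)
  expect_equal(reff@y1, flat@ym1)
  expect_equal(reff@y2, flat@ym2)
})

test_that("flattening straightens a sinusoidal bend and conserves mass", {
  nx <- 40; ny <- 40
  bend <- outer(seq_len(nx), seq_len(ny),
                function(i, j) 10 * sin(2 * pi * i / nx))
  a <- bentSlab(nx, ny, 90, z1 = 25, z2 = 60, bend = bend)
  img <- VolumeImage(a)
  sp <- new("SurfacePair", ym1 = 25 + bend, ym2 = 60 + bend,
            y1 = 25 + bend, y2 = 60 + bend)
  flat <- flattenSection(img, sp, df = 12)
  spf <- measureSurfaces(flat)
  expect_lt(var(as.numeric(spf@ym1)), 1)
  # above-threshold mass conserved within 2%
  expect_rel_equal(sum(imgData(flat) > 50), sum(a > 50), 0.02)
  # inverse remap is close to identity away from interpolation edges
  back <- unflattenSection(flat)
  core <- abs(imgData(back) - a)[, , 30:55]
  expect_lt(sqrt(mean(core^2)), 25)
  # flat surfaces give the identity transform
  spFlat <- new("SurfacePair", ym1 = matrix(25, nx, ny),
                ym2 = matrix(60, nx, ny), y1 = matrix(25, nx, ny),
                y2 = matrix(60, nx, ny))
  aflat <- bentSlab(nx, ny, 90, z1 = 25, z2 = 60)
  out <- flattenSection(VolumeImage(aflat), spFlat)
  expect_equal(imgData(out), aflat, tolerance = 1e-8)
  expect_error(flattenSection(img, new("SurfacePair", ym1 = sp@ym1,
                                       ym2 = sp@ym2, y1 = sp@y2,
                                       y2 = sp@y1)))
})

test_that("the local threshold field adapts where a global threshold fails", {
  set.seed(26)
  d <- c(64, 32, 32)
  a <- array(abs(rnorm(prod(d), 20, 3)), d)
  co <- as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3]))
  # brightly stained objects on the left half, much dimmer on the right
  obj <- array(FALSE, d)
  for (cx in list(c(10, 16, 16), c(22, 10, 20), c(44, 16, 16),
                  c(56, 22, 12))) {
    dd <- sqrt((co[, 1] - cx[1])^2 + (co[, 2] - cx[2])^2 +
               (co[, 3] - cx[3])^2)
    obj <- obj | array(dd <= 5, d)
  }
  bsel <- obj & array(co[, 1] <= 32, d)
  dsel <- obj & array(co[, 1] > 32, d)
  a[bsel] <- rlnorm(sum(bsel), log(1000), 0.5)
  a[dsel] <- rlnorm(sum(dsel), log(100), 0.2)
  img <- VolumeImage(a)
  field <- lmeThresholdField(img, cube = 16L, overlap = 0.5)
  thr <- thresholdVolume(field)
  lme <- a > thr
  glob <- a > tissuescope3d:::kapurThresholdValues(as.numeric(a), 128L)
  recall <- function(m) sum(m & obj) / sum(obj)
  dimObj <- obj & array(co[, 1] > 32, d)
  expect_gt(sum(lme & dimObj) / sum(dimObj), 0.9)
  expect_lt(sum(glob & dimObj) / sum(dimObj), 0.5)
  # a statistically homogeneous two-level image yields the global value
  b <- array(rep(c(10, 90), length.out = prod(d)), d)
  fb <- lmeThresholdField(VolumeImage(b), cube = 16L, overlap = 0.5)
  expect_lt(diff(range(fb@thresholds)), 1e-9)
  # interpolation anchors: the field equals the cube value at its centre
  tv <- thresholdVolume(fb)
  ctr <- round(fb@centers[[1]][1])
  expect_equal(tv[ctr, round(fb@centers[[2]][1]), round(fb@centers[[3]][1])],
               fb@thresholds[1, 1, 1])
})

test_that("vessels are segmented inside the slab and bridged across gaps", {
  nx <- 40; ny <- 40; nz <- 80
  a <- bentSlab(nx, ny, nz, z1 = 10, z2 = 70,
                holes = list(c(20, 20, 40, 8)))
  img <- VolumeImage(a)
  spm <- measureSurfaces(img)
  pr <- estimatePrior(spm)
  ref <- refineSurfacesICM(spm, pr)
  field <- lmeThresholdField(img, cube = 20L, overlap = 0.5,
                             minSeparation = 0)
  mask <- segmentVessels(img, ref, 50, minVoxels = 100L)
  co <- as.matrix(expand.grid(1:nx, 1:ny, 1:nz))
  cyl <- array(sqrt((co[, 1] - 20)^2 + (co[, 2] - 20)^2 +
                    (co[, 3] - 40)^2) <= 8, dim(a))
  jac <- sum(mask & cyl) / sum(mask | cyl)
  expect_gt(jac, 0.8)
  # fully stained slab: no vessels
  full <- bentSlab(nx, ny, nz, z1 = 10, z2 = 70)
  spf <- measureSurfaces(VolumeImage(full))
  maskf <- segmentVessels(VolumeImage(full), spf, 50, minVoxels = 100L)
  expect_equal(sum(maskf), 0)
})

test_that("gap interpolation extrudes, tracks centroids and bounds areas", {
  mk <- function(cx, cy, r, n = 40) {
    co <- as.matrix(expand.grid(1:n, 1:n))
    matrix(sqrt((co[, 1] - cx)^2 + (co[, 2] - cy)^2) <= r, n, n)
  }
  a <- mk(20, 20, 6)
  out <- interpolateVesselGap(a, a, 5)
  for (g in 1:5) expect_equal(out[, , g], a)
  # offset circle: centroid moves linearly across the gap
  b <- mk(26, 20, 6)
  out2 <- interpolateVesselGap(a, b, 9)
  cents <- vapply(1:9, function(g) {
    w <- which(out2[, , g], arr.ind = TRUE)
    mean(w[, 1])
  }, 0)
  expected <- 20 + 6 * (1:9) / 10
  expect_lt(max(abs(cents - expected)), 0.75)
  # areas lie between the end areas
  a2 <- mk(20, 20, 4)
  out3 <- interpolateVesselGap(a, a2, 7)
  areas <- vapply(1:7, function(g) sum(out3[, , g]), 0)
  expect_true(all(areas <= sum(a) + 1 & areas >= sum(a2) - 1))
  # disjoint faces stay unbridged with a warning
  expect_warning(res <- interpolateVesselGap(mk(8, 8, 3), mk(32, 32, 3), 4),
                 "unbridged")
  expect_equal(sum(res), 0)
})
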