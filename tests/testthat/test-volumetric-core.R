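# Noise-model calibration, outlier-tolerant fitting, BFBD de-noising and
# image metrics.

test_that("noise model recovers the generating alpha and beta", {
  set.seed(11)
  xs <- seq(0, 3, length.out = 72)
  # a smooth field spanning a wide photon-count range conditions the
  # variance-vs-intensity line well
  base <- outer(outer(20 + 180 * (1 + sin(xs)) / 2, 1 + 0.8 * cos(xs)),
                rep(1, 72)) + 10
  img <- VolumeImage(2.0 * array(rpois(72^3, as.numeric(base)), rep(72, 3)) +
                       100, spacing = 0.3)
  nm <- estimateNoiseModel(img)
  expect_false(nm@failed)
  expect_rel_equal(nm@alpha[1], 2.0, 0.05)
  expect_rel_equal(nm@beta, 100, 0.05)
  # linearity of binned mean variance vs intensity
  a <- imgData(img)
  dif <- a[, , 2:72] - a[, , 1:71]
  mid <- (a[, , 2:72] + a[, , 1:71]) / 2
  br <- seq(min(mid), max(mid), length.out = 33)
  bin <- findInterval(mid, br, rightmost.closed = TRUE)
  keep <- which(tabulate(bin, 32) >= 50)
  mv <- vapply(keep, function(b) mean((dif[bin == b])^2 / 2), 0)
  mi <- vapply(keep, function(b) mean(mid[bin == b]), 0)
  expect_gt(summary(lm(mv ~ mi))$r.squared, 0.9)
})

test_that("constant noise-free image flags a calibration failure", {
  img <- VolumeImage(array(7, c(8, 8, 8)))
  nm <- estimateNoiseModel(img)
  expect_true(nm@failed)
  expect_error(bfbdDenoise(img, nm), "not calibrated")
})

test_that("outlier-tolerant line fit resists positive spikes", {
  x <- 1:50
  y <- 3 + 0.8 * x
  fit <- fitLineOutlierTolerant(y)
  expect_equal(fit$slope, 0.8, tolerance = 1e-6)
  expect_equal(fit$intercept, 3, tolerance = 1e-5)
  expect_true(all(fit$inliers))
  # 20% large positive spikes: robust fit stays near truth, OLS does not
  set.seed(4)
  ys <- y + rnorm(50, 0, 0.3)
  spikes <- sample(50, 10)
  ys[spikes] <- ys[spikes] + 60
  rob <- fitLineOutlierTolerant(ys)
  ols <- lm(ys ~ x)
  expect_lt(abs(rob$intercept + 25 * rob$slope - (3 + 25 * 0.8)), 1)
  expect_gt(abs(mean(ols$fitted.values) - (3 + 25.5 * 0.8)),
            abs(mean(rob$fitted) - (3 + 25.5 * 0.8)))
  # the background prediction stays below an isolated foreground spike
  prof <- 10 + 0.2 * (1:20)
  prof[12] <- prof[12] + 40
  bgfit <- fitLineOutlierTolerant(prof)
  expect_lt(bgfit$fitted[12], prof[12] - 20)
  expect_false(bgfit$inliers[12])
  expect_error(fitLineOutlierTolerant(c(1, 2)), "3 points")
})

test_that("BFBD keeps a linear background and preserves step edges", {
  set.seed(5)
  nz <- 40
  base <- array(rep(100 + 2 * seq_len(nz), each = 24 * 24), c(24, 24, nz))
  img <- VolumeImage(base + array(rnorm(length(base), 0, 1), dim(base)))
  nm <- new("NoiseModel", alpha = 2, slabCenters = nz / 2, beta = 0,
            slabHeight = nz, failed = FALSE)
  den <- bfbdDenoise(img, nm, window = 5, threshold = 1.25)
  # pure sub-threshold noise on a linear background: output ~ background
  expect_lt(mean(abs(imgData(den) - base)), 1.5)
  # a bright step edge survives within one voxel
  step <- array(100, c(24, 24, nz))
  step[, , 21:nz] <- 400
  img2 <- VolumeImage(step + array(rnorm(length(step), 0, 2), dim(step)))
  den2 <- bfbdDenoise(img2, nm)
  prof <- apply(imgData(den2), 3, mean)
  edge <- which.max(diff(prof))
  expect_lte(abs(edge - 20), 1)
})

test_that("image metrics match hand-evaluated formulas and are symmetric", {
  a <- VolumeImage(array(c(1, 2, 3, 4, 5, 6, 7, 8), c(2, 2, 2)))
  b <- VolumeImage(array(c(2, 2, 3, 5, 5, 6, 9, 8), c(2, 2, 2)))
  m <- imageMetrics(a, b)
  expect_equal(m@mse, mean((imgData(a) - imgData(b))^2))
  expect_equal(m@coc, cor(as.numeric(imgData(a)), as.numeric(imgData(b))))
  m2 <- imageMetrics(b, a)
  expect_equal(m@mse, m2@mse)
  expect_equal(m@coc, m2@coc)
  ident <- imageMetrics(a, a)
  expect_equal(ident@mse, 0)
  expect_equal(ident@coc, 1)
  zm <- VolumeImage(imgData(a) - mean(imgData(a)))
  neg <- VolumeImage(-imgData(zm))
  expect_equal(imageMetrics(zm, neg)@coc, -1)
  expect_error(imageMetrics(a, VolumeImage(array(1, c(2, 2, 2)))),
               "zero-variance")
})

test_that("vicinity mask dilates by an isotropic ball", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  expect_identical(vicinityMask(m, 0), m)
  v1 <- vicinityMask(m, 1)
  # brute-force ball oracle
  co <- as.matrix(expand.grid(1:9, 1:9, 1:9))
  oracle <- array(sqrt(rowSums((co - 5)^2)) <= 1 + 1e-9, dim(m))
  expect_identical(v1, oracle)
  # inflating a sphere adds a shell at most 2 voxels thick
  s <- solidSphere(c(31, 31, 31), radius = 8)
  v2 <- vicinityMask(s, 2)
  expect_true(all(s[v2] | TRUE))
  expect_true(all(v2[s]))
  dist <- ts$edtDist(s)
  expect_true(all(dist[v2 & !s] <= 2 + 1e-9))
})

test_that("TIFF round trip preserves data and spacing metadata", {
  f <- tempfile(fileext = ".tif")
  vi <- VolumeImage(array(runif(4 * 5 * 3, 0, 500), c(4, 5, 3)),
                    spacing = c(0.3, 0.3, 0.5), channel = "DAPI",
                    zOrigin = 12)
  writeVolume(vi, f)
  back <- readVolume(f)
  expect_equal(imgData(back), imgData(vi), tolerance = 1e-4)
  expect_equal(voxelSpacing(back), c(0.3, 0.3, 0.5))
  expect_equal(channelName(back), "DAPI")
  expect_equal(back@zOrigin, 12)
})
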