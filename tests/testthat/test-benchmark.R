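# Scene generation, the degradation stack and reconstruction scoring.

test_that("scenes are deterministic and respect the stated geometry", {
  sc1 <- generateScene(size = 64, spacing = 0.3, seed = 7)
  sc2 <- generateScene(size = 64, spacing = 0.3, seed = 7)
  expect_identical(sc1@labels$bc, sc2@labels$bc)
  expect_identical(sc1@tables$nuclei, sc2@tables$nuclei)
  sc3 <- generateScene(size = 64, spacing = 0.3, seed = 8)
  expect_false(identical(sc1@labels$bc, sc3@labels$bc))
  # BC tube diameter ~1 µm = ~3.3 voxels at 0.3 µm spacing
  bc <- sc1@labels$bc
  if (any(bc)) {
    g <- skeletonizeToGraph(bc, 0.3)
    if (nrow(graphEdges(g)))
      expect_lt(abs(2 * weighted.mean(graphEdges(g)$meanRadius,
                                      graphEdges(g)$length) - 1.0), 0.5)
  }
  # nuclei never intersect the sinusoid lumen; each nucleus in one cell
  expect_equal(sum(sc1@labels$nuclei > 0 & sc1@labels$sinusoidLumen), 0)
  # zero-density request
  sc0 <- generateScene(size = 64, spacing = 0.3, seed = 7,
                       sinusoidLength = 0, bcLength = 0,
                       nucleusDensity = 0)
  expect_equal(sum(sc0@labels$bc), 0)
  expect_equal(nrow(sc0@tables$nuclei), 0)
})

test_that("uneven staining has the stated intensity statistics", {
  set.seed(61)
  m <- array(TRUE, c(64, 64, 64))
  vi <- applyUnevenStaining(m, snr = 2, seed = 3)
  fg <- imgData(vi) - 1000 / (2 - 1)
  expect_rel_equal(mean(fg), 1000, 0.15)
  # log of the staining looks Gaussian-ish: check sd on the log scale
  expect_gt(sd(log(fg)), 0.3)
  # snr contract: foreground mean ~ snr x background
  half <- array(FALSE, c(64, 64, 64)); half[1:32, , ] <- TRUE
  vs <- applyUnevenStaining(half, snr = 2, seed = 3)
  expect_rel_equal(mean(imgData(vs)[half]) / mean(imgData(vs)[!half]), 2,
                   0.1)
  empty <- applyUnevenStaining(array(FALSE, c(16, 16, 16)), snr = 4,
                               seed = 1)
  expect_equal(diff(range(imgData(empty))), 0)
})

test_that("the PSF kernel conserves intensity and elongates axially", {
  d <- c(33, 33, 33)
  delta <- array(0, d); delta[17, 17, 17] <- 1
  vi <- VolumeImage(delta, spacing = 0.3)
  out <- imgData(psfConvolve(vi, 647))
  expect_rel_equal(sum(out), 1, 1e-6)
  fwhm <- function(v) {
    h <- max(v) / 2
    sum(v >= h)
  }
  lat <- out[, 17, 17]; ax <- out[17, 17, ]
  expect_gt(fwhm(ax), fwhm(lat))
})

test_that("depth noise round-trips through the calibration", {
  # a z-constant wide-range field isolates the calibration from structure
  # gradients between z planes; each slab holds >= 64^3 voxels
  set.seed(12)
  sl <- ts$gaussSmooth(array(runif(96 * 96, 0, 1), c(96, 96, 1)), 2)[, , 1]
  sl <- (sl - min(sl)) / diff(range(sl)) * 2000
  base <- array(rep(sl, 64), c(96, 96, 64))
  bl <- VolumeImage(base, spacing = 0.3)
  nz1 <- addDepthNoise(bl, alpha0 = 1, alphaSlope = 0.05, beta = 100,
                       seed = 99)
  nz2 <- addDepthNoise(bl, alpha0 = 1, alphaSlope = 0.05, beta = 100,
                       seed = 99)
  expect_identical(imgData(nz1), imgData(nz2))
  nm <- estimateNoiseModel(nz1, slabHeight = 32L)
  expect_false(nm@failed)
  zUm <- (nm@slabCenters - 1) * 0.3
  expect_lt(max(abs(nm@alpha - (1 + 0.05 * zUm)) / (1 + 0.05 * zUm)), 0.1)
  expect_lt(abs(nm@beta - 100) / 100, 0.1)
  # alpha -> 0 limit: output -> input + beta
  tiny <- addDepthNoise(bl, alpha0 = 1e-4, alphaSlope = 0, beta = 50,
                        seed = 1)
  expect_lt(mean(abs(imgData(tiny) - imgData(bl) - 50)), 0.3)
})

test_that("reconstruction scoring matches voxel tallies", {
  sc <- generateScene(size = 64, spacing = 0.3, seed = 13)
  gt <- list(bc = sc@labels$bc,
             sinusoid = sc@labels$sinusoid | sc@labels$sinusoidLumen,
             nuclei = sc@labels$nuclei > 0, cells = sc@labels$cells)
  perfect <- evaluateReconstruction(gt, sc)
  expect_equal(perfect$bc$F, 1)
  expect_equal(perfect$sinusoid$PR, 1)
  if (!is.null(perfect$cells) && length(perfect$cells$perCellVolErr)) {
    expect_equal(perfect$cells$F, 1)
    expect_equal(perfect$cells$volumeErrorPct, 0)
  }
  # eroded prediction: no false positives, sensitivity = voxel tally
  er <- ts$erodeBall(gt$nuclei, 1)
  sc2 <- evaluateReconstruction(list(nuclei = er), sc)
  expect_equal(sc2$nuclei$PR, 1)
  expect_equal(sc2$nuclei$SN, sum(er & gt$nuclei) / sum(gt$nuclei))
  expect_error(evaluateReconstruction(list(nuclei = er[1:10, , ]), sc),
               "mismatch")
})

test_that("degradation stages can be bypassed and are seed-reproducible", {
  sc <- generateScene(size = 64, spacing = 0.3, seed = 14)
  a <- benchmarkDegrade(sc, snr = 4, seed = 5)
  b <- benchmarkDegrade(sc, snr = 4, seed = 5)
  expect_identical(imgData(a$bc), imgData(b$bc))
  noNoise <- benchmarkDegrade(sc, snr = 4, seed = 5, noise = FALSE)
  expect_false(identical(imgData(a$bc), imgData(noNoise$bc)))
  clean <- benchmarkDegrade(sc, snr = 4, seed = 5, stain = FALSE,
                            psf = FALSE, noise = FALSE)
  expect_equal(length(unique(as.numeric(imgData(clean$bc)))), 2L)
})
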