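# The 74-parameter nuclear feature profile.

test_that("a uniform digital sphere has the expected analytic profile", {
  d <- c(41, 41, 41)
  sph <- solidSphere(d, radius = 10)
  chans <- list(dapi = VolumeImage(sph * 200, spacing = 1),
                flk1 = VolumeImage(array(0, d), spacing = 1),
                phalloidin = VolumeImage(array(0, d), spacing = 1))
  mesh <- meshFromMask(sph, 1, smoothIters = 6L)[[1]]
  fv <- extractFeatures(mesh, chans, equalize = FALSE)
  expect_length(fv, 74)
  expect_true(all(is.finite(fv)))
  expect_gt(fv["Sphericity"], 0.93); expect_lte(fv["Sphericity"], 1.02)
  expect_lt(abs(fv["a/b"] - 1), 0.06)
  expect_lt(abs(fv["b/c"] - 1), 0.06)
  expect_equal(unname(fv["DAPI Sd"]), 0)
  expect_equal(unname(fv["HF2"]), 0)        # no intensity contrast
  expect_true(all(abs(fv[paste("Lacunarity", 1:5)] - 1) < 1e-9))
  expect_false(attr(fv, "unreliable"))
})

test_that("Haralick features match a direct GLCM oracle on a toy block", {
  set.seed(71)
  d <- c(4, 4, 4)
  vals <- array(sample(0:3, 64, TRUE), d)
  mask <- array(TRUE, d)
  hf <- haralick3d(vals, mask, levels = 4L, distances = 1L)
  # brute-force co-occurrence counts over the 13 directions
  dirs <- ts$haralickDirections()
  counts <- matrix(0, 4, 4)
  for (o in seq_len(nrow(dirs))) {
    for (x in 1:4) for (y in 1:4) for (z in 1:4) {
      x2 <- x + dirs[o, 1]; y2 <- y + dirs[o, 2]; z2 <- z + dirs[o, 3]
      if (x2 < 1 || x2 > 4 || y2 < 1 || y2 > 4 || z2 < 1 || z2 > 4) next
      a <- vals[x, y, z] + 1; b <- vals[x2, y2, z2] + 1
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  p <- counts / sum(counts)
  i <- row(p); j <- col(p)
  expect_equal(unname(hf[1]), sum(p^2))                       # ASM
  expect_equal(unname(hf[2]), sum((i - j)^2 * p))             # contrast
  expect_equal(unname(hf[5]), sum(p / (1 + (i - j)^2)))       # IDM
  expect_equal(unname(hf[9]), -sum(p * log(p + 1e-12)))       # entropy
})

test_that("the box-counting dimension of a filled cube is near 3", {
  a <- array(100, c(30, 30, 30))
  expect_lt(abs(ts$boxCountingDimension(a) - 3), 0.2)
})

test_that("feature extraction flags border-touching nuclei", {
  d <- c(24, 41, 41)
  half <- solidSphere(d, centre = c(2, 21, 21), radius = 10)
  chans <- list(dapi = VolumeImage(half * 100, spacing = 1),
                flk1 = VolumeImage(array(0, d), spacing = 1),
                phalloidin = VolumeImage(array(0, d), spacing = 1))
  mesh <- meshFromMask(half, 1)[[1]]
  fv <- extractFeatures(mesh, chans, equalize = FALSE)
  expect_true(attr(fv, "unreliable"))
})

test_that("shell intensities read the surrounding channels", {
  d <- c(41, 41, 41)
  sph <- solidSphere(d, radius = 8)
  shell <- ts$dilateBall(sph, 3) & !ts$dilateBall(sph, 1)
  chans <- list(dapi = VolumeImage(sph * 100, spacing = 1),
                flk1 = VolumeImage(shell * 50, spacing = 1),
                phalloidin = VolumeImage(array(0, d), spacing = 1))
  mesh <- meshFromMask(sph, 1)[[1]]
  fv <- extractFeatures(mesh, chans, equalize = FALSE)
  # rings at 2-3 voxels see the bright shell, ring 10 does not
  expect_gt(fv["FLK1 surface intensity 2 vx"],
            fv["FLK1 surface intensity 10 vx"])
})
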