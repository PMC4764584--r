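# Tile correlation, grid optimization, blending and rigid registration.

`%||%` <- function(a, b) if (is.null(a)) b else a

textureVolume <- function(d, seed = 81) {
  set.seed(seed)
  ts$gaussSmooth(array(rnorm(prod(d)), d), 1.5)
}

test_that("NCC finds exact shifts and rejects unrelated volumes", {
  v <- textureVolume(c(40, 40, 24))
  a <- VolumeImage(v[1:30, 1:30, 1:20])
  r <- nccShift(a, a, search = 4L)
  expect_equal(r$shift, c(0, 0, 0))
  expect_equal(r$peak, 1)
  # crops with a known offset
  b <- VolumeImage(v[4:33, 1:30, 2:21])   # offset (3, 0, 1)
  r2 <- nccShift(a, b, search = 5L)
  expect_equal(r2$shift, c(3, 0, 1))
  expect_gt(r2$peak, 0.99)
  # independent noise: peak well below a matched pair
  set.seed(82)
  n1 <- VolumeImage(array(rnorm(20^3), rep(20, 3)))
  n2 <- VolumeImage(array(rnorm(20^3), rep(20, 3)))
  r3 <- nccShift(n1, n2, search = 3L)
  expect_lt(r3$peak, 0.2)
})

test_that("tile-shift optimization recovers a known decomposition", {
  v <- textureVolume(c(76, 76, 20), seed = 83)
  ov <- 8
  t11 <- VolumeImage(v[1:40, 1:40, ])
  t21 <- VolumeImage(v[(41 - ov):76, 1:40, ])
  t12 <- VolumeImage(v[1:40, (41 - ov):76, ])
  t22 <- VolumeImage(v[(41 - ov):76, (41 - ov):76, ])
  tiles <- matrix(list(t11, t12, t21, t22), 2, 2, byrow = TRUE)
  # note: tiles[i, j]: i indexes x, j indexes y
  tiles <- matrix(list(), 2, 2)
  tiles[[1, 1]] <- t11; tiles[[2, 1]] <- t21
  tiles[[1, 2]] <- t12; tiles[[2, 2]] <- t22
  grid <- tileGrid(tiles, nominalOverlap = ov / 40)
  opt <- optimizeTileShifts(grid, search = 4L)
  expect_equal(opt$positions[1, 1, ], c(0, 0, 0))
  expect_equal(opt$positions[2, 1, ], c(40 - ov, 0, 0))
  expect_equal(opt$positions[1, 2, ], c(0, 40 - ov, 0))
  expect_equal(opt$positions[2, 2, ], c(40 - ov, 40 - ov, 0))
  # G at the solution is at least the nominal-initialization value
  nominalG <- optimizeTileShifts(grid, search = 0L)$G
  expect_gte(opt$G, nominalG)
  # 1x1 grid: zero shift, G = 0
  g1 <- optimizeTileShifts(tileGrid(matrix(list(t11), 1, 1)))
  expect_equal(g1$G, 0)
  # blending the optimized grid reproduces the source volume
  mo <- blendMosaic(opt)
  expect_lt(max(abs(imgData(mo) - v)), 0.02)
})


test_that("blending preserves exclusive regions and keeps seams monotone", {
  d <- c(24, 24, 12)
  t1 <- VolumeImage(array(10, d))
  t2 <- VolumeImage(array(20, d))
  tiles <- matrix(list(), 1, 2)
  tiles[[1, 1]] <- t1; tiles[[1, 2]] <- t2
  grid <- tileGrid(tiles, nominalOverlap = 0.25)
  grid$positions[1, 2, ] <- c(0, 18, 0)
  mo <- imgData(blendMosaic(grid))
  prof <- mo[12, , 6]
  expect_equal(prof[1], 10, tolerance = 1e-6)
  expect_equal(prof[length(prof)], 20, tolerance = 1e-6)
  expect_true(all(diff(prof) >= -1e-9))
  expect_true(all(prof <= 20 + 1e-6 & prof >= 10 - 1e-6))
  # two identical fully-overlapping tiles blend to themselves
  tiles2 <- matrix(list(), 1, 2)
  tiles2[[1, 1]] <- t1; tiles2[[1, 2]] <- t1
  g2 <- tileGrid(tiles2, nominalOverlap = 0.25)
  g2$positions[1, 2, ] <- c(0, 0, 0)
  expect_lt(max(abs(imgData(blendMosaic(g2)) - 10)), 1e-6)
})

test_that("rigid polar registration recovers rotation and shift", {
  set.seed(84)
  base <- ts$gaussSmooth(array(rnorm(96 * 96 * 12), c(96, 96, 12)), 2)
  fixed <- VolumeImage(base)
  ident <- registerRigidPolar(fixed, fixed, rotRange = 15)
  expect_lt(abs(ident$rotation), 0.5)
  expect_lte(max(abs(ident$translation)), 1)
  moved <- VolumeImage(ts$rotateVolumeZ(base, -10))
  rec <- registerRigidPolar(moved, fixed, rotRange = 15)
  expect_lt(abs(rec$rotation - 10), 1.0)
  # a 30-degree rotation lies outside the stated +/-15-degree basin
  far <- VolumeImage(ts$rotateVolumeZ(base, -30))
  res <- tryCatch(registerRigidPolar(far, fixed, rotRange = 15),
                  error = function(e) "nomatch")
  bad <- identical(res, "nomatch") || abs(res$rotation - 30) > 5
  expect_true(bad)
})
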