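# Meshing, gradient tuning, active-mesh expansion and skeletonization.

test_that("meshes from masks have correct volume and topology", {
  m <- meshFromMask(solidSphere(radius = 10), 1)
  expect_length(m, 1)
  expect_rel_equal(meshVolume(m[[1]]), 4 / 3 * pi * 1000, 0.05)
  expect_equal(eulerCharacteristic(m[[1]]), 2)
  mt <- meshFromMask(solidTorus(), 1)
  expect_equal(eulerCharacteristic(mt[[1]]), 0)
  expect_length(meshFromMask(array(FALSE, c(8, 8, 8)), 1), 0)
  # anisotropic spacing scales physical coordinates
  ms <- meshFromMask(solidSphere(radius = 8), c(0.5, 0.5, 1))
  expect_rel_equal(meshVolume(ms[[1]]), 4 / 3 * pi * 8^3 * 0.25, 0.06)
  # border-touching components are capped and flagged
  half <- solidSphere(c(21, 41, 41), centre = c(1, 21, 21), radius = 10)
  mb <- meshFromMask(half, 1)
  expect_true(mb[[1]]@flags$borderCapped)
  expect_equal(eulerCharacteristic(mb[[1]]), 2)   # capped, still closed
})

test_that("segmentStructure closes staining holes", {
  tube <- solidCylinderX(len = 40, radius = 3)
  holey <- tube
  holey[25:26, 12, 12] <- FALSE
  img <- VolumeImage(holey * 100)
  out <- segmentStructure(img, 50, closing = 2, minVoxels = 0L)
  expect_true(all(out[25:26, 12, 12]))
  empty <- segmentStructure(VolumeImage(array(0, c(8, 8, 8))), 50)
  expect_equal(sum(empty), 0)
})

test_that("gradient tuning recovers the true radius of a blurred sphere", {
  d <- c(48, 48, 48)
  sph <- solidSphere(d, radius = 10)
  blur <- ts$gaussSmooth(sph * 1000, 1.0)
  img <- VolumeImage(blur, spacing = 1)
  thr <- ts$kapurThresholdValues(as.numeric(blur), 128L)
  mesh0 <- meshFromMask(blur > thr, 1)[[1]]
  ctr0 <- colMeans(meshVertices(mesh0))
  r0 <- mean(sqrt(rowSums(sweep(meshVertices(mesh0), 2, ctr0)^2)))
  tuned <- tuneMeshToGradient(mesh0, img, search = 3)
  ctr <- colMeans(meshVertices(tuned))
  rt <- sqrt(rowSums(sweep(meshVertices(tuned), 2, ctr)^2))
  expect_lt(abs(mean(rt) - 10), 0.25)
  expect_lt(abs(mean(rt) - 10), abs(r0 - 10))   # tuning beats thresholding
  # tuning reduces the radius error for blur sigmas up to 2 voxels
  for (sg in c(1.5, 2)) {
    b <- ts$gaussSmooth(sph * 1000, sg)
    im <- VolumeImage(b, spacing = 1)
    m0 <- meshFromMask(b > ts$kapurThresholdValues(as.numeric(b), 128L),
                       1)[[1]]
    c0 <- colMeans(meshVertices(m0))
    e0 <- abs(mean(sqrt(rowSums(sweep(meshVertices(m0), 2, c0)^2))) - 10)
    tu <- tuneMeshToGradient(m0, im, search = 3)
    ct <- colMeans(meshVertices(tu))
    et <- abs(mean(sqrt(rowSums(sweep(meshVertices(tu), 2, ct)^2))) - 10)
    expect_lt(et, e0)
  }
  # a mesh already on the gradient maxima barely moves
  again <- tuneMeshToGradient(tuned, img, search = 1)
  expect_lt(mean(sqrt(rowSums((meshVertices(again) -
                               meshVertices(tuned))^2))), 0.35)
})

test_that("active meshes inflate to bright walls and respect collisions", {
  d <- c(40, 40, 40)
  co <- as.matrix(expand.grid(1:40, 1:40, 1:40))
  rr <- sqrt(rowSums((co - 20.5)^2))
  wall <- array(1000 * (rr >= 12 & rr <= 14), d)
  img <- VolumeImage(wall, spacing = 1)
  ico <- ts$icosphere(3L)
  seed <- new("TriangleMesh",
              vertices = sweep(ico$vertices * 3, 2, c(19.5, 19.5, 19.5),
                               "+"),
              triangles = ico$triangles, flags = list())
  out <- expandActiveMesh(seed, img, pressure = 1, stopIntensity = 500)
  rv <- sqrt(rowSums(sweep(meshVertices(out), 2, c(19.5, 19.5, 19.5))^2))
  expect_lt(abs(mean(rv) - 11.5), 1.0)   # stops at the inner wall rise
  expect_identical(expandActiveMesh(seed, img, pressure = 0), seed)
  # two chambers sharing a wall: meshes meet, intersection volume zero
  wall2 <- array(0, c(60, 40, 40))
  wall2[30:31, , ] <- 1000                       # dividing wall
  img2 <- VolumeImage(wall2, spacing = 1)
  occ <- new.env(); occ$grid <- array(0L, dim(wall2))
  s1 <- new("TriangleMesh",
            vertices = sweep(ico$vertices * 3, 2, c(15, 20, 20), "+"),
            triangles = ico$triangles, flags = list())
  s2 <- new("TriangleMesh",
            vertices = sweep(ico$vertices * 3, 2, c(45, 20, 20), "+"),
            triangles = ico$triangles, flags = list())
  st1 <- ts$activeMeshInit(s1, img2, 1, 0.35, NULL, 500, 0.25, 1L)
  st2 <- ts$activeMeshInit(s2, img2, 1, 0.35, NULL, 500, 0.25, 2L)
  for (i in 1:400) {
    if (!st1$done) st1 <- ts$activeMeshStep(st1, occ)
    if (!st2$done) st2 <- ts$activeMeshStep(st2, occ)
    if (st1$done && st2$done) break
  }
  m1 <- ts$meshToMask(new("TriangleMesh", vertices = st1$V,
                          triangles = st1$tri), dim(wall2), c(1, 1, 1))
  m2 <- ts$meshToMask(new("TriangleMesh", vertices = st2$V,
                          triangles = st2$tri), dim(wall2), c(1, 1, 1))
  expect_equal(sum(m1 & m2), 0)
  expect_lt(max(meshVertices(new("TriangleMesh", vertices = st1$V,
                                 triangles = st1$tri))[, 1]), 32)
})

test_that("skeleton graphs measure cylinders and junction angles", {
  cyl <- solidCylinderX(len = 100, radius = 4)
  g <- skeletonizeToGraph(cyl, 1)
  e <- graphEdges(g)
  expect_equal(nrow(e), 1)
  expect_rel_equal(e$length, 100, 0.05)
  expect_lt(abs(e$meanRadius - 4), 0.5)
  n <- graphNodes(g)
  expect_true(all(n$degree == 1))
  # skeleton length is stable under 1-voxel dilation
  gd <- skeletonizeToGraph(ts$dilateBall(cyl, 1), 1)
  expect_rel_equal(sum(graphEdges(gd)$length), sum(e$length), 0.05)
  # empty mask
  g0 <- skeletonizeToGraph(array(FALSE, c(8, 8, 8)), 1)
  expect_equal(nrow(graphNodes(g0)), 0)
  # symmetric 120-degree Y junction
  d <- c(81, 81, 21)
  arms <- list(c(0, 1), c(sin(2 * pi / 3), cos(2 * pi / 3)),
               c(sin(4 * pi / 3), cos(4 * pi / 3)))
  mask <- array(FALSE, d)
  ctr <- c(41, 41, 11)
  pts <- do.call(rbind, lapply(arms, function(u) {
    t(vapply(seq(0, 30, by = 0.25),
             function(s) c(ctr[1] + s * u[1], ctr[2] + s * u[2], ctr[3]),
             numeric(3)))
  }))
  mask <- array(ts$.stamp_points(mask, d, pts - 1), d)
  mask <- ts$dilateBall(mask, 3)
  gy <- skeletonizeToGraph(mask, 1)
  ny <- graphNodes(gy)
  expect_equal(sum(ny$degree >= 3), 1)
  # tangent window of most of the straight arms: chords over a longer window suppress the 26-connectivity staircase wobble
  st <- networkStats(gy, tissueVolume = prod(d) * 1e-9, tangentLength = 25)
  expect_equal(length(st$branchAngles), 3)
  expect_true(all(abs(st$branchAngles - 120) < 5))
})
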