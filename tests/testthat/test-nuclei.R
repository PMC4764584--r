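# Ellipsoid fitting, multiplicity classification, LoG seeding, splitting,
# DAPI integrals and histogram normalization.

test_that("minimum-volume ellipsoid recovers axes, encloses and rotates", {
  set.seed(31)
  th <- runif(400, 0, 2 * pi); ph <- acos(runif(400, -1, 1))
  P <- cbind(6 * sin(ph) * cos(th), 5 * sin(ph) * sin(th), 4 * cos(ph))
  e <- fitMinVolumeEllipsoid(P)
  ax <- semiAxes(e)
  expect_lt(max(abs(ax - c(6, 5, 4)) / c(6, 5, 4)), 0.01)
  expect_lte(max(ts$ellipsoidQF(e, P)), 1.001)
  # rotation equivariance
  a <- 0.7
  R <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
  e2 <- fitMinVolumeEllipsoid(P %*% t(R))
  expect_lt(max(abs(semiAxes(e2) - ax) / ax), 0.01)
  expect_equal(e2@E, R %*% e@E %*% t(R), tolerance = 0.05)
  expect_error(fitMinVolumeEllipsoid(cbind(P[, 1:2], 0)), "coplanar")
  expect_error(fitMinVolumeEllipsoid(P[1:5, ]), "10 points")
})

test_that("ellipsoid MSE follows the (n-9)-normalized formula", {
  e <- new("Ellipsoid", c = c(0, 0, 0), E = diag(1 / c(4, 9, 16)))
  # points exactly on the ellipsoid
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  P <- cbind(2 * cos(th), 3 * sin(th), 0)
  mesh <- new("TriangleMesh", vertices = P,
              triangles = matrix(rep(1:3, 4), 4, 3), flags = list())
  expect_equal(ellipsoidFitMSE(mesh, e), 0, tolerance = 1e-12)
  # hand-evaluated toy set
  set.seed(32)
  P2 <- matrix(rnorm(30), 10, 3)
  mesh2 <- new("TriangleMesh", vertices = P2,
               triangles = matrix(rep(1:3, 4), 4, 3), flags = list())
  qf <- rowSums((sweep(P2, 2, e@c) %*% e@E) * sweep(P2, 2, e@c))
  expect_equal(ellipsoidFitMSE(mesh2, e), sum((qf - 1)^2) / (10 - 9))
  # a dumbbell of two fused spheres prefers the double model
  m1 <- solidSphere(c(51, 31, 31), centre = c(16, 16, 16), radius = 9)
  m2 <- solidSphere(c(51, 31, 31), centre = c(34, 16, 16), radius = 9)
  dumb <- meshFromMask(m1 | m2, 1)[[1]]
  single <- fitMinVolumeEllipsoid(meshVertices(dumb))
  dbl <- ts$fitDoubleEllipsoid(dumb)
  expect_lt(ellipsoidFitMSE(dumb, dbl), ellipsoidFitMSE(dumb, single))
  small <- new("TriangleMesh", vertices = P2[1:9, ],
               triangles = matrix(rep(1:3, 4), 4, 3), flags = list())
  expect_error(ellipsoidFitMSE(small, e), "9 vertices")
})

test_that("multiplicity threshold matches the mixture's 95% bound", {
  set.seed(33)
  x <- c(rnorm(300, -4, 0.5), rnorm(200, -1, 0.5))
  cls <- classifyMultiplicity(x, rep(c("mono", "double"), c(300, 200)))
  expect_false(cls$fallback)
  expect_lt(abs(cls$threshold - (-4 + 1.96 * 0.5)), 0.25)
  # labels are monotone in ln(MSE)
  mult <- cls$multiplicity
  expect_true(max(x[mult != "multi"]) <= min(c(x[mult == "multi"], Inf)))
  # identical values fall back with a flag
  cls2 <- classifyMultiplicity(rep(1, 40))
  expect_true(cls2$fallback)
})

test_that("LoGMP seeds blobs at the expected scale", {
  d <- c(48, 48, 48)
  co <- as.matrix(expand.grid(1:48, 1:48, 1:48))
  blob <- array(exp(-((co[, 1] - 24)^2 + (co[, 2] - 24)^2 +
                      (co[, 3] - 24)^2) / (2 * 16)), d)
  img <- VolumeImage(blob, spacing = 1)
  s <- logmpSeeds(img, 2, 6)
  expect_equal(nrow(s), 1)
  expect_lt(max(abs(s - 23)), 1.5)        # 0-based µm coords of voxel 24
  # two overlapping spheres give two seeds
  d2 <- sqrt((co[, 1] - 17)^2 + (co[, 2] - 24)^2 + (co[, 3] - 24)^2)
  d3 <- sqrt((co[, 1] - 31)^2 + (co[, 2] - 24)^2 + (co[, 3] - 24)^2)
  two <- array(1000 * (d2 <= 9 | d3 <= 9), d)
  img2 <- VolumeImage(ts$gaussSmooth(two, 1), spacing = 1)
  s2 <- logmpSeeds(img2, 9 / sqrt(2) * 0.7, 9 / sqrt(2) * 1.3)
  expect_equal(nrow(s2), 2)
  expect_equal(nrow(logmpSeeds(VolumeImage(array(0, d)), 2, 6)), 0)
  expect_error(logmpSeeds(img, 6, 2), "sigmaMin")
})

test_that("splitting separates overlapping nuclei and conserves volume", {
  d <- c(64, 40, 40)
  co <- as.matrix(expand.grid(1:64, 1:40, 1:40))
  r <- 10
  c1 <- c(24, 20, 20); c2 <- c(24 + 1.4 * r, 20, 20)   # 30% overlap
  m <- array(sqrt(rowSums(sweep(co, 2, c1)^2)) <= r |
             sqrt(rowSums(sweep(co, 2, c2)^2)) <= r, d)
  dapi <- VolumeImage(ts$gaussSmooth(m * 1000, 1), spacing = 1)
  res <- splitNuclei(dapi, mask = m, minVoxels = 100L,
                     sigmaRange = c(r * 0.7, r * 1.3) / sqrt(2))
  expect_gte(length(res$objects), 2)
  cents <- t(vapply(res$objects, function(o) colMeans(o@mesh@vertices),
                    numeric(3)))
  d1 <- min(sqrt(rowSums(sweep(cents, 2, c1 - 1)^2)))
  d2 <- min(sqrt(rowSums(sweep(cents, 2, c2 - 1)^2)))
  expect_lt(d1, 2); expect_lt(d2, 2)
  vols <- vapply(res$objects, function(o) meshVolume(o@mesh), 0)
  parent <- sum(m)
  expect_gte(sum(vols), 0.8 * parent)
  expect_lte(sum(vols), 1.05 * parent)
  # a mono object passes through unchanged
  obj <- new("NucleusObject", mesh = res$objects[[1]]@mesh,
             multiplicity = "mono", dapiIntegral = 1, seed = c(0, 0, 0))
  expect_identical(splitMultinucleus(obj, dapi, m)[[1]], obj)
})

test_that("DAPI integral sums voxels inside the mesh", {
  sph <- solidSphere(c(31, 31, 31), radius = 9)
  mesh <- meshFromMask(sph, 1)[[1]]
  img <- VolumeImage(array(10, c(31, 31, 31)), spacing = 1)
  v <- dapiIntegral(mesh, img)
  expect_equal(v, 10 * sum(ts$meshToMask(mesh, c(31, 31, 31), c(1, 1, 1))))
  # brute-force point-in-mesh oracle on a small case: compare against the
  # voxelized sphere itself
  expect_rel_equal(v, 10 * sum(sph), 0.05)
  # additivity over disjoint meshes
  s2 <- solidSphere(c(31, 31, 31), centre = c(8, 8, 8), radius = 5)
  mesh2 <- meshFromMask(s2, 1)[[1]]
  both <- dapiIntegral(mesh, img) + dapiIntegral(mesh2, img)
  expect_equal(both, 10 * (sum(ts$meshToMask(mesh, c(31, 31, 31), c(1, 1, 1))) +
                           sum(ts$meshToMask(mesh2, c(31, 31, 31),
                                             c(1, 1, 1)))))
})

test_that("histogram stretching recovers the scale factor", {
  set.seed(34)
  ref <- rlnorm(20000, log(100), 0.3)
  h0 <- hist(ref, breaks = 80, plot = FALSE)
  expect_lt(abs(normalizeDapi(h0, h0) - 1), 0.02)
  hs <- hist(ref * 1.25, breaks = 80, plot = FALSE)
  s <- normalizeDapi(h0, hs)
  expect_rel_equal(s, 1.25, 0.02)
})
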