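# Network statistics, cylinder consistency, the lobule coordinate, zonation
# profiles, ploidy clustering and log-normal mixtures.

test_that("cylinder consistency reproduces the printed sample ratios", {
  r1 <- cylinderConsistency(Vs = 0.16, Ls = 2853.4, rs = 4.05e-3)
  expect_equal(r1$ratio, 0.92, tolerance = 0.01)
  expect_equal(cylinderConsistency(0.5, 100, 0)$Vc, 0)
  expect_error(cylinderConsistency(0, 1, 1))
  # a generated straight cylinder network is self-consistent
  cyl <- solidCylinderX(len = 100, radius = 4)
  g <- skeletonizeToGraph(cyl, 1)
  vol <- prod(dim(cyl)) * 1e-9            # mm^3
  st <- networkStats(g, vol)
  check <- cylinderConsistency(sum(cyl) * 1e-9 / vol, st$Ls, st$rs)
  expect_gt(check$ratio, 0.8); expect_lt(check$ratio, 1.2)
})

test_that("network statistics are exact on a straight cylinder", {
  cyl <- solidCylinderX(len = 100, radius = 4)
  g <- skeletonizeToGraph(cyl, 1)
  vol <- prod(dim(cyl)) * 1e-9
  st <- networkStats(g, vol)
  expect_equal(length(st$branchAngles), 0)
  expect_rel_equal(st$Ls, sum(graphEdges(g)$length) / 1000 / vol, 1e-9)
  expect_equal(st$nodeDensity, 0)
})

test_that("the chi coordinate meets its endpoint and midpoint identities", {
  expect_equal(chiCoordinate(0, 100, 100), 0)
  expect_equal(chiCoordinate(100, 0, 100), 100)
  expect_equal(chiCoordinate(50, 50, 100), 50)
  # strictly increasing along a straight CV -> PV segment
  dcv <- seq(0, 100, length.out = 11)
  chi <- chiCoordinate(dcv, 100 - dcv, 100)
  expect_true(all(diff(chi) > 0))
  # property: range and endpoints over random admissible inputs
  set.seed(51)
  for (i in 1:200) {
    D <- runif(1, 10, 500)
    dc <- runif(1, 0, D); dp <- runif(1, 0, D)
    v <- chiCoordinate(dc, dp, D)
    expect_gte(v, 0); expect_lte(v, 100)
  }
  expect_equal(chiCoordinate(0, 73, 73), 0)
  expect_equal(chiCoordinate(73, 0, 73), 100)
  expect_error(chiCoordinate(1, 1, 0), "positive")
})

test_that("zonation profiles are flat under uniformity and find enrichment", {
  set.seed(52)
  n <- 4000
  cells <- data.frame(chi = runif(n, 0, 100),
                      population = sample(c("2n", "4n"), n, TRUE),
                      boundary = FALSE)
  prof <- zonationProfile(cells, bins = 5)
  expect_lt(max(abs(prof - 1), na.rm = TRUE), 0.2)
  # normalization identity: population-share-weighted mean is 1 per bin
  shares <- table(cells$population) / n
  weighted <- prof %*% as.numeric(shares)
  expect_true(all(abs(weighted - 1) < 1e-9))
  # planted 3x enrichment of one population at chi < 20
  n2 <- 2000
  chi <- runif(n2, 0, 100)
  p <- ifelse(chi < 20, 0.6, 0.2)
  pop <- ifelse(runif(n2) < p, "2x2n", "2n")
  prof2 <- zonationProfile(data.frame(chi = chi, population = pop,
                                      boundary = FALSE), bins = 5)
  ratio <- prof2[1, "2x2n"] / mean(prof2[2:5, "2x2n"])
  expected <- 0.6 / 0.2 * mean(prof2[2:5, "2x2n"]) /
    mean(prof2[2:5, "2x2n"])
  expect_rel_equal(prof2[1, "2x2n"] / prof2[3, "2x2n"], 3, 0.15)
})

test_that("ploidy clustering recovers planted DAPI populations", {
  set.seed(53)
  nPer <- 80
  dapi <- c(rnorm(nPer, 1, 0.08), rnorm(nPer, 2, 0.16),
            rnorm(nPer, 4, 0.3), rnorm(nPer, 8, 0.6))
  vol <- c(rnorm(nPer, 3000, 300), rnorm(nPer, 4500, 400),
           rnorm(nPer, 6500, 500), rnorm(nPer, 9000, 700))
  truth <- rep(c("2n", "4n", "8n", "16n"), each = nPer)
  cells <- data.frame(volume = vol, dapi = dapi, nNuclei = 1L)
  out <- ploidyCluster(cells)
  expect_gt(mean(out$population == truth), 0.95)
  # scaling invariance via standardization
  cells2 <- cells; cells2$volume <- cells2$volume * 1000
  out2 <- ploidyCluster(cells2)
  expect_equal(out$population, out2$population)
  expect_error(ploidyCluster(data.frame(volume = 1:10, dapi = 1:10,
                                        nNuclei = 1L)), "fewer cells")
})

test_that("log-normal mixtures are recovered and canonically ordered", {
  # k = 1 closed form
  set.seed(54)
  x <- rlnorm(500, log(5000), 0.25)
  f1 <- fitLognormalMixture(x, k = 1)
  expect_equal(f1$meanlog, mean(log(x)))
  expect_equal(f1$sdlog, sqrt(mean((log(x) - mean(log(x)))^2)))
  # two components with the separation seen in hepatocyte volumes
  x2 <- c(rlnorm(1200, log(5678), 0.2), rlnorm(800, log(10606), 0.14))
  f2 <- fitLognormalMixture(x2, k = 2, seed = 9)
  expect_true(all(diff(f2$mean) > 0))
  expect_rel_equal(f2$mean[1], 5678, 0.05)
  expect_rel_equal(f2$mean[2], 10606, 0.05)
  expect_error(fitLognormalMixture(c(-1, x2), 2), "positive")
})
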