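# Synthetic FISH generator: determinism, placement geometry, ground-truth
# consistency and error handling.

test_that("identical spec and seed reproduce bit-identical images", {
  spec <- SyntheticSpec(seed = 11)
  a <- simulateNucleus2D(spec)
  b <- simulateNucleus2D(spec)
  expect_identical(dapiChannel(a$image), dapiChannel(b$image))
  expect_identical(probeChannel(a$image), probeChannel(b$image))
  expect_identical(a$truth, b$truth)

  spec3 <- SyntheticSpec(axesRange = c(2.5, 4), seed = 12)
  s1 <- simulateStack3D(spec3)
  s2 <- simulateStack3D(spec3)
  expect_identical(dapiChannel(s1$stack), dapiChannel(s2$stack))

  d1 <- simulateConditionDataset("quiescent", n = 3, seed = 5)
  d2 <- simulateConditionDataset("quiescent", n = 3, seed = 5)
  expect_identical(d1$truth, d2$truth)
  expect_identical(dapiChannel(d1$images[[2]]), dapiChannel(d2$images[[2]]))
})

test_that("radial fraction 0 with no jitter places the territory at the nucleus centre", {
  spec <- SyntheticSpec(radialFraction = 0, radialJitterSD = 0,
                        nTerritories = 1, seed = 3)
  sim <- simulateNucleus2D(spec)
  expect_equal(c(sim$truth$x_um, sim$truth$y_um), sim$nucleus$centre,
               tolerance = 1e-12)
  expect_equal(sim$truth$radial_fraction, 0)
})

test_that("a spherical nucleus gives centre-to-edge distance equal to its radius", {
  spec <- SyntheticSpec(axesRange = c(4, 4), radialFraction = 0,
                        radialJitterSD = 0, nTerritories = 1, seed = 8)
  sim <- simulateStack3D(spec)
  expect_equal(sim$truth$edge_distance_um, 4, tolerance = 1e-4)
})

test_that("noiseless uniform DAPI spreads 20% of signal into each equal-area shell", {
  spec <- SyntheticSpec(photonScale = 0, gaussianSD = 0,
                        backgroundLevel = 0, seed = 21)
  sim <- simulateNucleus2D(spec)
  shells <- equalAreaShells(NucleusMask(sim$mask,
                                        rep(spec@pixelSize, 2)))
  pct <- shellFractions(dapiChannel(sim$image), shells)
  expect_equal(pct, rep(20, 5), tolerance = 1e-3)
  # oracle: brute-force per-pixel sums over the emitted shell labels
  sums <- oracleShellSums(dapiChannel(sim$image), shellLabels(shells), 5)
  expect_equal(pct, 100 * sums / sum(sums), tolerance = 1e-12)
})

test_that("with no jitter the realized radial fraction matches r0 on the emitted mask", {
  for (r0 in c(0.3, 0.6, 0.8)) {
    spec <- SyntheticSpec(radialFraction = r0, radialJitterSD = 0,
                          nTerritories = 2, seed = round(100 * r0))
    sim <- simulateNucleus2D(spec)
    px <- spec@pixelSize
    for (i in seq_len(nrow(sim$truth))) {
      f <- realizedRadialFraction(c(sim$truth$x_um[i], sim$truth$y_um[i]),
                                  sim$mask, rep(px, 2))
      # 2 pixels of discretization allowance relative to the ray length
      tol <- 2 * px / (min(spec@axesRange))
      expect_lt(abs(f - r0), tol)
    }
  }
})

test_that("recorded edge distances match exhaustive boundary search on the emitted mask", {
  spec2 <- SyntheticSpec(radialFraction = 0.6, seed = 31)
  sim2 <- simulateNucleus2D(spec2)
  px <- spec2@pixelSize
  for (i in seq_len(nrow(sim2$truth))) {
    ora <- oracleEdgeDistance(c(sim2$truth$x_um[i], sim2$truth$y_um[i]),
                              sim2$mask, rep(px, 2))
    expect_lt(abs(ora - sim2$truth$edge_distance_um[i]),
              sqrt(2) * px + 1e-9)
  }

  spec3 <- SyntheticSpec(axesRange = c(2.5, 4), radialFraction = 0.4,
                         seed = 32)
  sim3 <- simulateStack3D(spec3)
  vox <- c(spec3@pixelSize, spec3@pixelSize, spec3@zSpacing)
  for (i in seq_len(nrow(sim3$truth))) {
    ora <- oracleEdgeDistance(unlist(sim3$truth[i, c("x_um", "y_um",
                                                     "z_um")]),
                              sim3$mask, vox)
    expect_lt(abs(ora - sim3$truth$edge_distance_um[i]),
              sqrt(sum(vox^2)) + 1e-9)
  }
})

test_that("jittered placements stay inside [0, 1] and inside the nucleus", {
  spec <- SyntheticSpec(radialFraction = 0.9, radialJitterSD = 0.5,
                        nTerritories = 4, seed = 44)
  sim <- simulateNucleus2D(spec)
  expect_true(all(sim$truth$radial_fraction >= 0))
  expect_true(all(sim$truth$radial_fraction <= 1))
  expect_true(all(sim$truth$edge_distance_um > 0))
})

test_that("infeasible territory placements and degenerate stacks are rejected", {
  expect_error(
    simulateNucleus2D(SyntheticSpec(territoryRadius = 2,
                                    radialFraction = 0.95, seed = 1),
                      id = "bad-nucleus"),
    "bad-nucleus")
  expect_error(
    simulateStack3D(SyntheticSpec(axesRange = c(2.5, 4), zSpacing = 3,
                                  seed = 1)),
    "degenerate stack")
})

test_that("condition presets carry Ki-67 labels and reject unknown conditions", {
  ds <- simulateConditionDataset("proliferating", n = 2, seed = 1)
  expect_true(all(vapply(ds$images, function(x) x@ki67, logical(1))))
  ds <- simulateConditionDataset("senescent", n = 2, seed = 1)
  expect_false(any(vapply(ds$images, function(x) x@ki67, logical(1))))
  expect_error(simulateConditionDataset("exponential", n = 2),
               "proliferating, quiescent, senescent")
})

test_that("an empty dataset request yields a valid empty truth table", {
  ds <- simulateConditionDataset("quiescent", n = 0, seed = 1)
  expect_length(ds$images, 0)
  expect_s3_class(ds$truth, "data.frame")
  expect_identical(nrow(ds$truth), 0L)
  expect_true(all(c("id", "radial_fraction", "edge_distance_um",
                    "condition") %in% names(ds$truth)))
})
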