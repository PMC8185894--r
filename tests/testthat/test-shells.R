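# Equal-area erosion shells, per-shell quantification, normalization,
# aggregation and positional categorization.

discMask <- function(radius, pad = 3) {
  n <- 2 * (radius + pad) + 1
  ctr <- radius + pad + 1
  m <- (row(matrix(0, n, n)) - ctr)^2 + (col(matrix(0, n, n)) - ctr)^2 <=
    radius^2
  list(mask = NucleusMask(m, c(1, 1)), centre = c(ctr, ctr))
}

test_that("equal-area shells of a disc follow the expected annulus geometry", {
  d <- discMask(100)
  shells <- equalAreaShells(d$mask)
  lab <- shellLabels(shells)
  at <- function(r, ang = 0.3) {
    ij <- round(d$centre + r * c(cos(ang), sin(ang)))
    lab[ij[1], ij[2]]
  }
  expect_identical(at(95), 1L)
  expect_identical(at(10), 5L)
  # inner edge of shell 1 at radius 100 * sqrt(4/5) ~ 89.4
  pos <- arrayInd(which(lab == 1L), dim(lab))
  rr <- sqrt((pos[, 1] - d$centre[1])^2 + (pos[, 2] - d$centre[2])^2)
  expect_equal(min(rr), 100 * sqrt(4 / 5), tolerance = 0.02)
})

test_that("shells partition random masks exactly into near-equal areas", {
  for (seed in 1:10) {
    m <- makeBlobbyMask(seed)
    mask <- NucleusMask(m, c(1, 1))
    shells <- equalAreaShells(mask)
    lab <- shellLabels(shells)
    # exact partition of the mask
    expect_identical(lab > 0, m)
    counts <- oracleShellCounts(lab, 5)
    expect_identical(as.numeric(shellAreas(shells)), counts)
    expect_true(all(abs(counts - sum(m) / 5) <= max(5, 0.015 * sum(m) / 5)))
    # every boundary pixel is in shell 1
    d <- EBImage::distmap(m * 1)
    expect_true(all(lab[m & d <= 1] == 1L))
    # shell index is non-decreasing with distance from the boundary
    splits <- split(as.numeric(d[m]), lab[m])
    for (k in 2:5)
      expect_gte(min(splits[[k]]), max(splits[[k - 1]]))
  }
})

test_that("too-small masks are rejected", {
  m <- matrix(FALSE, 8, 8)
  m[3:4, 3:7] <- TRUE  # 10 px
  expect_error(equalAreaShells(NucleusMask(m, c(1, 1)), nShells = 5),
               "too small")
})

test_that("shell fractions match a per-pixel accumulation oracle", {
  set.seed(42)
  d <- discMask(40)
  shells <- equalAreaShells(d$mask)
  uniform <- matrix(3.7, dim(shellLabels(shells))[1],
                    dim(shellLabels(shells))[2])
  expect_equal(shellFractions(uniform, shells), rep(20, 5),
               tolerance = 2e-3)

  inner <- (shellLabels(shells) == 5L) * 7
  expect_equal(shellFractions(inner, shells), c(0, 0, 0, 0, 100))

  rnd <- matrix(runif(length(uniform)), nrow(uniform))
  sums <- oracleShellSums(rnd, shellLabels(shells), 5)
  expect_equal(shellFractions(rnd, shells), 100 * sums / sum(sums),
               tolerance = 1e-12)

  expect_error(shellFractions(uniform * 0, shells), "zero total")
})

test_that("DAPI normalization follows its defining arithmetic", {
  expect_equal(normalizedProfile(rep(20, 5), rep(20, 5)), rep(1, 5))
  expect_equal(normalizedProfile(c(40, 30, 20, 10, 0), rep(20, 5)),
               c(2, 1.5, 1, 0.5, 0))
  expect_error(normalizedProfile(c(25, 25, 25, 25, 0), c(25, 25, 25, 25, 0)),
               "degenerate shell")
  expect_error(normalizedProfile(rep(10, 5), rep(20, 5)), "sum to 100")
})

test_that("a probe channel proportional to DAPI normalizes to ones", {
  for (seed in 1:5) {
    sim <- simulateNucleus2D(SyntheticSpec(seed = seed))
    mask <- segmentNucleus(sim$image)
    shells <- equalAreaShells(mask)
    dapi <- dapiChannel(sim$image)
    norm <- normalizedProfile(shellFractions(2.9 * dapi, shells),
                              shellFractions(dapi, shells))
    expect_equal(norm, rep(1, 5), tolerance = 1e-9)
  }
})

test_that("aggregation reproduces mean and SEM", {
  p <- matrix(rep(c(1.4, 1.1, 1, 0.9, 0.6), each = 2), nrow = 2)
  cp <- suppressWarnings(aggregateProfiles(p))
  expect_equal(profileMean(cp), c(1.4, 1.1, 1, 0.9, 0.6))
  expect_equal(profileSEM(cp), rep(0, 5))

  two <- rbind(c(1, 1, 1, 1, 1), c(3, 1, 1, 1, 1))
  cp2 <- suppressWarnings(aggregateProfiles(two))
  expect_equal(profileMean(cp2)[1], 2)
  expect_equal(profileSEM(cp2)[1], 1)

  expect_error(aggregateProfiles(two[1, , drop = FALSE]), "at least 2")
  expect_warning(aggregateProfiles(two), "fewer than the customary")

  set.seed(1)
  many <- matrix(rexp(50 * 5), 50, 5)
  cp3 <- aggregateProfiles(many)
  for (k in 1:5) {
    o <- streamingMeanSEM(many[, k])
    expect_equal(profileMean(cp3)[k], unname(o["mean"]), tolerance = 1e-12)
    expect_equal(profileSEM(cp3)[k], unname(o["sem"]), tolerance = 1e-12)
  }
})

test_that("positional categorization applies the skew rule", {
  expect_identical(as.character(categorizePosition(c(1.6, 1.3, 0.9, 0.6, 0.4))),
                   "peripheral")
  expect_identical(as.character(categorizePosition(c(0.4, 0.7, 1.0, 1.4, 1.7))),
                   "interior")
  expect_identical(as.character(categorizePosition(c(1, 1, 1, 1, 1))),
                   "intermediate")
  # ordered factor: interior < intermediate < peripheral
  expect_true(categorizePosition(rep(1, 5)) <
                categorizePosition(c(1.6, 1.3, 0.9, 0.6, 0.4)))
})

test_that("categorization is invariant to nucleus order and duplication", {
  set.seed(7)
  prof <- matrix(rexp(20 * 5, rate = 1), 20, 5)
  cat1 <- categorizePosition(suppressWarnings(aggregateProfiles(prof)))
  shuffled <- prof[sample(nrow(prof)), ]
  cat2 <- categorizePosition(suppressWarnings(aggregateProfiles(shuffled)))
  doubled <- rbind(prof, prof)
  cat3 <- categorizePosition(suppressWarnings(aggregateProfiles(doubled)))
  expect_identical(cat1, cat2)
  expect_identical(cat1, cat3)
})

test_that("category moves monotonically from interior to peripheral with r0", {
  cats <- vapply(c(0.2, 0.45, 0.70, 0.85), function(r0) {
    spec <- SyntheticSpec(radialFraction = r0, seed = 1000 + round(100 * r0))
    profs <- lapply(1:12, function(i) {
      sim <- simulateNucleus2D(spec, id = sprintf("n%02d", i),
                               seed = spec@seed + i)
      shellProfile(sim$image)
    })
    cp <- suppressWarnings(aggregateProfiles(do.call(rbind, profs)))
    as.character(categorizePosition(cp))
  }, character(1))
  ord <- factor(cats, levels = c("interior", "intermediate", "peripheral"),
                ordered = TRUE)
  expect_true(all(diff(as.integer(ord)) >= 0))
  expect_identical(cats[1], "interior")
  expect_identical(cats[3], "intermediate")
  expect_identical(cats[4], "peripheral")
})
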