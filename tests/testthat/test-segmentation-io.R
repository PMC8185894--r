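# Image reading/writing and nucleus/territory segmentation.

test_that("TIFF round-trip preserves 2D and 3D intensities", {
  sim <- simulateNucleus2D(SyntheticSpec(seed = 7))
  f <- tempfile(fileext = ".tif")
  writeFISHImage(sim$image, f)
  back <- readFISHImage(f, pixelSize = 0.1, id = "rt")
  expect_equal(dapiChannel(back), dapiChannel(sim$image), tolerance = 1e-6)
  expect_equal(probeChannel(back), probeChannel(sim$image),
               tolerance = 1e-6)

  sim3 <- simulateStack3D(SyntheticSpec(axesRange = c(2.5, 4), seed = 7))
  f3 <- tempfile(fileext = ".tif")
  writeFISHImage(sim3$stack, f3)
  back3 <- readFISHImage(f3, pixelSize = 0.1, zSpacing = 0.2)
  expect_identical(dim(dapiChannel(back3)), dim(dapiChannel(sim3$stack)))
  expect_equal(dapiChannel(back3), dapiChannel(sim3$stack),
               tolerance = 1e-6)
  expect_equal(voxelSize(back3), c(0.1, 0.1, 0.2))
})

test_that("bad channel maps and missing files give distinct errors", {
  sim <- simulateNucleus2D(SyntheticSpec(seed = 9))
  f <- tempfile(fileext = ".tif")
  writeFISHImage(sim$image, f)
  expect_error(readFISHImage(f, channelMap = c(dapi = 1, probe = 5)),
               "channels 1, 2")
  expect_error(readFISHImage(f, channelMap = c(dapi = 1, green = 2)),
               "probe")
  expect_error(readFISHImage(tempfile(fileext = ".tif")), "no such file")
})

test_that("dataset round-trip restores images and Ki-67 metadata", {
  ds <- simulateConditionDataset("quiescent", n = 2, seed = 3)
  dir <- tempfile("dataset")
  writeConditionDataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  back <- readConditionDataset(dir)
  expect_length(back$images, 2)
  expect_equal(dapiChannel(back$images[[1]]), dapiChannel(ds$images[[1]]),
               tolerance = 1e-6)
  expect_false(back$images[[1]]@ki67)
  expect_identical(imageId(back$images[[2]]), ds$manifest$id[2])
})

test_that("nucleus segmentation recovers the true mask on a noiseless ellipse", {
  spec <- SyntheticSpec(photonScale = 0, gaussianSD = 0, seed = 13)
  sim <- simulateNucleus2D(spec)
  mask <- segmentNucleus(sim$image)
  inter <- sum(maskArray(mask) & sim$mask)
  union <- sum(maskArray(mask) | sim$mask)
  expect_gte(inter / union, 0.98)
})

test_that("segmentation errors and multi-nucleus fields are handled", {
  blank <- NucleusImage(matrix(0, 64, 64), matrix(0, 64, 64), 0.1)
  expect_error(segmentNucleus(blank), "no nucleus found")

  # two discs: the larger is kept, with a warning
  n <- 200
  X <- row(matrix(0, n, n)); Y <- col(matrix(0, n, n))
  img <- 10 + 400 * (((X - 60)^2 + (Y - 60)^2) <= 45^2) +
    400 * (((X - 150)^2 + (Y - 150)^2) <= 30^2)
  expect_warning(m <- segmentNucleus(img, spacing = c(0.1, 0.1)),
                 "keeping the largest")
  inside <- maskArray(m)[60, 60]
  expect_true(inside)
  expect_false(maskArray(m)[150, 150])
  expect_equal(maskArea(m), sum(((X - 60)^2 + (Y - 60)^2) <= 45^2),
               tolerance = 0.02)
})

test_that("segmentation is deterministic and offset-invariant", {
  sim <- simulateNucleus2D(SyntheticSpec(seed = 17))
  m1 <- segmentNucleus(sim$image)
  m2 <- segmentNucleus(sim$image)
  expect_identical(maskArray(m1), maskArray(m2))
  shifted <- NucleusImage(dapiChannel(sim$image) + 57,
                          probeChannel(sim$image), 0.1)
  m3 <- segmentNucleus(shifted)
  expect_identical(maskArray(m1), maskArray(m3))
})

test_that("territory segmentation finds the planted blobs near their true centres", {
  spec <- SyntheticSpec(radialFraction = 0.5, seed = 19)
  sim <- simulateNucleus2D(spec)
  mask <- segmentNucleus(sim$image)
  labels <- segmentTerritories(probeChannel(sim$image), mask)
  expect_length(territorySizes(labels), 2)
  cent <- territoryCentroid(labels, rep(spec@pixelSize, 2))
  # match each found centroid to the nearest planted one
  for (i in seq_len(nrow(cent))) {
    dd <- sqrt((sim$truth$x_um - cent$x_um[i])^2 +
                 (sim$truth$y_um - cent$y_um[i])^2)
    expect_lt(min(dd), 2 * spec@pixelSize)
  }
})

test_that("territory labels are restricted to the mask and size-filtered", {
  sim <- simulateNucleus2D(SyntheticSpec(seed = 23))
  mask <- segmentNucleus(sim$image)
  labels <- segmentTerritories(probeChannel(sim$image), mask)
  expect_true(all(maskArray(mask)[territoryArray(labels) > 0]))

  # probe signal entirely outside the mask: nothing to label
  outside <- matrix(5, nrow(maskArray(mask)), ncol(maskArray(mask)))
  corner <- !maskArray(mask)
  outside[corner][seq_len(400)] <- 500
  expect_warning(empty <- segmentTerritories(outside, mask),
                 "no territories")
  expect_length(territorySizes(empty), 0)

  # a bright fragment below the minimum size is dropped
  probe <- matrix(5, 120, 120)
  m <- matrix(FALSE, 120, 120)
  m[(row(m) - 60)^2 + (col(m) - 60)^2 <= 50^2] <- TRUE
  probe[55:64, 55:64] <- 500      # 100 px blob
  probe[80:81, 80:81] <- 500      # 4 px speck, below minSize = 20
  labels <- segmentTerritories(probe, NucleusMask(m, c(0.1, 0.1)))
  expect_length(territorySizes(labels), 1)
  expect_equal(territorySizes(labels), 100)
})
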