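#' @include AllClasses.R geometry.R utils.R
NULL

# Photon-count (Poisson) noise at `photonScale` photons per intensity
# unit, then additive Gaussian read noise; intensities clamped at 0.
applyNoise <- function(x, photonScale, gaussianSD) {
  d <- dim(x)
  v <- as.numeric(x)
  if (photonScale > 0)
    v <- rpois(length(v), v * photonScale) / photonScale
  if (gaussianSD > 0)
    v <- v + rnorm(length(v), 0, gaussianSD)
  array(pmax(v, 0), dim = d)
}

# Draw a jittered radial fraction for one territory. The jittered value is
# clipped to [0, 1]; it is additionally capped so that the territory blob
# stays inside the nucleus along its placement ray.
drawRadialFraction <- function(spec, rayR, id) {
  if (spec@territoryRadius > rayR * (1 - spec@radialFraction))
    stop(sprintf(paste0("territory radius %.2f um cannot fit at radial ",
                        "fraction %.2f in nucleus '%s' (boundary distance ",
                        "along ray %.2f um)"),
                 spec@territoryRadius, spec@radialFraction, id, rayR))
  f <- spec@radialFraction +
    if (spec@radialJitterSD > 0) rnorm(1, 0, spec@radialJitterSD) else 0
  f <- min(max(f, 0), 1)
  min(f, 1 - spec@territoryRadius / rayR)
}

# Generator core, 2D. Consumes the current RNG stream.
simNucleus2DCore <- function(spec, id, dapiFalloff = 0) {
  px <- spec@pixelSize
  sideUm <- 2 * spec@axesRange[2] + 2
  n <- ceiling(sideUm / px)
  ctr <- rep(n * px / 2, 2)

  axes <- sort(runif(2, spec@axesRange[1], spec@axesRange[2]),
               decreasing = TRUE)
  phi <- runif(1, 0, pi)

  xs <- gridCentres(n, px)
  X <- matrix(xs, n, n) - ctr[1]
  Y <- matrix(xs, n, n, byrow = TRUE) - ctr[2]
  Xr <- cos(phi) * X + sin(phi) * Y
  Yr <- -sin(phi) * X + cos(phi) * Y
  fr2 <- (Xr / axes[1])^2 + (Yr / axes[2])^2
  inside <- fr2 <= 1

  dapi <- spec@backgroundLevel +
    spec@dapiLevel * inside * (1 - dapiFalloff * pmin(fr2, 1))
  probe <- matrix(spec@backgroundLevel, n, n)

  sigma <- spec@territoryRadius / 2
  tr <- vector("list", spec@nTerritories)
  for (j in seq_len(spec@nTerritories)) {
    psi <- runif(1, 0, 2 * pi)
    dirW <- c(cos(psi), sin(psi))
    dirE <- c(cos(phi) * dirW[1] + sin(phi) * dirW[2],
              -sin(phi) * dirW[1] + cos(phi) * dirW[2])
    rayR <- rayBoundaryDistance(dirE, axes)
    f <- drawRadialFraction(spec, rayR, id)
    pos <- ctr + f * rayR * dirW
    d2 <- (X + ctr[1] - pos[1])^2 + (Y + ctr[2] - pos[2])^2
    probe <- probe + spec@probeLevel * exp(-d2 / (2 * sigma^2)) * inside
    pE <- c(cos(phi) * (pos[1] - ctr[1]) + sin(phi) * (pos[2] - ctr[2]),
            -sin(phi) * (pos[1] - ctr[1]) + cos(phi) * (pos[2] - ctr[2]))
    tr[[j]] <- data.frame(
      id = id, territory = j, x_um = pos[1], y_um = pos[2], z_um = NA_real_,
      radial_fraction = f,
      edge_distance_um = interiorBoundaryDistance(pE, axes))
  }

  dapi <- applyNoise(dapi, spec@photonScale, spec@gaussianSD)
  probe <- applyNoise(probe, spec@photonScale, spec@gaussianSD)

  list(image = NucleusImage(dapi, probe, px, ki67 = NA, id = id),
       truth = do.call(rbind, tr),
       nucleus = list(centre = ctr, axes = axes, phi = phi),
       mask = inside)
}

# Generator core, 3D. The nucleus is an ellipsoid with its shortest
# semi-axis along z (adherent nuclei are flattened) and in-plane rotation
# only; the volume is filled slice by slice to bound memory.
simStack3DCore <- function(spec, id) {
  px <- spec@pixelSize
  zs <- spec@zSpacing
  sideUm <- 2 * spec@axesRange[2] + 2
  n <- ceiling(sideUm / px)
  nz <- ceiling((2 * spec@axesRange[2] + 1) / zs)
  ctr <- c(n * px / 2, n * px / 2, nz * zs / 2)

  axes <- sort(runif(3, spec@axesRange[1], spec@axesRange[2]),
               decreasing = TRUE)
  if (floor(2 * axes[3] / zs) < 3)
    stop(sprintf(paste0("degenerate stack: nucleus '%s' spans fewer than ",
                        "3 z sections (axial semi-axis %.2f um, spacing ",
                        "%.2f um)"), id, axes[3], zs))
  phi <- runif(1, 0, pi)

  xs <- gridCentres(n, px)
  X <- matrix(xs, n, n) - ctr[1]
  Y <- matrix(xs, n, n, byrow = TRUE) - ctr[2]
  Xr <- cos(phi) * X + sin(phi) * Y
  Yr <- -sin(phi) * X + cos(phi) * Y
  lat2 <- (Xr / axes[1])^2 + (Yr / axes[2])^2

  sigma <- spec@territoryRadius / 2
  tpos <- matrix(NA_real_, spec@nTerritories, 3)
  tr <- vector("list", spec@nTerritories)
  for (j in seq_len(spec@nTerritories)) {
    v <- rnorm(3)
    dirW <- v / sqrt(sum(v^2))
    dirE <- c(cos(phi) * dirW[1] + sin(phi) * dirW[2],
              -sin(phi) * dirW[1] + cos(phi) * dirW[2], dirW[3])
    rayR <- rayBoundaryDistance(dirE, axes)
    f <- drawRadialFraction(spec, rayR, id)
    pos <- ctr + f * rayR * dirW
    tpos[j, ] <- pos
    pE <- c(cos(phi) * (pos[1] - ctr[1]) + sin(phi) * (pos[2] - ctr[2]),
            -sin(phi) * (pos[1] - ctr[1]) + cos(phi) * (pos[2] - ctr[2]),
            pos[3] - ctr[3])
    tr[[j]] <- data.frame(
      id = id, territory = j, x_um = pos[1], y_um = pos[2], z_um = pos[3],
      radial_fraction = f,
      edge_distance_um = interiorBoundaryDistance(pE, axes))
  }

  dapi <- array(0, c(n, n, nz))
  probe <- array(0, c(n, n, nz))
  mask <- array(FALSE, c(n, n, nz))
  zc <- gridCentres(nz, zs)
  for (k in seq_len(nz)) {
    zrel <- (zc[k] - ctr[3]) / axes[3]
    ins <- lat2 <= 1 - zrel^2
    mask[, , k] <- ins
    dapi[, , k] <- spec@backgroundLevel + spec@dapiLevel * ins
    pr <- matrix(spec@backgroundLevel, n, n)
    for (j in seq_len(spec@nTerritories)) {
      d2 <- (X + ctr[1] - tpos[j, 1])^2 + (Y + ctr[2] - tpos[j, 2])^2 +
        (zc[k] - tpos[j, 3])^2
      pr <- pr + spec@probeLevel * exp(-d2 / (2 * sigma^2)) * ins
    }
    probe[, , k] <- pr
  }

  dapi <- applyNoise(dapi, spec@photonScale, spec@gaussianSD)
  probe <- applyNoise(probe, spec@photonScale, spec@gaussianSD)

  list(stack = VolumeStack(dapi, probe, voxelSize = c(px, px, zs), id = id),
       truth = do.call(rbind, tr),
       nucleus = list(centre = ctr, axes = axes, phi = phi),
       mask = mask)
}

#' Simulate a 2D FISH image of one nucleus
#'
#' Draws an elliptical nucleus with randomized orientation and semi-axes,
#' fills it with DAPI signal, places \code{nTerritories} Gaussian probe
#' blobs at the spec's normalized radial fraction (with jitter, clipped to
#' [0, 1] and kept inside the nucleus), and applies photon-count plus
#' Gaussian read noise to both channels. The exact placement parameters
#' are returned as ground truth.
#'
#' @param spec a [SyntheticSpec].
#' @param id nucleus identifier used in the truth table and in error
#'   messages.
#' @param seed RNG seed; defaults to the spec's seed, making repeated
#'   calls with the same spec bit-identical.
#' @param dapiFalloff optional mild radial falloff of the DAPI fill
#'   (0 = uniform, the default; 0.2 dims the edge by 20 percent).
#' @return A list with elements \code{image} (a [NucleusImage]),
#'   \code{truth} (data frame: territory centroids in micron, realized
#'   radial fraction, true distance to the nuclear edge), \code{nucleus}
#'   (centre, semi-axes, orientation) and \code{mask} (the true binary
#'   nucleus mask).
#' @examples
#' sim <- simulateNucleus2D(SyntheticSpec(radialFraction = 0, seed = 1))
#' sim$truth
#' @export
simulateNucleus2D <- function(spec, id = "nucleus-1", seed = spec@seed,
                              dapiFalloff = 0) {
  validObject(spec)
  withSeed(seed, simNucleus2DCore(spec, id, dapiFalloff))
}

#' Simulate a 3D confocal stack of one nucleus
#'
#' Draws an ellipsoidal nucleus (shortest axis along z) sampled as a
#' z-stack at the spec's axial spacing, places probe blobs at the spec's
#' radial fraction along random 3D directions, and applies the noise
#' model. True centre-to-edge distances are recorded in micron and are
#' independent of voxel anisotropy.
#'
#' @inheritParams simulateNucleus2D
#' @return A list as in [simulateNucleus2D()] with element \code{stack}
#'   (a [VolumeStack]) instead of \code{image}.
#' @examples
#' spec <- SyntheticSpec(axesRange = c(2.5, 4), radialFraction = 0.2)
#' sim <- simulateStack3D(spec, seed = 2)
#' sim$truth$edge_distance_um
#' @export
simulateStack3D <- function(spec, id = "nucleus-1", seed = spec@seed) {
  validObject(spec)
  withSeed(seed, simStack3DCore(spec, id))
}

#' Condition presets for the chromosome-10 tri-state
#'
#' Radial-placement presets emulating the three fibroblast conditions in
#' which chromosome 10 shows its characteristic tri-state: intermediate in
#' young proliferating cells, peripheral after serum starvation
#' (quiescence) and interior in replicative senescence. The study reports
#' ordinal categories, not coordinates, so the numeric fractions are a
#' package calibration: each value is centred in the equal-area shell band
#' that the corresponding category occupies (see the package vignette).
#' Ki-67 status follows the biology: positive only in proliferating cells.
#'
#' @return A data frame with columns \code{condition},
#'   \code{radialFraction} and \code{ki67}.
#' @examples
#' conditionPresets()
#' @export
conditionPresets <- function() {
  data.frame(
    condition = c("proliferating", "quiescent", "senescent"),
    radialFraction = c(0.70, 0.85, 0.20),
    ki67 = c(TRUE, FALSE, FALSE))
}

#' Simulate a per-condition FISH dataset
#'
#' Generates \code{n} synthetic nuclei (2D images or 3D stacks) with the
#' radial placement preset of the requested condition, attaches Ki-67
#' status labels, and returns images, ground truth and a manifest. This is
#' the entry point used to exercise the full measurement pipeline without
#' microscope data.
#'
#' @param condition one of \code{"proliferating"}, \code{"quiescent"},
#'   \code{"senescent"}.
#' @param chromosome chromosome label carried through the manifest
#'   (presets model the chromosome-10 pattern).
#' @param n number of nuclei (default 50, the customary 2D sample size;
#'   20 nuclei is the customary minimum for the 3D assay).
#' @param seed integer seed; the whole dataset is reproducible from
#'   (arguments, seed).
#' @param mode \code{"2d"} images or \code{"3d"} stacks.
#' @param spec optional [SyntheticSpec] overriding the generator defaults;
#'   its \code{radialFraction} and \code{nNuclei} are replaced by the
#'   preset and \code{n}.
#' @return A list with \code{images} (list of [NucleusImage] or
#'   [VolumeStack]), \code{truth} (row-bound territory truth table with
#'   condition column), \code{masks} (list of true nucleus masks),
#'   \code{manifest} (id, condition, chromosome, ki67, seed) and
#'   \code{spec}.
#' @examples
#' ds <- simulateConditionDataset("senescent", n = 2, seed = 1)
#' ds$manifest
#' @export
simulateConditionDataset <- function(condition, chromosome = "10", n = 50,
                                     seed = 1,
                                     mode = c("2d", "3d"), spec = NULL) {
  mode <- match.arg(mode)
  presets <- conditionPresets()
  hit <- match(condition, presets$condition)
  if (is.na(hit))
    stop(sprintf("unknown condition '%s'; valid presets: %s", condition,
                 paste(presets$condition, collapse = ", ")))
  if (is.null(spec)) {
    spec <- if (mode == "2d") SyntheticSpec()
            else SyntheticSpec(axesRange = c(3.5, 5))
  }
  spec@radialFraction <- presets$radialFraction[hit]
  spec@nNuclei <- n
  spec@seed <- seed
  validObject(spec)
  ki67 <- presets$ki67[hit]

  emptyTruth <- data.frame(id = character(), territory = integer(),
                           x_um = numeric(), y_um = numeric(),
                           z_um = numeric(), radial_fraction = numeric(),
                           edge_distance_um = numeric(),
                           condition = character())
  if (n == 0)
    return(list(images = list(), truth = emptyTruth, masks = list(),
                manifest = data.frame(id = character(),
                                      condition = character(),
                                      chromosome = character(),
                                      ki67 = logical(), seed = integer()),
                spec = spec, mode = mode))

  ids <- sprintf("chr%s-%s-%03d", chromosome, condition, seq_len(n))
  out <- withSeed(seed, lapply(ids, function(id) {
    if (mode == "2d") simNucleus2DCore(spec, id) else simStack3DCore(spec, id)
  }))
  images <- lapply(out, function(x) {
    img <- if (mode == "2d") x$image else x$stack
    if (is(img, "NucleusImage")) img@ki67 <- ki67
    img
  })
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  truth$condition <- condition
  list(images = images, truth = truth,
       masks = lapply(out, `[[`, "mask"),
       manifest = data.frame(id = ids, condition = condition,
                             chromosome = chromosome, ki67 = ki67,
                             seed = seed),
       spec = spec, mode = mode)
}
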