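#' @import methods
#' @importFrom stats rnorm rpois runif sd t.test cor.test uniroot setNames
#' @importFrom utils read.csv write.csv
NULL

#' Parameters of the synthetic FISH image generator
#'
#' A \code{SyntheticSpec} bundles every knob of the synthetic nucleus
#' generator: geometry of the elliptical (2D) or ellipsoidal (3D) nucleus,
#' sampling of the camera grid, placement of chromosome-territory probe
#' blobs at a controlled normalized radial position, fluorescence levels
#' and the acquisition noise model. Identical spec + seed pairs always
#' produce bit-identical images.
#'
#' The normalized radial position \code{radialFraction} is defined along
#' the ray from the nucleus centre through the territory centre: 0 places
#' the territory at the nucleus centre, 1 on the nuclear edge. This makes
#' the placement parameter shape-independent for elliptical nuclei.
#'
#' @slot nNuclei number of nuclei to draw per dataset (default 50, the
#'   customary sample size of the 2D erosion assay).
#' @slot axesRange numeric(2), min and max nuclear semi-axis in micron.
#' @slot pixelSize lateral sampling in micron/pixel.
#' @slot zSpacing axial section spacing in micron (3D stacks; default 0.2,
#'   the standard confocal sectioning step for this assay).
#' @slot nTerritories territories per nucleus (default 2, diploid).
#' @slot radialFraction target normalized radial position in [0, 1].
#' @slot radialJitterSD per-territory Gaussian jitter (sd) applied to the
#'   radial fraction; jittered values are clipped to [0, 1].
#' @slot territoryRadius nominal territory radius in micron.
#' @slot dapiLevel,probeLevel,backgroundLevel fluorescence intensities
#'   (arbitrary units) of the DAPI fill, the probe blob peak and the
#'   camera background.
#' @slot photonScale photon-count (Poisson) noise scale; 0 disables.
#' @slot gaussianSD additive Gaussian read-noise sd; 0 disables.
#' @slot seed integer RNG seed.
#' @seealso [simulateNucleus2D()], [simulateStack3D()],
#'   [simulateConditionDataset()]
#' @export
setClass("SyntheticSpec", representation(
  nNuclei = "numeric", axesRange = "numeric", pixelSize = "numeric",
  zSpacing = "numeric", nTerritories = "numeric",
  radialFraction = "numeric", radialJitterSD = "numeric",
  territoryRadius = "numeric", dapiLevel = "numeric",
  probeLevel = "numeric", backgroundLevel = "numeric",
  photonScale = "numeric", gaussianSD = "numeric", seed = "numeric"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@radialFraction < 0 || object@radialFraction > 1)
    msg <- c(msg, "radialFraction must lie in [0, 1]")
  if (length(object@axesRange) != 2L || any(object@axesRange <= 0) ||
      object@axesRange[1] > object@axesRange[2])
    msg <- c(msg, "axesRange must be an increasing pair of positive semi-axes")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@zSpacing <= 0) msg <- c(msg, "zSpacing must be > 0")
  if (object@nNuclei < 0) msg <- c(msg, "nNuclei must be >= 0")
  if (object@nTerritories < 1) msg <- c(msg, "nTerritories must be >= 1")
  if (object@radialJitterSD < 0) msg <- c(msg, "radialJitterSD must be >= 0")
  if (object@territoryRadius <= 0) msg <- c(msg, "territoryRadius must be > 0")
  if (object@photonScale < 0 || object@gaussianSD < 0)
    msg <- c(msg, "noise parameters must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticSpec-class
#' @param nNuclei,axesRange,pixelSize,zSpacing,nTerritories,radialFraction
#'   see slots.
#' @param radialJitterSD,territoryRadius,dapiLevel,probeLevel see slots.
#' @param backgroundLevel,photonScale,gaussianSD,seed see slots.
#' @return A validated \code{SyntheticSpec} object.
#' @examples
#' spec <- SyntheticSpec(radialFraction = 0.85, seed = 7)
#' spec
#' @export
SyntheticSpec <- function(nNuclei = 50, axesRange = c(5, 8),
                          pixelSize = 0.1, zSpacing = 0.2,
                          nTerritories = 2, radialFraction = 0.5,
                          radialJitterSD = 0.03, territoryRadius = 0.5,
                          dapiLevel = 400, probeLevel = 800,
                          backgroundLevel = 10, photonScale = 1,
                          gaussianSD = 3, seed = 1) {
  new("SyntheticSpec", nNuclei = nNuclei, axesRange = axesRange,
      pixelSize = pixelSize, zSpacing = zSpacing,
      nTerritories = nTerritories, radialFraction = radialFraction,
      radialJitterSD = radialJitterSD, territoryRadius = territoryRadius,
      dapiLevel = dapiLevel, probeLevel = probeLevel,
      backgroundLevel = backgroundLevel, photonScale = photonScale,
      gaussianSD = gaussianSD, seed = seed)
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec\n",
      sprintf("  nuclei: %g, territories/nucleus: %g\n",
              object@nNuclei, object@nTerritories),
      sprintf("  semi-axes: %.2f-%.2f um, pixel %.3f um, z step %.2f um\n",
              object@axesRange[1], object@axesRange[2],
              object@pixelSize, object@zSpacing),
      sprintf("  radial fraction: %.2f (jitter sd %.3f), territory radius %.2f um\n",
              object@radialFraction, object@radialJitterSD,
              object@territoryRadius),
      sprintf("  levels (dapi/probe/bg): %g/%g/%g, photon scale %g, gaussian sd %g\n",
              object@dapiLevel, object@probeLevel, object@backgroundLevel,
              object@photonScale, object@gaussianSD),
      sprintf("  seed: %g\n", object@seed), sep = "")
})

#' Two-channel 2D FISH image of a single nucleus
#'
#' Holds the DAPI counterstain and the chromosome-paint probe channel of
#' one imaged nucleus, the lateral pixel size and optional pKi-67 status
#' (carried as metadata from the experiment manifest, never inferred from
#' the image itself).
#'
#' @slot dapi,probe numeric matrices of identical dimension, finite,
#'   non-negative.
#' @slot pixelSize micron per pixel.
#' @slot ki67 logical; \code{NA} when the proliferation marker was not
#'   scored.
#' @slot id character identifier.
#' @export
setClass("NucleusImage", representation(
  dapi = "matrix", probe = "matrix", pixelSize = "numeric",
  ki67 = "logical", id = "character"))

setValidity("NucleusImage", function(object) {
  msg <- character()
  if (!identical(dim(object@dapi), dim(object@probe)))
    msg <- c(msg, "dapi and probe must have identical dimensions")
  if (!all(is.finite(object@dapi)) || any(object@dapi < 0) ||
      !all(is.finite(object@probe)) || any(object@probe < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname NucleusImage-class
#' @param dapi,probe,pixelSize,ki67,id see slots.
#' @export
NucleusImage <- function(dapi, probe, pixelSize, ki67 = NA, id = "nucleus") {
  new("NucleusImage", dapi = dapi, probe = probe, pixelSize = pixelSize,
      ki67 = as.logical(ki67), id = id)
}

setMethod("show", "NucleusImage", function(object) {
  cat(sprintf("NucleusImage '%s': %d x %d px (%.3f um/px), Ki-67 %s\n",
              object@id, nrow(object@dapi), ncol(object@dapi),
              object@pixelSize,
              if (is.na(object@ki67)) "unscored"
              else if (object@ki67) "positive" else "negative"))
})

#' Two-channel 3D confocal stack of a single nucleus
#'
#' @slot dapi,probe numeric 3D arrays (x, y, z) of identical dimension.
#' @slot voxelSize numeric(3), micron per voxel along (x, y, z); the axial
#'   spacing defaults to 0.2 micron in the generator.
#' @slot id character identifier.
#' @export
setClass("VolumeStack", representation(
  dapi = "array", probe = "array", voxelSize = "numeric", id = "character"))

setValidity("VolumeStack", function(object) {
  msg <- character()
  if (length(dim(object@dapi)) != 3L ||
      !identical(dim(object@dapi), dim(object@probe)))
    msg <- c(msg, "dapi and probe must be 3D arrays of identical dimension")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive spacings (x, y, z)")
  if (!all(is.finite(object@dapi)) || any(object@dapi < 0) ||
      !all(is.finite(object@probe)) || any(object@probe < 0))
    msg <- c(msg, "intensities must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname VolumeStack-class
#' @param dapi,probe,voxelSize,id see slots.
#' @export
VolumeStack <- function(dapi, probe, voxelSize, id = "nucleus") {
  new("VolumeStack", dapi = dapi, probe = probe,
      voxelSize = voxelSize, id = id)
}

setMethod("show", "VolumeStack", function(object) {
  d <- dim(object@dapi)
  cat(sprintf("VolumeStack '%s': %d x %d x %d voxels (%.3f x %.3f x %.3f um)\n",
              object@id, d[1], d[2], d[3], object@voxelSize[1],
              object@voxelSize[2], object@voxelSize[3]))
})

#' Binary nucleus mask
#'
#' Produced by [segmentNucleus()]: a single connected, hole-filled binary
#' region with its sampling recorded in micron per pixel/voxel.
#'
#' @slot mask logical matrix (2D) or 3D array.
#' @slot spacing micron per element along each axis (length 2 or 3).
#' @export
setClass("NucleusMask", representation(mask = "array", spacing = "numeric"))

setValidity("NucleusMask", function(object) {
  msg <- character()
  nd <- length(dim(object@mask))
  if (!nd %in% c(2L, 3L)) msg <- c(msg, "mask must be 2D or 3D")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (!any(object@mask)) msg <- c(msg, "mask must contain foreground")
  if (length(object@spacing) != nd || any(object@spacing <= 0))
    msg <- c(msg, "spacing must match mask dimensionality and be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname NucleusMask-class
#' @param mask,spacing see slots.
#' @export
NucleusMask <- function(mask, spacing) {
  m <- array(as.logical(mask), dim = dim(mask))
  new("NucleusMask", mask = m, spacing = spacing)
}

setMethod("show", "NucleusMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("NucleusMask: %s px, area %d elements (%.1f um^%d)\n",
              paste(d, collapse = " x "), sum(object@mask),
              sum(object@mask) * prod(object@spacing), length(d)))
})

#' Labelled chromosome territories
#'
#' Integer label image/volume from [segmentTerritories()]: 0 is background,
#' labels 1..k are territories sorted by size (largest first). Every
#' labelled element lies inside the nucleus mask the segmentation was
#' restricted to.
#'
#' @slot labels integer matrix or 3D array.
#' @slot sizes element count per label.
#' @export
setClass("TerritoryLabels", representation(labels = "array",
                                           sizes = "numeric"))

setValidity("TerritoryLabels", function(object) {
  k <- length(object@sizes)
  if (k > 0 && max(object@labels) != k)
    return("labels must be consecutive 1..k matching 'sizes'")
  TRUE
})

#' @rdname TerritoryLabels-class
#' @param labels,sizes see slots.
#' @export
TerritoryLabels <- function(labels, sizes) {
  new("TerritoryLabels", labels = array(as.integer(labels),
                                        dim = dim(labels)),
      sizes = sizes)
}

setMethod("show", "TerritoryLabels", function(object) {
  cat(sprintf("TerritoryLabels: %d territories (sizes: %s)\n",
              length(object@sizes),
              paste(object@sizes, collapse = ", ")))
})

#' Equal-area erosion shells of a nucleus
#'
#' Partition of a 2D nucleus mask into \code{nShells} concentric shells of
#' (near-)equal area; shell 1 is the most peripheral, shell \code{nShells}
#' the nuclear interior. Produced by [equalAreaShells()].
#'
#' @slot labels integer matrix, 0 outside the mask, 1..nShells inside.
#' @slot areas pixel count per shell.
#' @slot nShells number of shells (default 5 throughout the package).
#' @export
setClass("ShellDecomposition", representation(
  labels = "array", areas = "numeric", nShells = "integer"))

setValidity("ShellDecomposition", function(object) {
  msg <- character()
  if (length(object@areas) != object@nShells)
    msg <- c(msg, "areas must have one entry per shell")
  if (any(object@areas <= 0)) msg <- c(msg, "every shell must be nonempty")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ShellDecomposition", function(object) {
  cat(sprintf("ShellDecomposition: %d shells (1 = periphery), areas: %s px\n",
              object@nShells, paste(object@areas, collapse = ", ")))
})

#' Aggregated shell profile of one condition
#'
#' Per-shell mean and standard error (SEM) of the DAPI-normalized probe
#' signal over the nuclei of one condition; the input of
#' [categorizePosition()] and of the shell histogram plot.
#'
#' @slot condition,chromosome character labels.
#' @slot nNuclei number of nuclei aggregated (>= 2).
#' @slot shellMean,shellSEM numeric vectors, one value per shell
#'   (shell 1 = periphery).
#' @export
setClass("ConditionProfile", representation(
  condition = "character", chromosome = "character", nNuclei = "integer",
  shellMean = "numeric", shellSEM = "numeric"))

setValidity("ConditionProfile", function(object) {
  msg <- character()
  if (object@nNuclei < 2L)
    msg <- c(msg, "nNuclei must be >= 2 for the SEM to be defined")
  if (length(object@shellMean) != length(object@shellSEM))
    msg <- c(msg, "shellMean and shellSEM must have equal length")
  if (any(object@shellSEM < 0)) msg <- c(msg, "SEM must be >= 0")
  if (any(!is.finite(object@shellMean)) || any(object@shellMean < 0))
    msg <- c(msg, "shell means must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ConditionProfile", function(object) {
  cat(sprintf("ConditionProfile '%s' (chromosome %s), n = %d nuclei\n",
              object@condition, object@chromosome, object@nNuclei))
  cat("  mean +/- SEM per shell (1 = periphery):\n")
  cat(sprintf("  %s\n", paste(sprintf("%.3f+/-%.3f", object@shellMean,
                                      object@shellSEM), collapse = "  ")))
})

#' Binned territory-to-edge distance distribution
#'
#' Frequency distribution of 3D territory-centre to nuclear-edge
#' distances, binned in uniform left-closed right-open increments
#' (default 0.5 micron). Trailing empty bins are trimmed.
#'
#' @slot width bin width in micron.
#' @slot counts counts per bin, bin k covering [(k-1)w, kw).
#' @slot n total number of measurements (equals \code{sum(counts)}).
#' @slot condition character label.
#' @export
setClass("DistanceDistribution", representation(
  width = "numeric", counts = "numeric", n = "integer",
  condition = "character"))

setValidity("DistanceDistribution", function(object) {
  msg <- character()
  if (object@width <= 0) msg <- c(msg, "bin width must be > 0")
  if (sum(object@counts) != object@n)
    msg <- c(msg, "counts must sum to the number of measurements")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DistanceDistribution", function(object) {
  cat(sprintf("DistanceDistribution '%s': %d measurements, %.2f um bins\n",
              object@condition, object@n, object@width))
  cat("  counts:", paste(object@counts, collapse = " "), "\n")
})
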