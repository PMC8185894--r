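#' @include AllClasses.R
NULL

# Otsu threshold on arbitrary finite values (EBImage::otsu wants a 2D
# image; reshaping a vector into a one-column matrix keeps its
# histogram-based criterion intact).
otsuThreshold <- function(v) {
  EBImage::otsu(matrix(v, ncol = 1L), range = range(v))
}

# Label connected components of a 3D binary volume (6-connectivity
# laterally within slices via EBImage, merged across adjacent slices with
# union-find).
labelVolume <- function(mask) {
  d <- dim(mask)
  nz <- d[3]
  lab <- array(0L, d)
  offset <- 0L
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nz)) {
    sl <- EBImage::bwlabel(mask[, , k] * 1)
    m <- max(sl)
    if (m > 0) {
      sl[sl > 0] <- sl[sl > 0] + offset
      parent <- c(parent, offset + seq_len(m))
      if (k > 1L) {
        prev <- lab[, , k - 1L]
        both <- prev > 0 & sl > 0
        if (any(both)) {
          pairs <- unique(cbind(prev[both], sl[both]))
          for (r in seq_len(nrow(pairs))) {
            a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
            if (a != b) parent[b] <- a
          }
        }
      }
      lab[, , k] <- sl
      offset <- offset + m
    }
  }
  if (offset == 0L) return(lab)
  root <- vapply(seq_len(offset), find, integer(1))
  relab <- match(root, unique(root))
  idx <- which(lab > 0)
  lab[idx] <- relab[lab[idx]]
  lab
}

# Keep the largest connected component; warn if several pass minSize
# (one nucleus per field: multi-nucleus fields keep the largest).
largestComponent <- function(lab, minSize, what = "nucleus") {
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0L || max(sizes) < minSize)
    stop(sprintf("no %s found: no foreground component of at least %d elements",
                 what, minSize))
  if (sum(sizes >= minSize) > 1L)
    warning(sprintf("%d candidate %s regions found; keeping the largest",
                    sum(sizes >= minSize), what))
  lab == which.max(sizes)
}

# Gaussian smoothing along z with the given sigma (in voxels), used to
# complete the anisotropy-matched 3D pre-smoothing after per-slice gblur.
smoothAlongZ <- function(v, sigmaZ) {
  if (sigmaZ <= 0) return(v)
  half <- max(1L, ceiling(2 * sigmaZ))
  w <- exp(-((-half):half)^2 / (2 * sigmaZ^2))
  w <- w / sum(w)
  d <- dim(v)
  out <- array(0, d)
  for (i in seq_along(w)) {
    sh <- i - half - 1L
    src <- pmin(pmax(seq_len(d[3]) + sh, 1L), d[3])
    out <- out + w[i] * v[, , src, drop = FALSE]
  }
  out
}

#' Segment the nucleus from the DAPI channel
#'
#' Gaussian smoothing, automatic global (Otsu) thresholding, extraction of
#' the largest connected component and hole filling. Because the
#' threshold is data-adaptive, the resulting mask is invariant to a
#' constant intensity offset. Fields containing more than one
#' above-threshold nucleus keep the largest with a warning.
#'
#' For 3D stacks the smoothing sigma is 1 voxel laterally and
#' \code{0.5 * lateral/axial} voxels axially, so the physical smoothing
#' scale is comparable in all directions; holes are filled slice-wise.
#'
#' @param x a [NucleusImage], [VolumeStack], numeric matrix (2D DAPI) or
#'   3D array.
#' @param spacing micron per pixel/voxel (length 2 or 3); taken from the
#'   object for the image classes.
#' @param minSize minimum foreground size in pixels (2D, default 500) or
#'   voxels (3D, default 5000); smaller components are rejected as noise.
#' @param sigma lateral Gaussian smoothing sigma in pixels.
#' @param ... passed to the underlying method.
#' @return A [NucleusMask].
#' @examples
#' sim <- simulateNucleus2D(SyntheticSpec(seed = 3))
#' mask <- segmentNucleus(sim$image)
#' mask
#' @export
setGeneric("segmentNucleus", function(x, ...) standardGeneric("segmentNucleus"))

#' @rdname segmentNucleus
setMethod("segmentNucleus", "NucleusImage", function(x, ...) {
  segmentNucleus(dapiChannel(x), spacing = rep(pixelSize(x), 2), ...)
})

#' @rdname segmentNucleus
setMethod("segmentNucleus", "VolumeStack", function(x, ...) {
  segmentNucleus(dapiChannel(x), spacing = voxelSize(x), ...)
})

#' @rdname segmentNucleus
setMethod("segmentNucleus", "matrix",
          function(x, spacing = c(1, 1), minSize = 500, sigma = 1) {
  if (length(x) == 0L) stop("empty image")
  if (diff(range(x)) == 0)
    stop("no nucleus found: image has no contrast")
  sm <- EBImage::gblur(x / max(x), sigma = sigma)
  th <- otsuThreshold(sm)
  lab <- EBImage::bwlabel(sm > th)
  keep <- largestComponent(lab, minSize)
  keep <- EBImage::fillHull(keep * 1) > 0
  NucleusMask(keep, spacing = spacing)
})

#' @rdname segmentNucleus
setMethod("segmentNucleus", "array",
          function(x, spacing = c(1, 1, 1), minSize = 5000, sigma = 1) {
  if (length(dim(x)) != 3L)
    stop("expected a 3D array (x, y, z)")
  if (diff(range(x)) == 0)
    stop("no nucleus found: volume has no contrast")
  v <- x / max(x)
  for (k in seq_len(dim(v)[3]))
    v[, , k] <- EBImage::gblur(v[, , k], sigma = sigma)
  v <- smoothAlongZ(v, 0.5 * spacing[1] / spacing[3])
  th <- otsuThreshold(as.numeric(v))
  lab <- labelVolume(v > th)
  keep <- largestComponent(lab, minSize)
  for (k in seq_len(dim(keep)[3]))
    keep[, , k] <- EBImage::fillHull(keep[, , k] * 1) > 0
  NucleusMask(keep, spacing = spacing)
})

#' Segment chromosome territories inside a nucleus mask
#'
#' Thresholds the probe channel within the nucleus mask only (Otsu on the
#' in-mask intensities), labels connected components, removes components
#' below the minimum territory size and sorts labels by size, largest
#' first. If no territory survives, an empty labelling is returned with a
#' warning so the nucleus can be excluded downstream.
#'
#' @param probe numeric matrix or 3D array matching the mask's dimensions.
#' @param mask a [NucleusMask].
#' @param minSize minimum territory size; defaults to 20 pixels in 2D and
#'   100 voxels in 3D.
#' @return A [TerritoryLabels].
#' @examples
#' sim <- simulateNucleus2D(SyntheticSpec(seed = 4))
#' mask <- segmentNucleus(sim$image)
#' segmentTerritories(probeChannel(sim$image), mask)
#' @export
segmentTerritories <- function(probe, mask,
                               minSize = if (length(dim(probe)) == 3L)
                                 100 else 20) {
  stopifnot(is(mask, "NucleusMask"))
  m <- maskArray(mask)
  if (!identical(dim(probe), dim(m)))
    stop("probe dimensions do not match the nucleus mask")
  is3d <- length(dim(probe)) == 3L
  inMask <- probe[m]
  empty <- function() {
    warning("no territories found inside the nucleus mask")
    TerritoryLabels(array(0L, dim(probe)), numeric(0))
  }
  if (diff(range(inMask)) == 0) return(empty())
  th <- otsuThreshold(inMask)
  fg <- (probe > th) & m
  if (!any(fg)) return(empty())
  lab <- if (is3d) labelVolume(fg) else EBImage::bwlabel(fg * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minSize)
  if (length(keep) == 0L) return(empty())
  ord <- keep[order(sizes[keep], decreasing = TRUE)]
  idx <- which(lab > 0)
  relab <- match(lab[idx], ord)
  relab[is.na(relab)] <- 0L
  out <- array(0L, dim(probe))
  out[idx] <- relab
  TerritoryLabels(out, sizes[ord])
}
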