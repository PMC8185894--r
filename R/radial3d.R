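#' @include AllClasses.R segment.R
NULL

#' Geometric centre of each territory
#'
#' Unweighted centroid of the voxel centres of each territory label,
#' scaled to micron per axis. Geometric (not intensity-weighted), matching
#' the convention of measuring from the geometric centre of a segmented
#' territory; pass \code{weights} (the probe intensities) for an
#' intensity-weighted centroid instead.
#'
#' @param labels a [TerritoryLabels] (2D or 3D).
#' @param spacing micron per pixel/voxel along each axis.
#' @param weights optional non-negative array matching \code{labels} for
#'   intensity weighting.
#' @return A data frame with one row per territory: \code{territory},
#'   centroid coordinates in micron (\code{x_um}, \code{y_um} and, for
#'   volumes, \code{z_um}) and \code{n_voxels}.
#' @export
territoryCentroid <- function(labels, spacing, weights = NULL) {
  stopifnot(is(labels, "TerritoryLabels"))
  lab <- territoryArray(labels)
  nd <- length(dim(lab))
  if (length(spacing) != nd)
    stop("spacing must have one entry per array dimension")
  k <- length(territorySizes(labels))
  if (k == 0L) stop("empty territory labelling")
  if (!is.null(weights) && !identical(dim(weights), dim(lab)))
    stop("weights must match the label dimensions")
  rows <- lapply(seq_len(k), function(j) {
    idx <- which(lab == j)
    pos <- arrayInd(idx, dim(lab))
    w <- if (is.null(weights)) rep(1, length(idx)) else weights[idx]
    ctr <- (colSums(pos * w) / sum(w) - 0.5) * spacing
    out <- data.frame(territory = j, x_um = ctr[1], y_um = ctr[2],
                      n_voxels = length(idx))
    if (nd == 3L) out$z_um <- ctr[3]
    out
  })
  out <- do.call(rbind, rows)
  if (nd == 3L) out <- out[, c("territory", "x_um", "y_um", "z_um",
                               "n_voxels")]
  out
}

# Logical array marking mask elements on the mask boundary: foreground
# with at least one face-neighbour of background (array edges count as
# background).
maskBoundary <- function(m) {
  d <- dim(m)
  nd <- length(d)
  interior <- array(TRUE, d)
  for (ax in seq_len(nd)) {
    lo <- m; hi <- m
    idx <- slice.index(m, ax)
    shiftDown <- function(x, by) {
      # neighbour along axis `ax` at offset `by`; out-of-range = FALSE
      out <- array(FALSE, d)
      src <- idx + by
      ok <- src >= 1 & src <= d[ax]
      pos <- which(ok)
      from <- pos + by * prodBefore(d, ax)
      out[pos] <- x[from]
      out
    }
    interior <- interior & shiftDown(m, -1) & shiftDown(m, 1)
  }
  m & !interior
}

prodBefore <- function(d, ax) if (ax == 1L) 1L else prod(d[seq_len(ax - 1L)])

#' Distance from a territory centre to the nearest nuclear edge
#'
#' Minimum Euclidean distance, in micron and corrected for voxel
#' anisotropy, from a point to the centre of any boundary voxel of the
#' nucleus mask. Sub-voxel surface interpolation is not attempted, so the
#' discretization error is bounded by about half a voxel diagonal.
#'
#' @param centroid point in micron (length 2 or 3, matching the mask).
#' @param mask a [NucleusMask].
#' @param spacing micron per voxel; defaults to the mask's spacing.
#' @return Distance in micron.
#' @export
edgeDistance <- function(centroid, mask, spacing = maskSpacing(mask)) {
  stopifnot(is(mask, "NucleusMask"))
  m <- maskArray(mask)
  d <- dim(m)
  if (length(centroid) != length(d))
    stop("centroid dimensionality does not match the mask")
  vox <- pmin(pmax(ceiling(centroid / spacing), 1L), d)
  if (!m[matrix(vox, 1)])
    stop("centroid lies outside the nucleus mask (territory/segmentation inconsistency)")
  b <- which(maskBoundary(m))
  pos <- arrayInd(b, d)
  ctr <- sweep(sweep(pos, 2, 0.5), 2, spacing, `*`)
  sqrt(min(colSums((t(ctr) - centroid)^2)))
}

#' Measure all territories of a 3D stack
#'
#' Full 3D assay for one nucleus: segment the nucleus and its
#' territories, take the geometric centre of each territory, and measure
#' its distance to the nearest nuclear edge.
#'
#' @param stack a [VolumeStack].
#' @param mask optional precomputed [NucleusMask].
#' @param minTerritorySize minimum territory size in voxels.
#' @param ... passed to [segmentNucleus()].
#' @return Data frame with one row per territory: \code{id},
#'   \code{territory}, centroid in micron and \code{edge_distance_um}.
#' @examples
#' spec <- SyntheticSpec(axesRange = c(2.5, 4))
#' sim <- simulateStack3D(spec, seed = 11)
#' analyzeStack3D(sim$stack)
#' @export
analyzeStack3D <- function(stack, mask = NULL, minTerritorySize = 100,
                           ...) {
  stopifnot(is(stack, "VolumeStack"))
  if (is.null(mask)) mask <- segmentNucleus(stack, ...)
  labels <- segmentTerritories(probeChannel(stack), mask,
                               minSize = minTerritorySize)
  if (length(territorySizes(labels)) == 0L)
    stop(sprintf("no territories in nucleus '%s'", imageId(stack)))
  cent <- territoryCentroid(labels, voxelSize(stack))
  cent$edge_distance_um <- vapply(seq_len(nrow(cent)), function(i) {
    edgeDistance(unlist(cent[i, c("x_um", "y_um", "z_um")]), mask)
  }, numeric(1))
  cbind(id = imageId(stack), cent)
}

#' Run the 3D assay over a set of stacks
#'
#' @param stacks list of [VolumeStack] objects.
#' @param minNuclei warn when fewer nuclei than this are measured
#'   (the customary minimum for the 3D assay is 20 nuclei).
#' @param perNucleus if \code{TRUE} also return the per-nucleus mean
#'   distance next to the default one-measurement-per-territory rows.
#' @param ... passed to [analyzeStack3D()].
#' @return Data frame of per-territory measurements; with
#'   \code{perNucleus}, a list with elements \code{perTerritory} and
#'   \code{perNucleus}.
#' @export
analyzeCondition3D <- function(stacks, minNuclei = 20, perNucleus = FALSE,
                               ...) {
  rows <- lapply(stacks, function(s) {
    tryCatch(analyzeStack3D(s, ...), error = function(e) {
      warning(sprintf("nucleus '%s' excluded: %s", imageId(s),
                      conditionMessage(e)))
      NULL
    })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no stack could be analyzed")
  rownames(out) <- NULL
  if (length(unique(out$id)) < minNuclei)
    warning(sprintf("only %d nuclei measured (fewer than the customary %d)",
                    length(unique(out$id)), minNuclei))
  if (!perNucleus) return(out)
  agg <- aggregate(edge_distance_um ~ id, out, mean)
  list(perTerritory = out, perNucleus = agg)
}

#' Bin edge distances into a frequency distribution
#'
#' Counts measurements in uniform left-closed right-open bins
#' \eqn{[0, w), [w, 2w), \ldots} (default width 0.5 micron); trailing
#' empty bins are trimmed.
#'
#' @param distances non-negative distances in micron.
#' @param width bin width in micron (default 0.5).
#' @param condition label stored in the result.
#' @return A [DistanceDistribution].
#' @examples
#' binDistances(c(0.2, 0.4, 0.6))
#' @export
binDistances <- function(distances, width = 0.5, condition = "unspecified") {
  if (length(distances) == 0L) stop("no measurements to bin")
  assertScalar(width, "width")
  if (any(!is.finite(distances)) || any(distances < 0))
    stop("distances must be finite and >= 0")
  k <- floor(distances / width) + 1L
  new("DistanceDistribution", width = width, counts = tabulate(k),
      n = length(distances), condition = condition)
}

#' @rdname binDistances
#' @param x a [DistanceDistribution].
#' @return \code{distributionTable}: a data frame with \code{bin_start},
#'   \code{bin_end}, \code{count} and \code{condition}.
#' @export
distributionTable <- function(x) {
  stopifnot(is(x, "DistanceDistribution"))
  k <- seq_along(binCounts(x))
  data.frame(bin_start = (k - 1) * binWidth(x), bin_end = k * binWidth(x),
             count = binCounts(x), condition = conditionLabel(x))
}

# Midpoint of the modal bin (ties resolved towards the nuclear edge).
peakDistance <- function(x) {
  (which.max(binCounts(x)) - 0.5) * binWidth(x)
}

#' Compare edge-distance distributions between conditions
#'
#' Bins each group's raw distance measurements (common bin width),
#' reports the modal ("peak") bin midpoint per group, and runs a Welch
#' t-test on the raw distance lists for every pair of groups.
#'
#' @param groups named list of numeric distance vectors (one per
#'   condition).
#' @param width common bin width in micron.
#' @param alpha significance level for the pairwise flags.
#' @return A list with \code{distributions} (long data frame of binned
#'   counts), \code{peaks} (named vector of peak-bin midpoints, micron)
#'   and \code{tests} (pairwise Welch results).
#' @seealso [plotDistanceDistributions()]
#' @export
compareDistributions <- function(groups, width = 0.5, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups)))
    stop("'groups' must be a named list of at least two distance vectors")
  dists <- lapply(names(groups), function(nm)
    binDistances(groups[[nm]], width = width, condition = nm))
  names(dists) <- names(groups)
  peaks <- vapply(dists, peakDistance, numeric(1))
  cmb <- combn(names(groups), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    cbind(group_a = a, group_b = b,
          welchTest(groups[[a]], groups[[b]], alpha = alpha))
  }))
  list(distributions = do.call(rbind, lapply(dists, distributionTable)),
       peaks = peaks, tests = tests)
}

#' Overlay plot of edge-distance frequency distributions
#'
#' Frequency polygons of the binned territory-centre-to-edge distances,
#' one line per condition, distance from the nuclear edge on the x axis.
#'
#' @param comparison result of [compareDistributions()].
#' @param col line colours, one per condition.
#' @param ... further arguments to [graphics::matplot()].
#' @return Invisibly, the matrix of per-bin counts.
#' @importFrom graphics matplot legend
#' @importFrom grDevices hcl.colors
#' @importFrom utils combn
#' @importFrom stats aggregate
#' @export
plotDistanceDistributions <- function(comparison, col = NULL, ...) {
  tab <- comparison$distributions
  conds <- unique(tab$condition)
  nb <- max(tab$bin_end) / tab$bin_start[2]
  width <- tab$bin_end[1]
  edges <- seq(0, max(tab$bin_end), by = width)
  mids <- edges[-1] - width / 2
  mat <- sapply(conds, function(cn) {
    counts <- numeric(length(mids))
    sub <- tab[tab$condition == cn, ]
    counts[match(sub$bin_start, edges[-length(edges)])] <- sub$count
    counts
  })
  if (is.null(col)) col <- hcl.colors(length(conds), "Dark 3")
  matplot(mids, mat, type = "b", pch = 16, lty = 1, col = col,
          xlab = "distance from nuclear edge (um)", ylab = "frequency",
          ...)
  legend("topright", legend = conds, col = col, lty = 1, pch = 16,
         bty = "n")
  invisible(mat)
}
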