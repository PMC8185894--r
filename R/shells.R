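#' @include AllClasses.R segment.R
NULL

#' Divide a nucleus mask into concentric shells of equal area
#'
#' Implements the classical erosion analysis partition: the Euclidean
#' distance from the mask boundary is computed for every in-mask pixel,
#' pixels are ranked by that distance (ties broken deterministically in
#' raster order), and the ranking is cut at cumulative-area quantiles into
#' \code{nShells} shells. Shell 1 is the most peripheral band (it contains
#' every boundary pixel), shell \code{nShells} the nuclear interior. By
#' construction the shells partition the mask exactly and their areas
#' differ by at most one pixel.
#'
#' @param mask a [NucleusMask] (2D).
#' @param nShells number of shells (default 5).
#' @return A [ShellDecomposition].
#' @examples
#' m <- matrix(FALSE, 101, 101)
#' m[(row(m) - 51)^2 + (col(m) - 51)^2 <= 45^2] <- TRUE
#' shells <- equalAreaShells(NucleusMask(m, c(0.1, 0.1)))
#' shellAreas(shells)
#' @export
equalAreaShells <- function(mask, nShells = 5) {
  stopifnot(is(mask, "NucleusMask"))
  m <- maskArray(mask)
  if (length(dim(m)) != 2L)
    stop("equal-area shells are defined for 2D masks")
  nShells <- as.integer(nShells)
  assertScalar(nShells, "nShells")
  area <- sum(m)
  if (area < 5L * nShells)
    stop(sprintf("mask too small: %d px cannot form %d shells", area,
                 nShells))
  d <- EBImage::distmap(m * 1)
  idx <- which(m)
  o <- order(d[idx], idx)
  shellOfRank <- as.integer(ceiling(seq_len(area) * nShells / area))
  labels <- array(0L, dim(m))
  labels[idx[o]] <- shellOfRank
  ShellDecomposition(labels = labels,
                     areas = tabulate(shellOfRank, nbins = nShells),
                     nShells = nShells)
}

ShellDecomposition <- function(labels, areas, nShells) {
  new("ShellDecomposition", labels = labels, areas = areas,
      nShells = nShells)
}

#' Percentage of channel signal per shell
#'
#' Sums the intensity of one channel over each shell and expresses it as a
#' percentage of the total in-mask signal; the vector sums to 100.
#'
#' @param channel numeric matrix matching the shell label dimensions.
#' @param shells a [ShellDecomposition].
#' @return Numeric vector of length \code{nShells(shells)}, in percent.
#' @export
shellFractions <- function(channel, shells) {
  stopifnot(is(shells, "ShellDecomposition"))
  lab <- shellLabels(shells)
  if (!identical(dim(channel), dim(lab)))
    stop("channel dimensions do not match the shell decomposition")
  idx <- which(lab > 0)
  s <- vapply(seq_len(nShells(shells)),
              function(k) sum(channel[idx][lab[idx] == k]), numeric(1))
  tot <- sum(s)
  if (tot <= 0)
    stop("zero total in-mask signal; nucleus must be excluded")
  100 * s / tot
}

#' DAPI-normalized shell profile
#'
#' Divides the per-shell probe percentage by the per-shell DAPI
#' percentage. A value of 1 in a shell means the chromosome is distributed
#' there like bulk DNA; values above 1 indicate enrichment.
#'
#' @param probePercent,dapiPercent percentage vectors summing to 100.
#' @return Dimensionless numeric vector of per-shell ratios.
#' @export
normalizedProfile <- function(probePercent, dapiPercent) {
  if (length(probePercent) != length(dapiPercent))
    stop("probe and DAPI percentage vectors must have equal length")
  if (abs(sum(probePercent) - 100) > 1e-6 ||
      abs(sum(dapiPercent) - 100) > 1e-6)
    stop("percentage vectors must each sum to 100")
  if (any(dapiPercent <= 0))
    stop("degenerate shell with zero DAPI signal; nucleus must be excluded")
  probePercent / dapiPercent
}

#' Per-nucleus shell profile
#'
#' Runs the 2D shell quantification for one nucleus: percentage of probe
#' and of DAPI signal per shell and their ratio.
#'
#' @param image a [NucleusImage].
#' @param mask optional [NucleusMask]; segmented from the DAPI channel
#'   when missing.
#' @param shells optional [ShellDecomposition]; computed from the mask
#'   when missing.
#' @param nShells number of shells when computing the decomposition.
#' @return A data frame with one row per shell: \code{id}, \code{shell},
#'   \code{probe_pct}, \code{dapi_pct}, \code{normalized}.
#' @examples
#' sim <- simulateNucleus2D(SyntheticSpec(seed = 5))
#' shellProfile(sim$image)
#' @export
shellProfile <- function(image, mask = NULL, shells = NULL, nShells = 5) {
  stopifnot(is(image, "NucleusImage"))
  if (is.null(mask)) mask <- segmentNucleus(image)
  if (is.null(shells)) shells <- equalAreaShells(mask, nShells)
  probePct <- shellFractions(probeChannel(image), shells)
  dapiPct <- shellFractions(dapiChannel(image), shells)
  data.frame(id = imageId(image), shell = seq_len(nShells(shells)),
             probe_pct = probePct, dapi_pct = dapiPct,
             normalized = normalizedProfile(probePct, dapiPct))
}

#' Aggregate per-nucleus profiles into a condition profile
#'
#' Per-shell mean and standard error of the mean (sample SD / sqrt(n)) of
#' the normalized values over all nuclei of a condition. At least two
#' nuclei are required for the SEM to be defined; fewer than
#' \code{minNuclei} nuclei trigger a warning (the customary sample size of
#' this assay is 50 nuclei per chromosome and condition).
#'
#' @param profiles either a data frame as returned by [shellProfile()]
#'   (rows from several nuclei bound together) or a numeric matrix of
#'   normalized values with one row per nucleus.
#' @param condition,chromosome labels stored in the result.
#' @param minNuclei sample size below which a warning is emitted.
#' @return A [ConditionProfile].
#' @export
aggregateProfiles <- function(profiles, condition = "unspecified",
                              chromosome = "NA", minNuclei = 50) {
  mat <- profileMatrix(profiles)
  n <- nrow(mat)
  if (n < 2L) stop("at least 2 nuclei are required to aggregate")
  if (n < minNuclei)
    warning(sprintf("only %d nuclei (fewer than the customary %d)", n,
                    minNuclei))
  new("ConditionProfile", condition = condition, chromosome = chromosome,
      nNuclei = as.integer(n), shellMean = colMeans(mat),
      shellSEM = apply(mat, 2, sd) / sqrt(n))
}

# Normalized values as an n-nuclei x n-shells matrix from either input
# form.
profileMatrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  stopifnot(is.data.frame(profiles),
            all(c("id", "shell", "normalized") %in% names(profiles)))
  ids <- unique(profiles$id)
  ns <- max(profiles$shell)
  mat <- matrix(NA_real_, length(ids), ns,
                dimnames = list(ids, paste0("shell", seq_len(ns))))
  for (i in seq_along(ids)) {
    p <- profiles[profiles$id == ids[i], ]
    mat[i, p$shell] <- p$normalized
  }
  if (anyNA(mat)) stop("incomplete shell profiles")
  mat
}

#' Categorize a radial position profile
#'
#' Quantifies the verbal categorization rule of the erosion assay: a
#' profile skewed towards shells 1 and 2 is \emph{peripheral}, a skew
#' towards shells 4 and 5 is \emph{interior}, and a profile peaking in
#' shell 3 (or distributed flat, like bulk DNA) is \emph{intermediate}.
#' The skew is measured as \code{P - I}, where P is the mean normalized
#' signal of the two outermost shells and I the mean of the two innermost;
#' values beyond \code{delta} in either direction leave the intermediate
#' band.
#'
#' @param profile a [ConditionProfile] or a numeric vector of per-shell
#'   normalized values (shell 1 first).
#' @param delta dimensionless decision threshold (default 0.1).
#' @return An ordered factor with levels
#'   \code{interior < intermediate < peripheral}.
#' @examples
#' categorizePosition(c(1.6, 1.3, 0.9, 0.6, 0.4))
#' categorizePosition(c(1, 1, 1, 1, 1))
#' @export
categorizePosition <- function(profile, delta = 0.1) {
  v <- if (is(profile, "ConditionProfile")) profileMean(profile)
       else as.numeric(profile)
  ns <- length(v)
  if (ns < 5L) stop("a profile with at least 5 shells is required")
  P <- mean(v[1:2])
  I <- mean(v[(ns - 1):ns])
  lev <- c("interior", "intermediate", "peripheral")
  cat <- if (P - I > delta) "peripheral"
         else if (I - P > delta) "interior"
         else "intermediate"
  factor(cat, levels = lev, ordered = TRUE)
}

#' Run the full 2D erosion assay over a set of images
#'
#' Segments each nucleus, builds the equal-area shells, quantifies the
#' DAPI-normalized probe profile, and collects per-nucleus rows. Nuclei
#' that fail (no nucleus found, no in-mask signal, degenerate shell) are
#' skipped with a warning naming them.
#'
#' @param images list of [NucleusImage] objects (e.g. the \code{images}
#'   element of [simulateConditionDataset()]).
#' @param nShells number of shells.
#' @param ... passed to [segmentNucleus()].
#' @return Data frame of per-nucleus shell profiles (see
#'   [shellProfile()]).
#' @export
analyzeCondition2D <- function(images, nShells = 5, ...) {
  rows <- lapply(images, function(img) {
    tryCatch(shellProfile(img, mask = segmentNucleus(img, ...),
                          nShells = nShells),
             error = function(e) {
               warning(sprintf("nucleus '%s' excluded: %s", imageId(img),
                               conditionMessage(e)))
               NULL
             })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no nucleus could be analyzed")
  rownames(out) <- NULL
  out
}

#' Shell histogram of a condition profile
#'
#' Bar plot of the mean DAPI-normalized signal per shell with SEM error
#' bars: the standard graphical readout of the erosion assay (shells 1-2
#' are the nuclear periphery, 4-5 the interior).
#'
#' @param profile a [ConditionProfile].
#' @param col bar colour.
#' @param ylim y limits; computed from mean + SEM when missing.
#' @param ... further arguments to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @importFrom graphics arrows barplot abline
#' @export
plotShellProfile <- function(profile, col = "grey70", ylim = NULL, ...) {
  stopifnot(is(profile, "ConditionProfile"))
  m <- profileMean(profile)
  s <- profileSEM(profile)
  if (is.null(ylim)) ylim <- c(0, max(m + s) * 1.1)
  bp <- barplot(m, names.arg = seq_along(m), col = col, ylim = ylim,
                xlab = "shell (1 = periphery)",
                ylab = "normalized signal (% probe / % DAPI)",
                main = sprintf("%s (chr %s, n = %d)",
                               conditionLabel(profile),
                               profile@chromosome, nNuclei(profile)), ...)
  nz <- s > 0
  if (any(nz))
    arrows(bp[nz], (m - s)[nz], bp[nz], (m + s)[nz], angle = 90,
           code = 3, length = 0.05)
  abline(h = 1, lty = 2, col = "grey40")
  invisible(bp)
}
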