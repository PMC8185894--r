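#' @include AllClasses.R
NULL

# TIFF pages are stored as 32-bit float in [0, 1]; raw intensities are
# divided by this fixed scale on write and multiplied back on read.
.TIFF_SCALE <- 65536

#' Write a nucleus image or stack as multi-page TIFF
#'
#' 2D images are written as one page per channel in the order (DAPI,
#' probe); 3D stacks as z-major pages with channels interleaved within
#' each section (z1-DAPI, z1-probe, z2-DAPI, ...). Intensities are stored
#' as 32-bit float scaled by a fixed constant, so arbitrary-unit values
#' round-trip to single precision.
#'
#' @param x a [NucleusImage] or [VolumeStack].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeFISHImage <- function(x, path) {
  pages <- if (is(x, "NucleusImage")) {
    list(dapiChannel(x), probeChannel(x))
  } else if (is(x, "VolumeStack")) {
    d <- dapiChannel(x); p <- probeChannel(x)
    unlist(lapply(seq_len(dim(d)[3]), function(k)
      list(d[, , k], p[, , k])), recursive = FALSE)
  } else stop("'x' must be a NucleusImage or VolumeStack")
  mx <- max(vapply(pages, max, numeric(1)))
  if (mx >= .TIFF_SCALE)
    stop(sprintf("intensities above the storage scale (%g)", .TIFF_SCALE))
  tiff::writeTIFF(lapply(pages, function(pg) pg / .TIFF_SCALE), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-page FISH TIFF
#'
#' Reads a two-channel TIFF written by [writeFISHImage()] (or any TIFF
#' with the same page layout). With \code{zSpacing = NULL} the file is a
#' 2D field whose pages are channels; with a numeric \code{zSpacing} the
#' pages are z sections with channels interleaved and a [VolumeStack] is
#' returned with the z extent implied by the page count.
#'
#' @param path TIFF file.
#' @param channelMap named integer vector mapping channel names
#'   (\code{dapi}, \code{probe}) to channel indices.
#' @param pixelSize lateral micron/pixel recorded on the result.
#' @param zSpacing axial micron spacing for stacks; \code{NULL} for 2D.
#' @param ki67 optional Ki-67 status carried from the dataset manifest.
#' @param id identifier.
#' @param scale intensity scale applied on read (the write-side scale by
#'   default).
#' @return A [NucleusImage] or [VolumeStack].
#' @export
readFISHImage <- function(path, channelMap = c(dapi = 1, probe = 2),
                          pixelSize = 0.1, zSpacing = NULL, ki67 = NA,
                          id = sub("\\.tiff?$", "", basename(path)),
                          scale = .TIFF_SCALE) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  if (!all(c("dapi", "probe") %in% names(channelMap)))
    stop("channelMap must name the 'dapi' and 'probe' channels")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop(sprintf("unreadable TIFF '%s': %s", path,
                                   conditionMessage(e))))
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop(sprintf("pages of '%s' have non-matching dimensions", path))
  nPages <- length(pages)
  nCh <- if (is.null(zSpacing)) nPages else length(channelMap)
  if (any(channelMap > nCh) || any(channelMap < 1))
    stop(sprintf("channel map requests channel %d but only channels %s are available",
                 max(channelMap), paste(seq_len(nCh), collapse = ", ")))
  if (is.null(zSpacing)) {
    NucleusImage(dapi = pages[[channelMap["dapi"]]] * scale,
                 probe = pages[[channelMap["probe"]]] * scale,
                 pixelSize = pixelSize, ki67 = ki67, id = id)
  } else {
    if (nPages %% nCh != 0L)
      stop(sprintf("page count %d is not a multiple of %d channels",
                   nPages, nCh))
    nz <- nPages %/% nCh
    pick <- function(ch) {
      arr <- array(0, c(dims[[1]], nz))
      for (k in seq_len(nz))
        arr[, , k] <- pages[[(k - 1L) * nCh + ch]] * scale
      arr
    }
    VolumeStack(dapi = pick(channelMap["dapi"]),
                probe = pick(channelMap["probe"]),
                voxelSize = c(pixelSize, pixelSize, zSpacing), id = id)
  }
}

#' Write a simulated dataset to disk
#'
#' Exports a [simulateConditionDataset()] result as one multi-page TIFF
#' per nucleus plus a manifest CSV (id, file, condition, chromosome,
#' Ki-67 status, seed, sampling) and a ground-truth CSV.
#'
#' @param dataset result of [simulateConditionDataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data frame with its \code{file}
#'   column.
#' @export
writeConditionDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- dataset$manifest
  man$file <- paste0(man$id, ".tif")
  man$mode <- dataset$mode
  man$pixel_size_um <- dataset$spec@pixelSize
  man$z_spacing_um <- if (dataset$mode == "3d") dataset$spec@zSpacing
                      else NA_real_
  for (i in seq_along(dataset$images))
    writeFISHImage(dataset$images[[i]], file.path(dir, man$file[i]))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(dataset$truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(man)
}

#' Read a dataset directory written by [writeConditionDataset()]
#'
#' @param dir dataset directory containing \code{manifest.csv}.
#' @return A list with \code{images} (list of [NucleusImage] /
#'   [VolumeStack] with Ki-67 status from the manifest) and
#'   \code{manifest}.
#' @export
readConditionDataset <- function(dir) {
  manPath <- file.path(dir, "manifest.csv")
  if (!file.exists(manPath))
    stop(sprintf("no manifest.csv in '%s'", dir))
  man <- read.csv(manPath, stringsAsFactors = FALSE)
  images <- lapply(seq_len(nrow(man)), function(i) {
    readFISHImage(file.path(dir, man$file[i]),
                  pixelSize = man$pixel_size_um[i],
                  zSpacing = if (identical(man$mode[i], "3d"))
                    man$z_spacing_um[i] else NULL,
                  ki67 = man$ki67[i], id = man$id[i])
  })
  list(images = images, manifest = man)
}
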