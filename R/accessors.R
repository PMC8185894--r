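# Accessor generics: user code should use these rather than reaching into
# slots with `@`.

#' Accessors for radialFISH classes
#'
#' Small accessor generics for the image, mask, shell and profile classes.
#' \code{dapiChannel}/\code{probeChannel} return the intensity arrays,
#' \code{maskArray} the logical mask, \code{shellLabels}/\code{shellAreas}
#' the shell partition, \code{profileMean}/\code{profileSEM} the aggregated
#' per-shell values, \code{binCounts}/\code{binWidth} the binned distance
#' distribution.
#'
#' @param x an object of the documented class.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dapiChannel", function(x) standardGeneric("dapiChannel"))
#' @rdname accessors
#' @export
setGeneric("probeChannel", function(x) standardGeneric("probeChannel"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("maskSpacing", function(x) standardGeneric("maskSpacing"))
#' @rdname accessors
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))
#' @rdname accessors
#' @export
setGeneric("territoryArray", function(x) standardGeneric("territoryArray"))
#' @rdname accessors
#' @export
setGeneric("territorySizes", function(x) standardGeneric("territorySizes"))
#' @rdname accessors
#' @export
setGeneric("shellLabels", function(x) standardGeneric("shellLabels"))
#' @rdname accessors
#' @export
setGeneric("shellAreas", function(x) standardGeneric("shellAreas"))
#' @rdname accessors
#' @export
setGeneric("nShells", function(x) standardGeneric("nShells"))
#' @rdname accessors
#' @export
setGeneric("profileMean", function(x) standardGeneric("profileMean"))
#' @rdname accessors
#' @export
setGeneric("profileSEM", function(x) standardGeneric("profileSEM"))
#' @rdname accessors
#' @export
setGeneric("nNuclei", function(x) standardGeneric("nNuclei"))
#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname accessors
setMethod("dapiChannel", "NucleusImage", function(x) x@dapi)
#' @rdname accessors
setMethod("dapiChannel", "VolumeStack", function(x) x@dapi)
#' @rdname accessors
setMethod("probeChannel", "NucleusImage", function(x) x@probe)
#' @rdname accessors
setMethod("probeChannel", "VolumeStack", function(x) x@probe)
#' @rdname accessors
setMethod("pixelSize", "NucleusImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("voxelSize", "VolumeStack", function(x) x@voxelSize)
#' @rdname accessors
setMethod("imageId", "NucleusImage", function(x) x@id)
#' @rdname accessors
setMethod("imageId", "VolumeStack", function(x) x@id)

#' @rdname accessors
setMethod("maskArray", "NucleusMask", function(x) x@mask)
#' @rdname accessors
setMethod("maskSpacing", "NucleusMask", function(x) x@spacing)
#' @rdname accessors
setMethod("maskArea", "NucleusMask", function(x) sum(x@mask))

#' @rdname accessors
setMethod("territoryArray", "TerritoryLabels", function(x) x@labels)
#' @rdname accessors
setMethod("territorySizes", "TerritoryLabels", function(x) x@sizes)

#' @rdname accessors
setMethod("shellLabels", "ShellDecomposition", function(x) x@labels)
#' @rdname accessors
setMethod("shellAreas", "ShellDecomposition", function(x) x@areas)
#' @rdname accessors
setMethod("nShells", "ShellDecomposition", function(x) x@nShells)

#' @rdname accessors
setMethod("profileMean", "ConditionProfile", function(x) x@shellMean)
#' @rdname accessors
setMethod("profileSEM", "ConditionProfile", function(x) x@shellSEM)
#' @rdname accessors
setMethod("nNuclei", "ConditionProfile", function(x) x@nNuclei)
#' @rdname accessors
setMethod("conditionLabel", "ConditionProfile", function(x) x@condition)

#' @rdname accessors
setMethod("binCounts", "DistanceDistribution", function(x) x@counts)
#' @rdname accessors
setMethod("binWidth", "DistanceDistribution", function(x) x@width)
#' @rdname accessors
setMethod("conditionLabel", "DistanceDistribution", function(x) x@condition)
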