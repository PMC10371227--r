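# Accessor generics: slots are never reached into from user code.

#' @rdname AnnotatedFrame-class
#' @param x an object.
#' @export
setGeneric("masks", function(x) standardGeneric("masks"))
#' @rdname AnnotatedFrame-class
#' @export
setMethod("masks", "AnnotatedFrame", function(x) x@masks)

#' @rdname AnnotatedFrame-class
#' @export
setGeneric("trackLabels", function(x) standardGeneric("trackLabels"))
#' @rdname AnnotatedFrame-class
#' @export
setMethod("trackLabels", "AnnotatedFrame", function(x) x@labels)

#' @rdname AnnotatedFrame-class
#' @export
setGeneric("motherPairs", function(x) standardGeneric("motherPairs"))
#' @rdname AnnotatedFrame-class
#' @export
setMethod("motherPairs", "AnnotatedFrame", function(x) x@motherPairs)

#' @rdname AnnotatedFrame-class
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))
#' @rdname AnnotatedFrame-class
#' @export
setMethod("frameDim", "AnnotatedFrame", function(x) x@dim)

#' @rdname SemanticTargets-class
#' @param x an object.
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname SemanticTargets-class
#' @export
setMethod("channels", "SemanticTargets", function(x) x@channels)

#' Extract one named channel of a semantic stack
#' @param x a [SemanticTargets-class].
#' @param name one of [semanticChannelNames()].
#' @return Numeric H x W matrix.
#' @export
semanticChannel <- function(x, name) {
  stopifnot(name %in% semanticChannelNames())
  x@channels[, , name]
}

#' @rdname SemanticTargets-class
#' @export
setGeneric("isBinary", function(x) standardGeneric("isBinary"))
#' @rdname SemanticTargets-class
#' @export
setMethod("isBinary", "SemanticTargets", function(x) x@binary)

#' @rdname SimulatedMovie-class
#' @param x an object.
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname SimulatedMovie-class
#' @export
setMethod("frames", "SimulatedMovie", function(x) x@frames)

#' @rdname SimulatedMovie-class
#' @export
setGeneric("images", function(x) standardGeneric("images"))
#' @rdname SimulatedMovie-class
#' @export
setMethod("images", "SimulatedMovie", function(x) x@images)

#' @rdname SimulatedMovie-class
#' @export
setGeneric("trueVolumes", function(x) standardGeneric("trueVolumes"))
#' @rdname SimulatedMovie-class
#' @export
setMethod("trueVolumes", "SimulatedMovie", function(x) x@trueVolumes)

#' @rdname SimulatedMovie-class
#' @export
setGeneric("trueCytokinesis", function(x) standardGeneric("trueCytokinesis"))
#' @rdname SimulatedMovie-class
#' @export
setMethod("trueCytokinesis", "SimulatedMovie", function(x) x@trueCytokinesis)

#' @rdname SimulatedMovie-class
#' @export
setGeneric("lineage", function(x) standardGeneric("lineage"))
#' @rdname SimulatedMovie-class
#' @export
setMethod("lineage", "SimulatedMovie", function(x) x@lineage)

#' @rdname SimulatedMovie-class
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))
#' @rdname SimulatedMovie-class
#' @export
setMethod("simParams", "SimulatedMovie", function(x) x@params)

#' @rdname SegmentedInstance-class
#' @param x an object.
#' @export
setGeneric("instanceMask", function(x) standardGeneric("instanceMask"))
#' @rdname SegmentedInstance-class
#' @export
setMethod("instanceMask", "SegmentedInstance", function(x) x@mask)

#' @rdname SegmentedInstance-class
#' @export
setGeneric("sizeCategory", function(x) standardGeneric("sizeCategory"))
#' @rdname SegmentedInstance-class
#' @export
setMethod("sizeCategory", "SegmentedInstance", function(x) x@category)

#' @rdname SegmentedInstance-class
#' @export
setGeneric("instanceScore", function(x) standardGeneric("instanceScore"))
#' @rdname SegmentedInstance-class
#' @export
setMethod("instanceScore", "SegmentedInstance", function(x) x@score)

#' @rdname SegmentedInstance-class
#' @export
setGeneric("instanceSpline", function(x) standardGeneric("instanceSpline"))
#' @rdname SegmentedInstance-class
#' @export
setMethod("instanceSpline", "SegmentedInstance", function(x) x@spline)

#' @rdname LineageLedger-class
#' @param x an object.
#' @export
setGeneric("ledgerTable", function(x) standardGeneric("ledgerTable"))
#' @rdname LineageLedger-class
#' @export
setMethod("ledgerTable", "LineageLedger", function(x) x@table)

#' @rdname GrowthEstimate-class
#' @param x an object.
#' @export
setGeneric("growthRate", function(x) standardGeneric("growthRate"))
#' @rdname GrowthEstimate-class
#' @export
setMethod("growthRate", "GrowthEstimate", function(x)
  data.frame(time = x@times, rate = x@rateMean, rate_sd = x@rateSD))

#' @rdname GrowthEstimate-class
#' @export
setGeneric("smoothedVolume", function(x) standardGeneric("smoothedVolume"))
#' @rdname GrowthEstimate-class
#' @export
setMethod("smoothedVolume", "GrowthEstimate", function(x)
  data.frame(time = x@times, volume = x@volMean, volume_sd = x@volSD))
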