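#' Accessor generics
#'
#' Small accessor generics shared by the container classes: movie frame
#' stacks, acquisition metadata, tissue masks, frequency axes, heterogeneity
#' fields and alternans-map slots.
#'
#' @param x An object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("tissueMask", function(x) standardGeneric("tissueMask"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("freqAxis", function(x) standardGeneric("freqAxis"))

#' @rdname accessors
#' @export
setGeneric("hetField", function(x) standardGeneric("hetField"))

#' @rdname accessors
#' @export
setGeneric("hetDelta", function(x) standardGeneric("hetDelta"))

#' @rdname accessors
#' @export
setGeneric("apd", function(x) standardGeneric("apd"))

#' @rdname accessors
#' @export
setGeneric("upstrokeTimes", function(x) standardGeneric("upstrokeTimes"))

#' @rdname accessors
#' @export
setGeneric("diastolicIntervals", function(x) standardGeneric("diastolicIntervals"))

#' @rdname accessors
#' @export
setGeneric("deltaAPD", function(x) standardGeneric("deltaAPD"))

#' @rdname accessors
#' @export
setGeneric("nodalMask", function(x) standardGeneric("nodalMask"))

#' @rdname accessors
#' @export
setGeneric("patternLabel", function(x) standardGeneric("patternLabel"))

#' @rdname accessors
#' @export
setGeneric("phaseField", function(x) standardGeneric("phaseField"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("uStack", function(x) standardGeneric("uStack"))

#' @rdname accessors
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))
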