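#' @rdname PathwayRef-class
#' @param x a PathwayRef or PathwayDataset object.
#' @export
setGeneric("nPathways", function(x) standardGeneric("nPathways"))

#' @rdname PathwayRef-class
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname PathwayRef-class
#' @export
setGeneric("pathwayIds", function(x) standardGeneric("pathwayIds"))

#' @rdname PathwayRef-class
#' @export
setGeneric("reactionIds", function(x) standardGeneric("reactionIds"))

#' @rdname PathwayRef-class
#' @param id a single pathway id.
#' @export
setGeneric("pathwayReactions", function(x, id) standardGeneric("pathwayReactions"))

#' @rdname PathwayRef-class
#' @export
setGeneric("keyReactions", function(x, id) standardGeneric("keyReactions"))

#' @rdname PathwayRef-class
#' @param ec a single normalized EC string.
#' @export
setGeneric("reactionPathways", function(x, ec) standardGeneric("reactionPathways"))

#' @rdname PathwayDataset-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname PathwayDataset-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname PathwayDataset-class
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname PathwayDataset-class
#' @export
setGeneric("hasLabels", function(x) standardGeneric("hasLabels"))

#' @rdname PathwayDataset-class
#' @export
setGeneric("sampleAbundances", function(x, id) standardGeneric("sampleAbundances"))
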