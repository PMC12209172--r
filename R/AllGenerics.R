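#' Accessors for nucleoFRET S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object a nucleoFRET S4 object.
#' @return The slot value documented for each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("crosstalkAlpha", function(object) standardGeneric("crosstalkAlpha"))
#' @rdname accessors
#' @export
setGeneric("crosstalkBeta", function(object) standardGeneric("crosstalkBeta"))
#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))
#' @rdname accessors
#' @export
setGeneric("binFrequencies", function(object) standardGeneric("binFrequencies"))
#' @rdname accessors
#' @export
setGeneric("binSEM", function(object) standardGeneric("binSEM"))
#' @rdname accessors
#' @export
setGeneric("nParticles", function(object) standardGeneric("nParticles"))
#' @rdname accessors
#' @export
setGeneric("components", function(object) standardGeneric("components"))
#' @rdname accessors
#' @export
setGeneric("bicTable", function(object) standardGeneric("bicTable"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("kd", function(object) standardGeneric("kd"))
#' @rdname accessors
#' @export
setGeneric("kdSE", function(object) standardGeneric("kdSE"))
#' @rdname accessors
#' @export
setGeneric("c50", function(object) standardGeneric("c50"))
#' @rdname accessors
#' @export
setGeneric("c50CI", function(object) standardGeneric("c50CI"))
#' @rdname accessors
#' @export
setGeneric("bandLabel", function(object) standardGeneric("bandLabel"))
#' @rdname accessors
#' @export
setGeneric("intensitySamples", function(object) standardGeneric("intensitySamples"))

#' @rdname accessors
#' @export
setMethod("crosstalkAlpha", "CrosstalkModel", function(object) object@alpha)
#' @rdname accessors
#' @export
setMethod("crosstalkBeta", "CrosstalkModel", function(object) object@beta)
#' @rdname accessors
#' @export
setMethod("binCenters", "EprProfile", function(object) object@binCenters)
#' @rdname accessors
#' @export
setMethod("binFrequencies", "EprProfile", function(object) object@frequencies)
#' @rdname accessors
#' @export
setMethod("binSEM", "EprProfile", function(object) object@sem)
#' @rdname accessors
#' @export
setMethod("nParticles", "EprProfile", function(object) object@nParticles)
#' @rdname accessors
#' @export
setMethod("components", "MixtureFit", function(object) object@components)
#' @rdname accessors
#' @export
setMethod("bicTable", "MixtureFit", function(object) object@bicTable)
#' @rdname accessors
#' @export
setMethod("isConverged", "MixtureFit", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("isConverged", "OneSiteFit", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("isConverged", "HalfSaturationFit", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("kd", "OneSiteFit", function(object) object@kd)
#' @rdname accessors
#' @export
setMethod("kdSE", "OneSiteFit", function(object) object@seKd)
#' @rdname accessors
#' @export
setMethod("c50", "HalfSaturationFit", function(object) object@c50)
#' @rdname accessors
#' @export
setMethod("c50CI", "HalfSaturationFit", function(object) object@ci)
#' @rdname accessors
#' @export
setMethod("bandLabel", "IntensityProfile", function(object) object@bandLabel)
#' @rdname accessors
#' @export
setMethod("intensitySamples", "IntensityProfile", function(object) object@samples)
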