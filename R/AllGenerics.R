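#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname wavelengths
#' @export
setGeneric("reflectance", function(x) standardGeneric("reflectance"))

#' @rdname wavelengths
#' @export
setGeneric("speciesLabels", function(x) standardGeneric("speciesLabels"))

#' @rdname wavelengths
#' @export
setGeneric("phylumLabels", function(x) standardGeneric("phylumLabels"))

#' @rdname wavelengths
#' @export
setGeneric("drynessStates", function(x) standardGeneric("drynessStates"))

#' @rdname wavelengths
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname trimWavelengths
#' @export
setGeneric("trimWavelengths",
           function(x, lo = 400, hi = 900) standardGeneric("trimWavelengths"))

#' @rdname averageReplicates
#' @export
setGeneric("averageReplicates",
           function(x, groupBy = c("species", "dryness"))
             standardGeneric("averageReplicates"))

#' @rdname resampleToGrid
#' @export
setGeneric("resampleToGrid",
           function(x, step = 1) standardGeneric("resampleToGrid"))

#' @rdname firstDerivative
#' @export
setGeneric("firstDerivative", function(x, ...) standardGeneric("firstDerivative"))
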