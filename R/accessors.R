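#' Accessors for SpectraSet
#'
#' `wavelengths()` returns the shared wavelength grid (nm); `reflectance()`
#' the wavelengths-by-samples percent reflectance matrix; `speciesLabels()`,
#' `phylumLabels()` and `drynessStates()` the per-sample labels;
#' `sampleIds()` the unique sample identifiers.
#'
#' @param x a [SpectraSet-class] (or [DerivativeSet-class] for `wavelengths`).
#' @return vectors/matrix as described.
#' @name wavelengths
#' @aliases reflectance speciesLabels phylumLabels drynessStates sampleIds
NULL

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "SpectraSet",
          function(x) rowData(x)$wavelength_nm)

#' @rdname wavelengths
#' @export
setMethod("wavelengths", "DerivativeSet", function(x) x@wavelengths)

#' @rdname wavelengths
#' @export
setMethod("reflectance", "SpectraSet",
          function(x) assay(x, "reflectance"))

#' @rdname wavelengths
#' @export
setMethod("speciesLabels", "SpectraSet",
          function(x) as.character(colData(x)$species))

#' @rdname wavelengths
#' @export
setMethod("phylumLabels", "SpectraSet",
          function(x) as.character(colData(x)$phylum))

#' @rdname wavelengths
#' @export
setMethod("drynessStates", "SpectraSet",
          function(x) as.character(colData(x)$dryness))

#' @rdname wavelengths
#' @export
setMethod("sampleIds", "SpectraSet", function(x) colnames(x))

#' Derivative values
#'
#' @param x a [DerivativeSet-class].
#' @return the wavelengths-by-samples matrix of forward-difference values
#'   (%/nm).
#' @export
derivativeValues <- function(x) {
  stopifnot(is(x, "DerivativeSet"))
  x@values
}
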