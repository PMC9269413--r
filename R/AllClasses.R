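#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Container for labelled reflectance spectra
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] for
#' libraries of field reflectance spectra. The single assay, `"reflectance"`,
#' is a wavelengths-by-samples matrix of percent reflectance (0--100 scale).
#' Row metadata carries the wavelength grid in nm (`wavelength_nm`, strictly
#' increasing); column metadata carries the sample labels: `species` (one of
#' the six intertidal seaweed species), `phylum` (derived from species) and
#' `dryness` (`wet`, `moderate` or `dry` -- the state of an intertidal thallus
#' between tides).
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [SpectraSet()] for construction, [readSpectra()] for file input.
#' @export
setClass("SpectraSet", contains = "SummarizedExperiment")

#' First-derivative spectra
#'
#' Holds forward-difference derivative spectra (%/nm) for a set of samples.
#' The derivative value at wavelength w is (R(w+1) - R(w)) / 1 nm, assigned to
#' the left wavelength, so the grid is one point shorter than the reflectance
#' grid it came from.
#'
#' @slot wavelengths numeric, nm (left endpoints of the difference intervals).
#' @slot values matrix, wavelengths x samples, %/nm.
#' @export
setClass("DerivativeSet",
  representation(wavelengths = "numeric", values = "matrix"),
  validity = function(object) {
    if (nrow(object@values) != length(object@wavelengths))
      return("values must have one row per wavelength")
    if (is.unsorted(object@wavelengths, strictly = TRUE))
      return("wavelengths must be strictly increasing")
    TRUE
  }
)

.SPECIES <- c(
  "Ulva pertusa", "Sargassum thunbergii", "Sargassum fusiforme",
  "Chondrus ocellatus", "Chondria crassiaulis", "Grateloupia filicina"
)
.PHYLA <- c("Chlorophyta", "Ochrophyta", "Rhodophyta")
.SPECIES_PHYLUM <- c(
  "Ulva pertusa"         = "Chlorophyta",
  "Sargassum thunbergii" = "Ochrophyta",
  "Sargassum fusiforme"  = "Ochrophyta",
  "Chondrus ocellatus"   = "Rhodophyta",
  "Chondria crassiaulis" = "Rhodophyta",
  "Grateloupia filicina" = "Rhodophyta"
)
.DRYNESS <- c("wet", "moderate", "dry")

setValidity("SpectraSet", function(object) {
  msg <- character()
  if (!"reflectance" %in% assayNames(object))
    msg <- c(msg, "assay 'reflectance' is required")
  rd <- rowData(object)
  if (!"wavelength_nm" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain 'wavelength_nm'")
  } else {
    wl <- rd$wavelength_nm
    if (anyNA(wl) || is.unsorted(wl, strictly = TRUE))
      msg <- c(msg, "wavelengths must be finite and strictly increasing")
  }
  cd <- colData(object)
  for (f in c("species", "dryness", "phylum"))
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData must contain '%s'", f))
  if (ncol(object) > 0 && all(c("species", "phylum", "dryness") %in% colnames(cd))) {
    if (!all(cd$species %in% .SPECIES))
      msg <- c(msg, "unknown species label")
    if (!all(cd$dryness %in% .DRYNESS))
      msg <- c(msg, "dryness must be one of wet, moderate, dry")
    if (all(cd$species %in% .SPECIES) &&
        !identical(as.character(cd$phylum),
                   unname(.SPECIES_PHYLUM[as.character(cd$species)])))
      msg <- c(msg, "phylum labels inconsistent with species")
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "sample ids must be unique")
  }
  if ("reflectance" %in% assayNames(object)) {
    refl <- assay(object, "reflectance")
    if (!all(is.finite(refl)))
      msg <- c(msg, "reflectance must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectraSet
#'
#' @param reflectance numeric matrix, wavelengths x samples, percent (0--100).
#'   A plain vector is accepted for a single sample.
#' @param wavelengths numeric vector of wavelengths in nm, strictly increasing,
#'   one per row of `reflectance`.
#' @param species character vector of species names, one per sample; must be
#'   among [seaweedSpecies()]. The phylum label is derived automatically.
#' @param dryness character vector of dryness states (`"wet"`, `"moderate"`,
#'   `"dry"`), one per sample.
#' @param sampleIds optional unique sample identifiers; defaults to
#'   `sample_1 .. sample_n`.
#' @return a [SpectraSet-class] object.
#' @examples
#' wl <- 400:900
#' refl <- matrix(50, length(wl), 2)
#' ss <- SpectraSet(refl, wl, species = rep("Ulva pertusa", 2),
#'                  dryness = c("wet", "dry"))
#' @export
SpectraSet <- function(reflectance, wavelengths, species, dryness,
                       sampleIds = NULL) {
  if (is.vector(reflectance)) reflectance <- matrix(reflectance, ncol = 1L)
  n <- ncol(reflectance)
  if (is.null(sampleIds)) sampleIds <- paste0("sample_", seq_len(n))
  species <- as.character(species)
  dryness <- as.character(dryness)
  stopifnot(length(species) == n, length(dryness) == n,
            length(wavelengths) == nrow(reflectance))
  bad <- setdiff(species, .SPECIES)
  if (length(bad))
    stop("unknown species label(s): ", paste(unique(bad), collapse = ", "),
         "\n  known species: ", paste(.SPECIES, collapse = ", "))
  colnames(reflectance) <- sampleIds
  se <- SummarizedExperiment(
    assays  = list(reflectance = reflectance),
    rowData = DataFrame(wavelength_nm = as.numeric(wavelengths)),
    colData = DataFrame(
      sample_id = sampleIds,
      species   = species,
      phylum    = unname(.SPECIES_PHYLUM[species]),
      dryness   = dryness,
      row.names = sampleIds
    )
  )
  new("SpectraSet", se)
}

#' Species and phylum vocabulary
#'
#' @return `seaweedSpecies()` returns the six species names;
#'   `speciesToPhylum()` maps species names to their phylum
#'   (Chlorophyta for *Ulva*, Ochrophyta for both *Sargassum*,
#'   Rhodophyta for the remaining three).
#' @param species character vector of species names.
#' @examples
#' speciesToPhylum("Ulva pertusa")
#' @export
seaweedSpecies <- function() .SPECIES

#' @rdname seaweedSpecies
#' @export
speciesToPhylum <- function(species) {
  species <- as.character(species)
  bad <- setdiff(species, .SPECIES)
  if (length(bad))
    stop("unknown species label(s): ", paste(unique(bad), collapse = ", "))
  unname(.SPECIES_PHYLUM[species])
}

setMethod("show", "SpectraSet", function(object) {
  wl <- wavelengths(object)
  cat(sprintf("SpectraSet: %d spectra, %d wavelengths (%g-%g nm)\n",
              ncol(object), length(wl),
              if (length(wl)) min(wl) else NA, if (length(wl)) max(wl) else NA))
  if (ncol(object)) {
    sp <- table(colData(object)$species)
    cat("species: ",
        paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "DerivativeSet", function(object) {
  cat(sprintf("DerivativeSet: %d spectra, %d wavelengths (%g-%g nm), %%/nm\n",
              ncol(object@values), length(object@wavelengths),
              min(object@wavelengths), max(object@wavelengths)))
  invisible(NULL)
})
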