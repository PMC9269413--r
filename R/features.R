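# Derivative spectroscopy features: green peak, red valley, red/blue edges,
# edge areas and the RVI/NDVI indices built from them.

# Feature names in the fixed reporting order (descending screening
# significance as conventionally tabulated for these 14 variables).
.FEATURES <- c("NDVI_RgRr", "RVI_RgRr", "V_re", "A_be", "R_g", "L_re",
               "L_g", "L_r", "R_r", "L_be", "NDVI_AreAbe", "A_re", "V_be",
               "RVI_AreAbe")

# Search windows (nm): green peak and red valley on the reflectance curve,
# red and blue edge on the first-derivative curve.
.WINDOWS <- list(
  green    = c(510, 560),
  redvalley = c(640, 680),
  rededge  = c(680, 760),
  blueedge = c(490, 530)
)

#' The fourteen spectral variables
#'
#' Names of the fourteen derivative-spectroscopy variables computed by
#' [extractFeatures()], in the fixed reporting order used throughout the
#' package: green peak amplitude/location (`R_g`, `L_g`; maximum reflectance
#' in 510--560 nm), red valley amplitude/location (`R_r`, `L_r`; minimum
#' reflectance in 640--680 nm), red edge amplitude/location (`V_re`, `L_re`;
#' maximum of the first derivative in 680--760 nm), blue edge
#' amplitude/location (`V_be`, `L_be`; derivative maximum in 490--530 nm),
#' edge areas (`A_re`, `A_be`; sums of derivative values over the edge
#' windows) and the ratio / normalized-difference indices of the amplitude and
#' area pairs (`RVI_RgRr`, `RVI_AreAbe`, `NDVI_RgRr`, `NDVI_AreAbe`).
#'
#' @return character vector of length 14.
#' @export
spectralVariables <- function() .FEATURES

#' First-derivative spectrum
#'
#' Forward difference on a uniform 1-nm (or uniform `step`) grid: the value at
#' wavelength w is (R(w + step) - R(w)) / step, assigned to the left
#' wavelength w. The derivative of a constant spectrum is identically zero.
#'
#' @param x a [SpectraSet-class], or a numeric wavelength vector (with
#'   `reflectance` supplied).
#' @param reflectance numeric reflectance vector when `x` is the wavelength
#'   vector.
#' @param ... unused.
#' @return a [DerivativeSet-class] (for a SpectraSet) or a list with
#'   `wavelengths` and `values` (vector input).
#' @export
setMethod("firstDerivative", "SpectraSet", function(x, ...) {
  wl <- wavelengths(x)
  .checkUniform(wl)
  step <- wl[2] - wl[1]
  vals <- diff(reflectance(x)) / step
  new("DerivativeSet", wavelengths = wl[-length(wl)], values = vals)
})

#' @rdname firstDerivative
#' @export
setMethod("firstDerivative", "numeric", function(x, reflectance, ...) {
  stopifnot(length(x) == length(reflectance))
  .checkUniform(x)
  step <- x[2] - x[1]
  list(wavelengths = x[-length(x)], values = diff(reflectance) / step)
})

.checkUniform <- function(wl) {
  if (length(wl) < 2) .stopf("need at least 2 wavelengths")
  d <- diff(wl)
  if (max(abs(d - d[1])) > 1e-9)
    .stopf("first derivative requires a uniform wavelength grid")
}

#' Extremum of a curve within a wavelength window
#'
#' Finds the maximum or minimum of a sampled curve over the grid points in the
#' closed window \[lo, hi\]. Ties break to the smallest wavelength, so results
#' are deterministic (a constant curve reports the window's lower bound).
#'
#' @param wavelengths numeric, strictly increasing (nm).
#' @param values numeric curve sampled at `wavelengths` (reflectance % or
#'   derivative %/nm).
#' @param lo,hi window bounds in nm (closed interval).
#' @param mode `"max"` or `"min"`.
#' @return list with `location` (nm) and `value`.
#' @examples
#' ref <- buildReferenceCurve(defaultAnchorTables()[["Ulva pertusa"]])
#' findWindowExtremum(ref$wavelength_nm, ref$reflectance_pct,
#'                    640, 680, "min")  # red valley: 669 nm, 5.78%
#' @export
findWindowExtremum <- function(wavelengths, values, lo, hi,
                               mode = c("max", "min")) {
  mode <- match.arg(mode)
  stopifnot(length(wavelengths) == length(values))
  idx <- which(wavelengths >= lo & wavelengths <= hi)
  if (!length(idx)) .stopf("no grid points in window [%g, %g]", lo, hi)
  v <- values[idx]
  j <- if (mode == "max") which.max(v) else which.min(v)
  list(location = wavelengths[idx[j]], value = v[j])
}

#' Sum of derivative values over a window (edge area)
#'
#' On a 1-nm grid the sum of first-derivative values over \[lo, hi\] equals
#' the area under the derivative curve. By the telescoping identity of the
#' forward difference, the area over \[a, b\] equals R(b + 1) - R(a).
#'
#' @param wavelengths numeric, derivative grid (left endpoints, nm).
#' @param values numeric derivative values (%/nm).
#' @param lo,hi window bounds in nm (closed interval).
#' @return numeric area (%).
#' @export
windowArea <- function(wavelengths, values, lo, hi) {
  stopifnot(length(wavelengths) == length(values))
  idx <- which(wavelengths >= lo & wavelengths <= hi)
  if (!length(idx)) .stopf("no grid points in window [%g, %g]", lo, hi)
  sum(values[idx])
}

#' Ratio and normalized-difference vegetation indices
#'
#' `RVI(x, y) = x / y`; `NDVI(x, y) = (x - y) / (x + y)`, computed for the
#' green-peak/red-valley amplitude pair and the red-edge/blue-edge area pair.
#' A zero denominator yields `NA` with a warning (the sample is excluded from
#' downstream fits).
#'
#' @param R_g,R_r green peak and red valley amplitudes (%).
#' @param A_re,A_be red and blue edge areas (%).
#' @return named list `RVI_RgRr`, `RVI_AreAbe`, `NDVI_RgRr`, `NDVI_AreAbe`.
#' @export
computeIndices <- function(R_g, R_r, A_re, A_be) {
  safeDiv <- function(num, den, what) {
    if (isTRUE(all.equal(den, 0)) || den == 0) {
      warning("undefined feature ", what, ": zero denominator", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  list(
    RVI_RgRr   = safeDiv(R_g, R_r, "RVI_RgRr"),
    RVI_AreAbe = safeDiv(A_re, A_be, "RVI_AreAbe"),
    NDVI_RgRr  = safeDiv(R_g - R_r, R_g + R_r, "NDVI_RgRr"),
    NDVI_AreAbe = safeDiv(A_re - A_be, A_re + A_be, "NDVI_AreAbe")
  )
}

#' Extract the fourteen spectral variables from one spectrum
#'
#' The spectrum must be trimmed and resampled to a uniform 1-nm grid covering
#' the feature windows (400--900 nm suffices). Windows: green peak = maximum
#' reflectance in 510--560 nm; red valley = minimum reflectance in
#' 640--680 nm (the chlorophyll absorption valley); red and blue edges =
#' maximum of the first derivative in 680--760 and 490--530 nm; edge areas =
#' derivative sums over those windows. Location features are grid wavelengths.
#'
#' @param wavelengths numeric, uniform 1-nm grid (nm).
#' @param reflectance numeric percent reflectance at `wavelengths`.
#' @return named numeric vector of the 14 variables (see
#'   [spectralVariables()] for order); undefined indices are `NA`.
#' @examples
#' ref <- buildReferenceCurve(defaultAnchorTables()[["Ulva pertusa"]])
#' f <- extractFeatures(ref$wavelength_nm, ref$reflectance_pct)
#' f[c("L_g", "L_r", "R_r")]  # 554 nm, 669 nm, 5.78%
#' @export
extractFeatures <- function(wavelengths, reflectance) {
  d <- firstDerivative(wavelengths, reflectance)
  g  <- findWindowExtremum(wavelengths, reflectance,
                           .WINDOWS$green[1], .WINDOWS$green[2], "max")
  rv <- findWindowExtremum(wavelengths, reflectance,
                           .WINDOWS$redvalley[1], .WINDOWS$redvalley[2], "min")
  re <- findWindowExtremum(d$wavelengths, d$values,
                           .WINDOWS$rededge[1], .WINDOWS$rededge[2], "max")
  be <- findWindowExtremum(d$wavelengths, d$values,
                           .WINDOWS$blueedge[1], .WINDOWS$blueedge[2], "max")
  A_re <- windowArea(d$wavelengths, d$values,
                     .WINDOWS$rededge[1], .WINDOWS$rededge[2])
  A_be <- windowArea(d$wavelengths, d$values,
                     .WINDOWS$blueedge[1], .WINDOWS$blueedge[2])
  idx <- computeIndices(g$value, rv$value, A_re, A_be)
  out <- c(NDVI_RgRr = idx$NDVI_RgRr, RVI_RgRr = idx$RVI_RgRr,
           V_re = re$value, A_be = A_be, R_g = g$value, L_re = re$location,
           L_g = g$location, L_r = rv$location, R_r = rv$value,
           L_be = be$location, NDVI_AreAbe = idx$NDVI_AreAbe, A_re = A_re,
           V_be = be$value, RVI_AreAbe = idx$RVI_AreAbe)
  out[.FEATURES]
}

#' Feature table for a spectral library
#'
#' Applies [extractFeatures()] to every sample and returns one row per sample
#' with the label columns followed by the 14 variables in the fixed order.
#'
#' @param x a [SpectraSet-class] on a uniform 1-nm grid covering 490--761 nm.
#' @return data.frame with columns `sample_id, species, phylum, dryness` then
#'   the 14 feature columns. Samples with undefined features keep `NA` values;
#'   a message reports how many.
#' @export
buildFeatureTable <- function(x) {
  stopifnot(is(x, "SpectraSet"))
  if (ncol(x) == 0) {
    out <- data.frame(sample_id = character(), species = character(),
                      phylum = character(), dryness = character())
    for (f in .FEATURES) out[[f]] <- numeric()
    return(out)
  }
  wl <- wavelengths(x)
  refl <- reflectance(x)
  feats <- t(vapply(seq_len(ncol(x)),
                    function(i) extractFeatures(wl, refl[, i]),
                    numeric(length(.FEATURES))))
  cd <- colData(x)
  out <- data.frame(sample_id = colnames(x),
                    species = as.character(cd$species),
                    phylum = as.character(cd$phylum),
                    dryness = as.character(cd$dryness),
                    feats, check.names = FALSE, row.names = NULL)
  nbad <- sum(!stats::complete.cases(out[, .FEATURES]))
  if (nbad > 0)
    message(nbad, " sample(s) have undefined features (zero denominators)")
  out
}
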