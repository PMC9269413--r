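# Synthetic spectrum generator. The study's field spectra are not deposited;
# this module generates labelled stand-in spectra whose class structure is
# pinned to published band-wise reflectance values (anchor points) for the six
# species / three phyla. All generated data are synthetic and are documented
# as such.

#' Anchor tables for reference curves
#'
#' An anchor table is an ordered list of (wavelength nm, reflectance %)
#' control points through which a class's reference curve passes exactly.
#' `defaultAnchorTables()` returns the built-in tables: one per phylum
#' template (`Chlorophyta`, `Ochrophyta`, `Rhodophyta`) and one per species.
#' Species tables are derived from their phylum template by small wavelength
#' shifts of the mid-visible extremum anchor and amplitude scaling of the
#' visible band, making species within a phylum separable but similar while
#' phyla stay far apart.
#'
#' @param className name of the class the anchors describe.
#' @param wavelength,reflectance numeric vectors: strictly increasing
#'   wavelengths (nm) and reflectance values in \[0, 100\] (%); at least 4
#'   anchors.
#' @return `anchorTable()`: a data.frame with class attribute `"AnchorTable"`,
#'   columns `wavelength_nm`, `reflectance_pct`, attribute `className`.
#'   `defaultAnchorTables()`: a named list of anchor tables.
#' @examples
#' tabs <- defaultAnchorTables()
#' tabs[["Ulva pertusa"]]
#' @export
anchorTable <- function(className, wavelength, reflectance) {
  stopifnot(length(wavelength) == length(reflectance))
  if (length(wavelength) < 4)
    .stopf("anchor table '%s' needs at least 4 anchors", className)
  if (is.unsorted(wavelength, strictly = TRUE))
    .stopf("anchor wavelengths must be strictly increasing ('%s')", className)
  if (any(reflectance < 0 | reflectance > 100))
    .stopf("anchor reflectance must lie in [0, 100] ('%s')", className)
  out <- data.frame(wavelength_nm = as.numeric(wavelength),
                    reflectance_pct = as.numeric(reflectance))
  attr(out, "className") <- className
  class(out) <- c("AnchorTable", "data.frame")
  out
}

# Shape-preserving interpolation; two control points degenerate to the
# linear segment (itself shape-preserving).
.pchip <- function(x, y, xout) {
  if (length(x) == 2) stats::approx(x, y, xout = xout)$y
  else pracma::pchip(x, y, xout)
}

# Shift selected anchor wavelengths and scale visible-band (<= visHi nm)
# amplitudes; used to derive species tables from phylum templates.
.deriveSpeciesTable <- function(template, className, shiftAt = numeric(),
                                shiftBy = 0, ampScale = 1, visHi = 700) {
  wl <- template$wavelength_nm
  refl <- template$reflectance_pct
  if (length(shiftAt) && shiftBy != 0)
    wl[wl %in% shiftAt] <- wl[wl %in% shiftAt] + shiftBy
  vis <- wl <= visHi
  refl[vis] <- pmin(100, refl[vis] * ampScale)
  anchorTable(className, wl, refl)
}

#' @rdname anchorTable
#' @export
defaultAnchorTables <- function() {
  chloro <- anchorTable("Chlorophyta",
    wavelength  = c(400, 492, 554, 669, 760, 780, 900),
    reflectance = c(3.6, 7.72, 25.27, 5.78, 83.4, 80, 80))
  ochro <- anchorTable("Ochrophyta",
    wavelength  = c(400, 492, 570, 583, 596, 620, 643, 700, 760, 780, 900),
    reflectance = c(0.85, 1.4, 3.0, 2.6, 3.74, 1.8, 2.19, 3.5, 34.91, 35, 35))
  rhodo <- anchorTable("Rhodophyta",
    wavelength  = c(400, 492, 536, 648, 663, 678, 700, 760, 780, 900),
    reflectance = c(30.4, 33.79, 12.55, 33.87, 31.0, 32.31, 40, 86.04, 85, 85))
  list(
    "Chlorophyta" = chloro,
    "Ochrophyta"  = ochro,
    "Rhodophyta"  = rhodo,
    "Ulva pertusa" = .deriveSpeciesTable(chloro, "Ulva pertusa"),
    "Sargassum thunbergii" =
      .deriveSpeciesTable(ochro, "Sargassum thunbergii"),
    "Sargassum fusiforme" =
      .deriveSpeciesTable(ochro, "Sargassum fusiforme", ampScale = 1.07),
    "Chondria crassiaulis" =
      .deriveSpeciesTable(rhodo, "Chondria crassiaulis"),
    "Chondrus ocellatus" =
      .deriveSpeciesTable(rhodo, "Chondrus ocellatus",
                          shiftAt = 536, shiftBy = -14, ampScale = 0.95),
    "Grateloupia filicina" =
      .deriveSpeciesTable(rhodo, "Grateloupia filicina",
                          shiftAt = 536, shiftBy = -9, ampScale = 1.05)
  )
}

#' Build a reference curve from an anchor table
#'
#' Interpolates the anchors with a shape-preserving piecewise cubic Hermite
#' (PCHIP, [pracma::pchip]): between adjacent anchors the curve is monotone,
#' so it never overshoots and every local extremum of the reference curve is
#' an anchor. The curve passes through each anchor exactly.
#'
#' @param anchors an `AnchorTable` (see [anchorTable()]).
#' @param grid wavelength grid (nm) at which to evaluate; must lie within the
#'   anchor span.
#' @return data.frame with columns `wavelength_nm` and `reflectance_pct`.
#' @examples
#' ref <- buildReferenceCurve(defaultAnchorTables()[["Ulva pertusa"]], 400:900)
#' ref$reflectance_pct[ref$wavelength_nm == 554]  # 25.27, the green peak
#' @export
buildReferenceCurve <- function(anchors, grid = 400:900) {
  wl <- anchors$wavelength_nm
  refl <- anchors$reflectance_pct
  if (is.unsorted(wl, strictly = TRUE))
    .stopf("anchor wavelengths must be strictly increasing")
  if (min(grid) < min(wl) || max(grid) > max(wl))
    .stopf("grid [%g, %g] extends beyond the anchor span [%g, %g]",
           min(grid), max(grid), min(wl), max(wl))
  data.frame(wavelength_nm = as.numeric(grid),
             reflectance_pct = .pchip(wl, refl, as.numeric(grid)))
}

#' Dryness-state spectral effect
#'
#' The study never quantifies how drying changes a thallus spectrum; the
#' generator uses a simple multiplicative brightness model (drier = brighter),
#' a synthetic stand-in, with results clipped to the physical \[0, 100\] range.
#'
#' @param reflectance numeric vector of percent reflectance.
#' @param state one of `"wet"`, `"moderate"`, `"dry"`.
#' @param gains named numeric gains per state (defaults 0.90 / 1.00 / 1.10).
#' @return the scaled reflectance vector.
#' @export
applyDrynessState <- function(reflectance, state,
                              gains = c(wet = 0.90, moderate = 1.00,
                                        dry = 1.10)) {
  state <- match.arg(state, .DRYNESS)
  if (any(gains <= 0)) .stopf("dryness gains must be positive")
  pmin(100, pmax(0, reflectance * gains[[state]]))
}

#' Noise model for the synthetic generator
#'
#' Sample-level noise applied to a reference curve, in order: a multiplicative
#' gain ~ Normal(1, `ampSd`) truncated to \[0.7, 1.3\] (models illumination /
#' biomass variability and dominates within-class variance), an integer
#' wavelength shift uniform on \{-`shiftMaxNm` .. `shiftMaxNm`\} (models
#' calibration jitter), and additive Gaussian noise of sd `smoothSdPct` (%)
#' smoothed with a Gaussian kernel of width `smoothKernelNm` nm (models
#' correlated sensor noise).
#'
#' @param ampSd sd of the multiplicative gain (unitless, mean 1).
#' @param smoothSdPct sd of the additive noise before smoothing (%).
#' @param smoothKernelNm Gaussian smoothing sd of the additive noise (nm).
#' @param shiftMaxNm maximum absolute wavelength shift (integer nm).
#' @return a list of class `"NoiseModel"`.
#' @export
noiseModel <- function(ampSd = 0.08, smoothSdPct = 0.4, smoothKernelNm = 5,
                       shiftMaxNm = 2) {
  vals <- c(ampSd, smoothSdPct, smoothKernelNm, shiftMaxNm)
  if (any(vals < 0)) .stopf("noise model parameters must be non-negative")
  structure(list(ampSd = ampSd, smoothSdPct = smoothSdPct,
                 smoothKernelNm = smoothKernelNm,
                 shiftMaxNm = as.integer(shiftMaxNm)),
            class = "NoiseModel")
}

#' Generator configuration
#'
#' Defaults reproduce the study scale: 382 samples over six species (64 each
#' for four species, 63 for the two *Sargassum*), split as evenly as possible
#' over the three dryness states.
#'
#' @param counts species-by-dryness integer matrix of sample counts (rownames
#'   species, colnames dryness states); `NULL` for the 382-sample default.
#' @param noise a [noiseModel()].
#' @param drynessGains named gains per dryness state.
#' @param seed integer RNG seed; generation is fully reproducible from it.
#' @param anchors named list of anchor tables containing every species used.
#' @param grid wavelength grid for the generated spectra (default 400:900 nm).
#' @return a list of class `"GeneratorConfig"`.
#' @export
generatorConfig <- function(counts = NULL, noise = noiseModel(),
                            drynessGains = c(wet = 0.90, moderate = 1.00,
                                             dry = 1.10),
                            seed = 1, anchors = defaultAnchorTables(),
                            grid = 400:900) {
  if (is.null(counts)) {
    totals <- c("Ulva pertusa" = 64L, "Sargassum thunbergii" = 63L,
                "Sargassum fusiforme" = 63L, "Chondrus ocellatus" = 64L,
                "Chondria crassiaulis" = 64L, "Grateloupia filicina" = 64L)
    counts <- t(vapply(totals, function(n) {
      base <- n %/% 3L
      extra <- n %% 3L
      base + c(rep(1L, extra), rep(0L, 3L - extra))
    }, integer(3)))
    colnames(counts) <- .DRYNESS
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("counts must have species rownames and dryness colnames")
  if (sum(counts) < 1) .stopf("total sample count must be at least 1")
  if (any(drynessGains <= 0)) .stopf("dryness gains must be positive")
  miss <- setdiff(rownames(counts), names(anchors))
  if (length(miss))
    .stopf("no anchor table for: %s", paste(miss, collapse = ", "))
  structure(list(counts = counts, noise = noise,
                 drynessGains = drynessGains, seed = as.integer(seed),
                 anchors = anchors, grid = as.numeric(grid)),
            class = "GeneratorConfig")
}

#' Generate a synthetic labelled spectral library
#'
#' For each sample the pipeline is: species reference curve (monotone
#' interpolation of its anchor table) -> dryness gain -> truncated
#' multiplicative gain -> integer wavelength shift -> additive smoothed
#' Gaussian noise -> clip to \[0, 100\]. Fully reproducible from
#' `config$seed`.
#'
#' @param config a [generatorConfig()].
#' @return a [SpectraSet-class] with one column per generated sample.
#' @examples
#' ss <- generateDataset(generatorConfig(seed = 7))
#' ncol(ss)  # 382
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  grid <- config$grid
  nm <- config$noise
  funs <- lapply(config$anchors, function(a)
    function(x) .pchip(a$wavelength_nm, a$reflectance_pct, x))
  .withSeed(config$seed, {
    cols <- list(); species <- character(); dryness <- character()
    ids <- character()
    for (sp in rownames(config$counts)) {
      f <- funs[[sp]]
      spanSp <- range(config$anchors[[sp]]$wavelength_nm)
      for (st in colnames(config$counts)) {
        n <- config$counts[sp, st]
        for (i in seq_len(n)) {
          r <- f(grid)
          r <- applyDrynessState(r, st, config$drynessGains)
          gain <- stats::rnorm(1, 1, nm$ampSd)
          tries <- 0
          while ((gain < 0.7 || gain > 1.3) && tries < 1000) {
            gain <- stats::rnorm(1, 1, nm$ampSd); tries <- tries + 1
          }
          if (gain < 0.7 || gain > 1.3) gain <- min(1.3, max(0.7, gain))
          r <- r * gain
          shift <- if (nm$shiftMaxNm > 0)
            sample.int(2L * nm$shiftMaxNm + 1L, 1L) - nm$shiftMaxNm - 1L
          else 0L
          if (shift != 0)
            r <- f(pmin(spanSp[2], pmax(spanSp[1], grid - shift))) *
                 config$drynessGains[[st]] * gain
          if (nm$smoothSdPct > 0)
            r <- r + .gaussianSmooth(stats::rnorm(length(grid), 0,
                                                  nm$smoothSdPct),
                                     nm$smoothKernelNm)
          r <- pmin(100, pmax(0, r))
          cols[[length(cols) + 1L]] <- r
          species <- c(species, sp)
          dryness <- c(dryness, st)
          ids <- c(ids, sprintf("%s_%s_%02d", gsub(" ", "_", sp), st, i))
        }
      }
    }
    SpectraSet(do.call(cbind, cols), grid, species = species,
               dryness = dryness, sampleIds = ids)
  })
}
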