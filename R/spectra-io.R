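#' Read a labelled spectral library from CSV
#'
#' Two dialects are supported. The long dialect has one row per
#' (sample, wavelength) with columns `sample_id, species, dryness,
#' wavelength_nm, reflectance_pct`. The wide dialect has one row per sample:
#' label columns `sample_id, species, dryness` followed by one column per
#' wavelength, named by the wavelength in nm (e.g. `"400" .. "900"`).
#'
#' Reflectance is stored on the percent (0--100) scale. A curve lying entirely
#' in \[0, 1\] is rejected as a probable unit error unless `fractional = TRUE`,
#' in which case all input values are multiplied by 100 on read.
#'
#' All samples must share one wavelength grid (a mixed-grid library cannot be
#' held in the matrix container; resample the per-sample files upstream).
#' Input sample order is preserved.
#'
#' @param path path to a CSV file (UTF-8, header row mandatory).
#' @param dialect `"long"` or `"wide"`.
#' @param fractional logical; set `TRUE` when the file stores reflectance as a
#'   0--1 fraction rather than percent.
#' @return a [SpectraSet-class].
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path, dialect = c("long", "wide"), fractional = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (dialect == "long") {
    need <- c("sample_id", "species", "dryness", "wavelength_nm",
              "reflectance_pct")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      .stopf("long CSV is missing column(s): %s", paste(miss, collapse = ", "))
    refl <- suppressWarnings(as.numeric(raw$reflectance_pct))
    if (anyNA(refl))
      .stopf("non-numeric reflectance at data row %d", which(is.na(refl))[1])
    wl <- suppressWarnings(as.numeric(raw$wavelength_nm))
    if (anyNA(wl))
      .stopf("non-numeric wavelength at data row %d", which(is.na(wl))[1])
    ids <- unique(raw$sample_id)
    grids <- split(wl, factor(raw$sample_id, levels = ids))
    g1 <- sort(grids[[1]])
    same <- vapply(grids, function(g) identical(sort(g), g1), logical(1))
    if (!all(same))
      .stopf("samples are on different wavelength grids (first mismatch: %s)",
             names(grids)[which(!same)[1]])
    mat <- matrix(NA_real_, length(g1), length(ids),
                  dimnames = list(NULL, ids))
    ord <- order(match(raw$sample_id, ids), wl)
    mat[] <- refl[ord]
    labs <- raw[!duplicated(raw$sample_id), c("sample_id", "species", "dryness")]
    wlOut <- g1
  } else {
    need <- c("sample_id", "species", "dryness")
    miss <- setdiff(need, names(raw))
    if (length(miss))
      .stopf("wide CSV is missing column(s): %s", paste(miss, collapse = ", "))
    wlCols <- setdiff(names(raw), need)
    wlOut <- suppressWarnings(as.numeric(wlCols))
    if (anyNA(wlOut))
      .stopf("non-numeric wavelength column name: %s", wlCols[which(is.na(wlOut))[1]])
    o <- order(wlOut)
    wlOut <- wlOut[o]
    mat <- matrix(NA_real_, length(wlOut), nrow(raw),
                  dimnames = list(NULL, raw$sample_id))
    for (i in seq_len(nrow(raw))) {
      v <- suppressWarnings(as.numeric(unlist(raw[i, wlCols[o]])))
      if (anyNA(v))
        .stopf("non-numeric reflectance at data row %d", i)
      mat[, i] <- v
    }
    labs <- raw[, need]
  }
  bad <- setdiff(unique(labs$species), .SPECIES)
  if (length(bad))
    .stopf("unknown species label(s): %s\n  known species: %s",
           paste(bad, collapse = ", "), paste(.SPECIES, collapse = ", "))
  if (fractional) {
    mat <- mat * 100
  } else {
    allFrac <- apply(mat, 2, function(v) all(v >= 0 & v <= 1))
    if (any(allFrac))
      .stopf(paste("sample '%s' lies entirely in [0, 1]; reflectance must be",
                   "on the percent scale (use fractional = TRUE for 0-1 input)"),
             colnames(mat)[which(allFrac)[1]])
  }
  SpectraSet(mat, wlOut, species = labs$species, dryness = labs$dryness,
             sampleIds = labs$sample_id)
}

#' Write a spectral library to CSV
#'
#' Writes a [SpectraSet-class] in either CSV dialect understood by
#' [readSpectra()]. Numeric values are formatted with 10 significant digits,
#' so write -> read -> write is byte-stable and read-back values agree with
#' the originals to formatting precision.
#'
#' @param x a non-empty [SpectraSet-class].
#' @param path output file path.
#' @param dialect `"long"` or `"wide"`.
#' @return invisibly, `path`.
#' @export
writeSpectra <- function(x, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(is(x, "SpectraSet"))
  if (ncol(x) == 0) .stopf("cannot write an empty SpectraSet")
  wl <- wavelengths(x)
  refl <- reflectance(x)
  cd <- colData(x)
  if (dialect == "long") {
    df <- data.frame(
      sample_id = rep(colnames(x), each = length(wl)),
      species = rep(as.character(cd$species), each = length(wl)),
      dryness = rep(as.character(cd$dryness), each = length(wl)),
      wavelength_nm = rep(.fmtNum(wl), times = ncol(x)),
      reflectance_pct = .fmtNum(as.vector(refl)),
      check.names = FALSE
    )
  } else {
    df <- data.frame(
      sample_id = colnames(x),
      species = as.character(cd$species),
      dryness = as.character(cd$dryness),
      check.names = FALSE
    )
    m <- t(refl)
    vals <- as.data.frame(matrix(.fmtNum(m), nrow = nrow(m)))
    names(vals) <- .fmtNum(wl)
    df <- cbind(df, vals)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trim spectra to a wavelength interval
#'
#' Field spectroradiometer readings below 400 nm are noisy and those above
#' 900 nm are degraded by water-vapour absorption, so downstream analysis uses
#' the closed interval \[400, 900\] nm by default. Both endpoints are kept.
#'
#' @param x a [SpectraSet-class].
#' @param lo,hi interval bounds in nm (closed on both ends).
#' @return the trimmed [SpectraSet-class]; labels untouched.
#' @export
setMethod("trimWavelengths", "SpectraSet", function(x, lo = 400, hi = 900) {
  if (lo > hi) .stopf("empty wavelength range: lo = %g > hi = %g", lo, hi)
  keep <- which(wavelengths(x) >= lo & wavelengths(x) <= hi)
  if (!length(keep))
    .stopf("no wavelengths in [%g, %g]", lo, hi)
  x[keep, ]
})

#' Average replicate spectra
#'
#' Replicate field reads of the same target are averaged pointwise into one
#' representative curve per group, reducing instrument noise. Groups are
#' defined by a subset of the label columns; the group size is recorded as an
#' `_n<k>` suffix on the new sample id.
#'
#' @param x a [SpectraSet-class]; all spectra share the grid by construction.
#' @param groupBy character, label columns to group by (any of `"species"`,
#'   `"dryness"`, `"sample_id"`).
#' @return a [SpectraSet-class] with one spectrum per group.
#' @export
setMethod("averageReplicates", "SpectraSet",
          function(x, groupBy = c("species", "dryness")) {
  cd <- as.data.frame(colData(x))
  miss <- setdiff(groupBy, colnames(cd))
  if (length(miss))
    .stopf("unknown grouping column(s): %s", paste(miss, collapse = ", "))
  key <- do.call(paste, c(lapply(groupBy, function(k) cd[[k]]), sep = "|"))
  keys <- unique(key)
  refl <- reflectance(x)
  out <- vapply(keys, function(k) rowMeans(refl[, key == k, drop = FALSE]),
                numeric(nrow(refl)))
  sizes <- vapply(keys, function(k) sum(key == k), integer(1))
  first <- match(keys, key)
  ids <- paste0(gsub("[| ]", "_", keys), "_n", sizes)
  SpectraSet(out, wavelengths(x),
             species = as.character(cd$species[first]),
             dryness = as.character(cd$dryness[first]),
             sampleIds = ids)
})

#' Resample spectra onto a regular integer-nm grid
#'
#' Linear interpolation onto the integer multiples of `step` nm spanned by the
#' input grid. No extrapolation: the output grid is contained in the input
#' range. Data already on the target grid pass through exactly.
#'
#' @param x a [SpectraSet-class] with at least 2 wavelengths.
#' @param step grid step in nm (default 1, the instrument's sampling interval).
#' @return a resampled [SpectraSet-class].
#' @export
setMethod("resampleToGrid", "SpectraSet", function(x, step = 1) {
  wl <- wavelengths(x)
  if (length(wl) < 2) .stopf("need at least 2 wavelengths to resample")
  grid <- seq(ceiling(min(wl) / step) * step, floor(max(wl) / step) * step,
              by = step)
  if (!length(grid))
    .stopf("no multiple of %g nm lies inside [%g, %g]", step, min(wl), max(wl))
  refl <- reflectance(x)
  out <- apply(refl, 2, function(v) stats::approx(wl, v, xout = grid)$y)
  cd <- colData(x)
  SpectraSet(out, grid, species = as.character(cd$species),
             dryness = as.character(cd$dryness), sampleIds = colnames(x))
})
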