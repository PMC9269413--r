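ulvaRef <- buildReferenceCurve(defaultAnchorTables()[["Ulva pertusa"]],
                               400:900)
rhodoRef <- buildReferenceCurve(defaultAnchorTables()[["Rhodophyta"]],
                                400:900)

test_that("forward difference behaves on constants, ramps and the red edge", {
  wl <- 400:500
  d <- firstDerivative(wl, rep(50, length(wl)))
  expect_equal(d$values, rep(0, length(wl) - 1))
  expect_equal(d$wavelengths, wl[-length(wl)])

  d <- firstDerivative(wl, 0.1 * wl)
  expect_equal(d$values, rep(0.1, length(wl) - 1), tolerance = 1e-12)

  expect_error(firstDerivative(c(400, 401, 403), c(1, 2, 3)), "uniform")

  # the red-edge segment of the green-seaweed reference rises monotonically
  d <- firstDerivative(ulvaRef$wavelength_nm, ulvaRef$reflectance_pct)
  seg <- d$values[d$wavelengths >= 680 & d$wavelengths <= 755]
  expect_true(all(seg > 0))
})

test_that("window extremum matches an exhaustive scan and breaks ties low", {
  cst <- findWindowExtremum(400:900, rep(5, 501), 510, 560, "max")
  expect_equal(cst$location, 510)
  expect_equal(cst$value, 5)

  set.seed(14)
  for (i in 1:200) {
    wl <- 400:500
    v <- runif(101)
    lo <- sample(400:450, 1); hi <- lo + sample(5:50, 1)
    mode <- sample(c("max", "min"), 1)
    got <- findWindowExtremum(wl, v, lo, hi, mode)
    # brute-force scan oracle with explicit first-tie rule
    bestLoc <- NA; bestVal <- if (mode == "max") -Inf else Inf
    for (j in seq_along(wl)) {
      if (wl[j] < lo || wl[j] > hi) next
      better <- if (mode == "max") v[j] > bestVal else v[j] < bestVal
      if (better) { bestVal <- v[j]; bestLoc <- wl[j] }
    }
    expect_identical(got$location, bestLoc)
    expect_identical(got$value, bestVal)
  }
  expect_error(findWindowExtremum(400:500, runif(101), 600, 650), "window")
})

test_that("edge areas telescope to endpoint reflectance differences", {
  wl <- 400:900
  expect_equal(windowArea(wl[-501], rep(0, 500), 680, 760), 0)

  set.seed(15)
  for (i in 1:20) {
    v <- runif(501, 1, 80)
    d <- firstDerivative(wl, v)
    a <- sample(400:850, 1); b <- a + sample(3:40, 1)
    expect_equal(windowArea(d$wavelengths, d$values, a, b),
                 v[wl == b + 1] - v[wl == a], tolerance = 1e-9)
  }

  d <- firstDerivative(ulvaRef$wavelength_nm, ulvaRef$reflectance_pct)
  A_re <- windowArea(d$wavelengths, d$values, 680, 760)
  A_be <- windowArea(d$wavelengths, d$values, 490, 530)
  expect_gt(A_re, 0)
  expect_gt(A_re, A_be)
})

test_that("vegetation indices follow their closed forms", {
  idx <- computeIndices(R_g = 10, R_r = 10, A_re = 4, A_be = 2)
  expect_equal(idx$NDVI_RgRr, 0)
  expect_equal(idx$RVI_RgRr, 1)
  expect_equal(idx$NDVI_AreAbe, 1 / 3)

  # arithmetic on the printed green-peak / red-valley amplitudes
  idx <- computeIndices(R_g = 25.27, R_r = 5.78, A_re = 1, A_be = 1)
  expect_equal(idx$NDVI_RgRr, (25.27 - 5.78) / (25.27 + 5.78))
  expect_equal(idx$NDVI_RgRr, 0.6277, tolerance = 1e-4)
  expect_equal(idx$RVI_RgRr, 25.27 / 5.78)
  expect_equal(idx$RVI_RgRr, 4.3720, tolerance = 1e-4)

  expect_warning(idx <- computeIndices(1, 0, 1, 1), "zero denominator")
  expect_true(is.na(idx$RVI_RgRr))
})

test_that("feature extraction recovers the printed reference values", {
  f <- extractFeatures(ulvaRef$wavelength_nm, ulvaRef$reflectance_pct)
  expect_equal(unname(f["L_r"]), 669)
  expect_equal(unname(f["R_r"]), 5.78)
  expect_equal(unname(f["L_g"]), 554)
  expect_equal(unname(f["R_g"]), 25.27)
  expect_named(f, spectralVariables())
})

test_that("a constant spectrum yields degenerate but defined features", {
  wl <- 400:900
  suppressWarnings(f <- extractFeatures(wl, rep(50, 501)))
  expect_equal(unname(f["V_re"]), 0)
  expect_equal(unname(f["V_be"]), 0)
  expect_equal(unname(f["A_re"]), 0)
  expect_equal(unname(f["A_be"]), 0)
  expect_equal(unname(f["NDVI_RgRr"]), 0)
  expect_equal(unname(f["RVI_RgRr"]), 1)
  expect_true(is.na(f["NDVI_AreAbe"]))  # 0/0 is undefined, flagged
  expect_equal(unname(f["L_g"]), 510)
  expect_equal(unname(f["L_r"]), 640)
  expect_equal(unname(f["L_re"]), 680)
  expect_equal(unname(f["L_be"]), 490)
})

test_that("red-seaweed green-window features equal the brute-force scan", {
  # the red-seaweed curve falls then rises over 510-560, so the window
  # "peak" is a boundary value -- the scan rule must still hold
  f <- extractFeatures(rhodoRef$wavelength_nm, rhodoRef$reflectance_pct)
  idx <- which(rhodoRef$wavelength_nm >= 510 & rhodoRef$wavelength_nm <= 560)
  expect_equal(unname(f["R_g"]), max(rhodoRef$reflectance_pct[idx]))
  expect_equal(unname(f["L_g"]),
               rhodoRef$wavelength_nm[idx][which.max(rhodoRef$reflectance_pct[idx])])
})

test_that("wavelength shifts move locations and preserve amplitudes", {
  k <- 3
  wl <- 400:900
  shifted <- c(rep(ulvaRef$reflectance_pct[1], k),
               ulvaRef$reflectance_pct[1:(501 - k)])
  f0 <- extractFeatures(wl, ulvaRef$reflectance_pct)
  f1 <- extractFeatures(wl, shifted)
  for (loc in c("L_g", "L_r", "L_re", "L_be"))
    expect_equal(unname(f1[loc]), unname(f0[loc]) + k)
  for (amp in c("R_g", "R_r", "V_re", "V_be"))
    expect_equal(unname(f1[amp]), unname(f0[amp]), tolerance = 1e-9)
})

test_that("NDVI of strictly positive spectra stays inside (-1, 1)", {
  set.seed(16)
  for (i in 1:50) {
    v <- runif(501, 0.5, 95)
    f <- suppressWarnings(extractFeatures(400:900, v))
    expect_gt(f["NDVI_RgRr"], -1)
    expect_lt(f["NDVI_RgRr"], 1)
  }
})

test_that("feature tables have one row per sample in the fixed column order", {
  empty <- buildFeatureTable(randomSpectraSet(2, 400:900, seed = 1)[, 0])
  expect_equal(nrow(empty), 0)

  ss <- generateDataset(generatorConfig(seed = 2))
  ft <- buildFeatureTable(ss)
  expect_equal(dim(ft), c(382, 18))
  expect_identical(colnames(ft),
                   c("sample_id", "species", "phylum", "dryness",
                     spectralVariables()))
  expect_true(all(vapply(ft[, spectralVariables()], is.numeric, logical(1))))

  # internal consistency: R_g column equals the window scan per sample
  wl <- wavelengths(ss)
  for (i in sample(382, 10)) {
    ext <- findWindowExtremum(wl, reflectance(ss)[, i], 510, 560, "max")
    expect_equal(ft$R_g[i], ext$value)
    expect_equal(ft$L_g[i], ext$location)
  }

  # round-trip through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(ft, path, row.names = FALSE)
  back <- read.csv(path, check.names = FALSE)
  expect_equal(back[, spectralVariables()], ft[, spectralVariables()],
               tolerance = 1e-9)
})
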