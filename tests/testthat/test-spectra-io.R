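test_that("long CSV fixtures round-trip with labels intact", {
  ss <- randomSpectraSet(n = 2, wl = 400:420, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(ss, path, "long")
  back <- readSpectra(path, "long")
  expect_equal(ncol(back), 2)
  expect_identical(speciesLabels(back), speciesLabels(ss))
  expect_identical(drynessStates(back), drynessStates(ss))
  expect_identical(phylumLabels(back), phylumLabels(ss))
  expect_identical(sampleIds(back), sampleIds(ss))
  expect_equal(reflectance(back), reflectance(ss), tolerance = 1e-9)
})

test_that("read(write(X)) == X for both dialects on random sets", {
  for (i in 1:100) {
    ss <- randomSpectraSet(n = sample(1:4, 1), wl = seq(400, 430), seed = i)
    for (dialect in c("long", "wide")) {
      path <- withr::local_tempfile(fileext = ".csv")
      writeSpectra(ss, path, dialect)
      back <- readSpectra(path, dialect)
      expect_equal(reflectance(back), reflectance(ss), tolerance = 1e-9)
      expect_identical(speciesLabels(back), speciesLabels(ss))
      expect_identical(wavelengths(back), wavelengths(ss))
    }
  }
})

test_that("wide CSV with wavelength columns 400..900 yields a 501-point grid", {
  ss <- randomSpectraSet(n = 1, wl = 400:900, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(ss, path, "wide")
  back <- readSpectra(path, "wide")
  expect_length(wavelengths(back), 501)
  # and the long dialect writes one data row per wavelength
  pathL <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(ss, pathL, "long")
  expect_equal(length(readLines(pathL)) - 1L, 501L)
})

test_that("write -> read -> write is byte-identical", {
  ss <- randomSpectraSet(n = 3, wl = 400:450, seed = 7)
  for (dialect in c("long", "wide")) {
    p1 <- withr::local_tempfile(fileext = ".csv")
    p2 <- withr::local_tempfile(fileext = ".csv")
    writeSpectra(ss, p1, dialect)
    writeSpectra(readSpectra(p1, dialect), p2, dialect)
    expect_identical(readLines(p1), readLines(p2))
  }
})

test_that("reader rejects bad labels, bad numbers and empty sets", {
  ss <- randomSpectraSet(n = 2, wl = 400:410, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(ss, path, "long")
  txt <- readLines(path)
  txt2 <- sub(speciesLabels(ss)[1], "Kelpzilla maximus", txt, fixed = TRUE)
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt2, p2)
  expect_error(readSpectra(p2, "long"), "unknown species")
  txt3 <- txt
  txt3[3] <- sub(",[0-9.]+$", ",oops", txt3[3])
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(txt3, p3)
  expect_error(readSpectra(p3, "long"), "non-numeric reflectance at data row 2")
  expect_error(writeSpectra(ss[, 0], path, "long"), "empty")
})

test_that("fractional input is detected and converted", {
  wl <- 400:410
  frac <- matrix(runif(length(wl), 0.1, 0.9), ncol = 1)
  ss <- SpectraSet(frac * 100, wl, "Ulva pertusa", "wet", "a")
  path <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(SpectraSet(frac * 100, wl, "Ulva pertusa", "wet", "a"),
               path, "long")
  # rewrite the file with 0-1 values
  df <- read.csv(path)
  df$reflectance_pct <- df$reflectance_pct / 100
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_error(readSpectra(path, "long"), "fractional")
  back <- readSpectra(path, "long", fractional = TRUE)
  expect_equal(reflectance(back), reflectance(ss), tolerance = 1e-6)
})

test_that("trimming keeps the closed [400, 900] interval and is idempotent", {
  ss <- randomSpectraSet(n = 2, wl = 325:1075, seed = 2)
  tr <- trimWavelengths(ss)
  expect_identical(wavelengths(tr), as.numeric(400:900))
  expect_length(wavelengths(tr), 501)
  expect_identical(speciesLabels(tr), speciesLabels(ss))
  expect_equal(reflectance(trimWavelengths(tr)), reflectance(tr))
  expect_equal(reflectance(trimWavelengths(tr, 400, 900)), reflectance(tr))
  expect_error(trimWavelengths(ss, 500, 450), "empty|range")
})

test_that("replicate averaging is the pointwise mean", {
  wl <- 400:405
  refl <- matrix(rep(c(10, 20, 30, 40, 50, 60), 10), ncol = 10)
  ss <- SpectraSet(refl, wl, species = rep("Ulva pertusa", 10),
                   dryness = rep("wet", 10))
  avg <- averageReplicates(ss)
  expect_equal(ncol(avg), 1)
  expect_equal(as.vector(reflectance(avg)), c(10, 20, 30, 40, 50, 60))
  expect_match(sampleIds(avg), "_n10$")

  two <- SpectraSet(cbind(rep(0, 6), rep(100, 6)), wl,
                    species = rep("Ulva pertusa", 2),
                    dryness = rep("dry", 2))
  expect_equal(as.vector(reflectance(averageReplicates(two))), rep(50, 6))

  vals <- c(3.2, 8.1, 1.7, 9.9, 4.4)
  five <- SpectraSet(matrix(rep(vals, each = 6), 6, 5), wl,
                     species = rep("Chondrus ocellatus", 5),
                     dryness = rep("wet", 5))
  expect_equal(as.vector(reflectance(averageReplicates(five)))[1],
               sum(vals) / 5)
})

test_that("resampling is exact on-grid and matches a piecewise-linear oracle", {
  ss <- randomSpectraSet(n = 2, wl = 400:450, seed = 9)
  expect_equal(reflectance(resampleToGrid(ss)), reflectance(ss))

  two <- SpectraSet(matrix(c(0, 2), 2, 1), c(400, 402), "Ulva pertusa", "wet")
  rs <- resampleToGrid(two)
  expect_equal(as.vector(reflectance(rs)),  c(0, 1, 2))

  set.seed(21)
  wl <- sort(400 + cumsum(runif(60, 0.3, 2.5)))
  v <- runif(length(wl), 5, 60)
  jit <- SpectraSet(matrix(v, ncol = 1), wl, "Grateloupia filicina", "dry")
  rs <- resampleToGrid(jit)
  # brute-force linear interpolation oracle
  oracle <- vapply(wavelengths(rs), function(x) {
    i <- max(which(wl <= x))
    if (wl[i] == x) return(v[i])
    v[i] + (v[i + 1] - v[i]) * (x - wl[i]) / (wl[i + 1] - wl[i])
  }, numeric(1))
  expect_lt(max(abs(as.vector(reflectance(rs)) - oracle)), 1e-9)
})
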