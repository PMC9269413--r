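# Fixtures are built in code; nothing is stored on disk.

# A small random SpectraSet on an integer grid, labels drawn from the
# package vocabulary.
randomSpectraSet <- function(n = 3, wl = seq(400, 420), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  refl <- matrix(runif(length(wl) * n, 2, 90), length(wl), n)
  SpectraSet(refl, wl,
             species = sample(seaweedSpecies(), n, replace = TRUE),
             dryness = sample(c("wet", "moderate", "dry"), n, replace = TRUE),
             sampleIds = sprintf("s%03d", seq_len(n)))
}

# The 8-variable subset retained by the published elimination run.
optimalSubset8 <- function() {
  c("NDVI_RgRr", "RVI_RgRr", "V_re", "A_be", "R_g", "L_re", "L_g", "L_r")
}

# Two well-separated Gaussian blobs as a trivially separable 2-class
# feature table.
separableBlobs <- function(n = 40, d = 2, gap = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n / 2 * d), ncol = d),
             matrix(rnorm(n / 2 * d, mean = gap), ncol = d))
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(d))
  df$species <- rep(c("Ulva pertusa", "Chondrus ocellatus"), each = n / 2)
  df
}

# Small noise-free generator configuration: every sample equals its species
# reference curve (gains 1, all noise off).
noiseFreeConfig <- function(perSpecies = 4, seed = 1) {
  counts <- matrix(perSpecies, 6, 1,
                   dimnames = list(seaweedSpecies(), "moderate"))
  generatorConfig(counts = counts,
                  noise = noiseModel(ampSd = 0, smoothSdPct = 0,
                                     shiftMaxNm = 0),
                  drynessGains = c(wet = 1, moderate = 1, dry = 1),
                  seed = seed)
}
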