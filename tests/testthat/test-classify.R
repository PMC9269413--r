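test_that("stratified splitting respects the 3:1 ratio and the seed", {
  ss <- generateDataset(generatorConfig(seed = 8))
  ft <- buildFeatureTable(ss)
  sp <- splitTrainTest(ft, classColumn = "species", seed = 42)
  # per-class rounding of 0.75 * (64, 64, 64, 64, 63, 63) gives 286 / 96
  expect_equal(nrow(sp$train), 286)
  expect_equal(nrow(sp$test), 96)
  perClass <- table(sp$train$species)
  expect_true(all(perClass %in% c(47, 48)))

  sp2 <- splitTrainTest(ft, classColumn = "species", seed = 42)
  expect_identical(sp$train$sample_id, sp2$train$sample_id)

  tiny <- ft[c(1, 2, 100, 101), ]
  spt <- splitTrainTest(tiny, trainFraction = 0.5, seed = 1)
  expect_equal(as.integer(table(spt$train$species)), c(1L, 1L))
  expect_equal(as.integer(table(spt$test$species)), c(1L, 1L))

  expect_error(splitTrainTest(ft[c(1, 100, 101), ], seed = 1),
               "at least 2 samples")
})

test_that("grid search is exhaustive, tie-broken low, and refits cleanly", {
  blobs <- separableBlobs(n = 40, seed = 30)
  m <- gridSearchSvm(blobs, c("f1", "f2"), gValues = c(0.5, 1, 2),
                     cValues = c(0.5, 1, 2), folds = 4, seed = 1)
  # trivially separable: every grid point reaches 100% CV accuracy,
  # so the tie rule picks the smallest cost then the smallest width
  expect_true(all(m$cvSurface$accuracy == 100))
  expect_equal(m$c, 0.5)
  expect_equal(m$g, 0.5)
  expect_true(m$g %in% c(0.5, 1, 2) && m$c %in% c(0.5, 1, 2))
  expect_equal(nrow(m$cvSurface), 9)

  # a 1x1 grid equals a direct single fit
  m1 <- gridSearchSvm(blobs, c("f1", "f2"), gValues = 1, cValues = 1,
                      folds = 4, seed = 1)
  st <- list(center = colMeans(blobs[, 1:2]),
             scale = apply(blobs[, 1:2], 2, sd))
  Xs <- scale(as.matrix(blobs[, 1:2]), st$center, st$scale)
  direct <- e1071::svm(Xs, factor(blobs$species), kernel = "radial",
                       gamma = 1, cost = 1, scale = FALSE)
  expect_identical(
    as.character(predictModel(m1, blobs)$labels),
    as.character(predict(direct, Xs)))
})

test_that("predictions are valid probabilities and order-equivariant", {
  blobs <- separableBlobs(n = 60, d = 3, seed = 31)
  m <- gridSearchSvm(blobs, c("f1", "f2", "f3"), gValues = 1, cValues = 1,
                     folds = 4, seed = 2)
  set.seed(32)
  newX <- as.data.frame(matrix(rnorm(100 * 3, 5), ncol = 3))
  names(newX) <- c("f1", "f2", "f3")
  pr <- predictModel(m, newX)
  expect_lt(max(abs(rowSums(pr$probabilities) - 1)), 1e-6)
  expect_equal(nrow(pr$probabilities), 100)

  # extra unused columns do not change predictions
  withJunk <- cbind(newX, junk = rnorm(100))
  expect_identical(predictModel(m, withJunk)$probabilities,
                   pr$probabilities)

  # permuting rows permutes outputs identically
  perm <- sample(100)
  prP <- predictModel(m, newX[perm, ])
  expect_equal(unname(prP$probabilities), unname(pr$probabilities[perm, ]))

  expect_error(predictModel(m, newX[, 1:2]), "missing feature")
})

test_that("fusion soft-voting is deterministic and fits separable data", {
  ss <- generateDataset(noiseFreeConfig(perSpecies = 8))
  ft <- suppressMessages(buildFeatureTable(ss))
  feats <- setdiff(spectralVariables(), c("NDVI_AreAbe", "RVI_AreAbe"))
  fu <- trainFusion(ft, feats, g = 1, c = 1, seed = 5)
  pr <- predictModel(fu, ft)
  # noise-free species are separable by construction: training accuracy 100%
  expect_equal(as.character(pr$labels), ft$species)
  expect_lt(max(abs(rowSums(pr$probabilities) - 1)), 1e-6)

  fu2 <- trainFusion(ft, feats, g = 1, c = 1, seed = 5)
  expect_identical(predictModel(fu2, ft)$probabilities, pr$probabilities)
})

test_that("when both members agree the fusion vote returns their label", {
  blobs <- separableBlobs(n = 40, seed = 33)
  m <- gridSearchSvm(blobs, c("f1", "f2"), gValues = 1, cValues = 1,
                     folds = 4, seed = 1)
  fu <- trainFusion(blobs, c("f1", "f2"), g = 1, c = 1, seed = 1)
  svmLab <- as.character(predictModel(m, blobs)$labels)
  fuLab <- as.character(predictModel(fu, blobs)$labels)
  # on trivially separable data both members agree everywhere
  expect_identical(fuLab, svmLab)
  expect_identical(svmLab, blobs$species)
})

test_that("standardization statistics come from training data only", {
  blobs <- separableBlobs(n = 40, seed = 34)
  m <- gridSearchSvm(blobs, c("f1", "f2"), gValues = 1, cValues = 1,
                     folds = 4, seed = 1)
  expect_equal(m$center, colMeans(as.matrix(blobs[, 1:2])))
  # predictions for a row do not depend on what else is in the test batch
  one <- blobs[1, ]
  batch <- rbind(one, transform(blobs[2:10, ], f1 = f1 + 1000))
  expect_equal(predictModel(m, one)$probabilities[1, ],
               predictModel(m, batch)$probabilities[1, ])
})

test_that("the phylum task is easier than the species task", {
  sub8 <- optimalSubset8()
  wins <- 0L
  for (s in 1:20) {
    ss <- generateDataset(generatorConfig(seed = s))
    ft <- buildFeatureTable(ss)
    acc <- vapply(c("species", "phylum"), function(lv) {
      sp <- splitTrainTest(ft, classColumn = lv, seed = s + 100)
      m <- gridSearchSvm(sp$train, sub8, classColumn = lv,
                         gValues = 1, cValues = 1, folds = 4, seed = s + 200)
      pr <- predictModel(m, sp$test)
      overallAccuracy(confusionMatrix(sp$test[[lv]], pr$labels, m$levels))
    }, numeric(1))
    if (acc["phylum"] >= acc["species"]) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})
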