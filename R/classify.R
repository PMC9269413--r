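# Classification: stratified train/test split, RBF-SVM with exhaustive
# (g, c) grid search under k-fold cross-validation, and a soft-voting fusion
# of the SVM with a gradient-boosted tree classifier.

#' Stratified train/test split
#'
#' Splits a feature table into training and test sets at `trainFraction`
#' (default 3:1), stratified by class so each class contributes its share
#' within one sample of `trainFraction * n`. Reproducible from `seed`.
#'
#' @param featureTable data.frame from [buildFeatureTable()].
#' @param trainFraction fraction of each class assigned to training
#'   (0 < fraction < 1, default 0.75).
#' @param classColumn label column to stratify by (default `"species"`).
#' @param seed integer RNG seed.
#' @return list with `train` and `test` data.frames.
#' @export
splitTrainTest <- function(featureTable, trainFraction = 0.75,
                           classColumn = "species", seed = 1) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  cls <- factor(featureTable[[classColumn]])
  if (any(table(cls) < 2))
    .stopf("every class needs at least 2 samples to split")
  .withSeed(seed, {
    trainIdx <- integer()
    for (lv in levels(cls)) {
      idx <- which(cls == lv)
      k <- round(length(idx) * trainFraction)
      k <- min(max(k, 1L), length(idx) - 1L)
      trainIdx <- c(trainIdx, sample(idx, k))
    }
    trainIdx <- sort(trainIdx)
    list(train = featureTable[trainIdx, , drop = FALSE],
         test = featureTable[-trainIdx, , drop = FALSE])
  })
}

# Standardize a numeric matrix with training statistics; zero-sd columns get
# sd 1 so constants pass through unchanged.
.standardize <- function(X, center, scale) {
  sweep(sweep(X, 2, center), 2, scale, "/")
}

.trainStats <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

# Seeded stratified fold assignment.
.foldAssign <- function(y, folds, seed) {
  .withSeed(seed, {
    f <- integer(length(y))
    for (lv in levels(y)) {
      idx <- sample(which(y == lv))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
}

# Deterministic class scores from a fitted e1071 SVM: one-vs-one decision
# values are aggregated per class and passed through a softmax. (The libsvm
# Platt-scaling probabilities are not reproducible run-to-run, so the package
# defines its probability scale this way; see the methods vignette.)
.svmScores <- function(fit, X, levels) {
  pr <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  scores <- matrix(0, nrow(X), length(levels),
                   dimnames = list(NULL, levels))
  for (j in seq_len(ncol(dv))) {
    ab <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1]]
    scores[, ab[1]] <- scores[, ab[1]] + dv[, j]
    scores[, ab[2]] <- scores[, ab[2]] - dv[, j]
  }
  e <- exp(scores - apply(scores, 1, max))
  e / rowSums(e)
}

#' Grid search for the RBF-kernel SVM
#'
#' Exhaustively evaluates mean cross-validated accuracy over a grid of RBF
#' kernel widths `g` and soft-margin penalties `c`, picks the maximum (ties
#' resolved toward the smallest `c`, then the smallest `g`), and refits on the
#' full training set. Features are standardized with training statistics;
#' the same statistics are applied at prediction time. Multiclass handling is
#' libsvm's pairwise (one-vs-one) decomposition.
#'
#' The default grid spans 0.05--10.0 in steps of 0.25 for both parameters;
#' `fineGrid()` gives the 0.05-step version.
#'
#' @param train training data.frame (labels + feature columns).
#' @param features character vector of feature columns to use.
#' @param classColumn label column (default `"species"`).
#' @param gValues,cValues numeric grids for the kernel width and penalty.
#' @param folds number of cross-validation folds (default 4).
#' @param seed integer seed for the fold assignment.
#' @return list of class `"TrainedModel"` with elements `kind = "svm"`,
#'   `g`, `c`, `cvAccuracy`, `cvSurface` (data.frame g, c, accuracy),
#'   `features`, `classColumn`, `levels`, `center`, `scale`, `fit`.
#' @export
gridSearchSvm <- function(train, features, classColumn = "species",
                          gValues = coarseGrid(), cValues = coarseGrid(),
                          folds = 4, seed = 1) {
  stopifnot(all(gValues > 0), all(cValues > 0), folds >= 2)
  dat <- .modelFrame(train, features, classColumn)
  y <- dat$y; X <- dat$X
  if (nlevels(y) < 2) .stopf("training data contain a single class")
  if (any(table(y) < folds))
    .stopf("every class needs at least %d samples for %d-fold CV",
           folds, folds)
  st <- .trainStats(X)
  Xs <- .standardize(X, st$center, st$scale)
  fold <- .foldAssign(y, folds, seed)
  surface <- expand.grid(g = gValues, c = cValues)
  folded <- lapply(seq_len(folds), function(k) {
    list(tr = which(fold != k), te = which(fold == k))
  })
  acc <- vapply(seq_len(nrow(surface)), function(i) {
    gg <- surface$g[i]; cc <- surface$c[i]
    hits <- 0L
    for (fk in folded) {
      fit <- e1071::svm(Xs[fk$tr, , drop = FALSE], y[fk$tr],
                        kernel = "radial", gamma = gg, cost = cc,
                        scale = FALSE)
      hits <- hits + sum(stats::predict(fit, Xs[fk$te, , drop = FALSE]) ==
                           y[fk$te])
    }
    100 * hits / length(y)
  }, numeric(1))
  surface$accuracy <- acc
  best <- surface[order(-surface$accuracy, surface$c, surface$g), ][1, ]
  fit <- e1071::svm(Xs, y, kernel = "radial", gamma = best$g, cost = best$c,
                    scale = FALSE)
  structure(list(kind = "svm", g = best$g, c = best$c,
                 cvAccuracy = best$accuracy, cvSurface = surface,
                 features = features, classColumn = classColumn,
                 levels = levels(y), center = st$center, scale = st$scale,
                 fit = fit),
            class = "TrainedModel")
}

#' @rdname gridSearchSvm
#' @export
coarseGrid <- function() seq(0.05, 10, by = 0.25)

#' @rdname gridSearchSvm
#' @export
fineGrid <- function() seq(0.05, 10, by = 0.05)

.modelFrame <- function(df, features, classColumn) {
  miss <- setdiff(c(features, classColumn), colnames(df))
  if (length(miss))
    .stopf("missing column(s): %s", paste(miss, collapse = ", "))
  X <- as.matrix(df[, features, drop = FALSE])
  ok <- stats::complete.cases(X)
  if (!all(ok))
    warning(sum(!ok), " sample(s) with undefined features excluded",
            call. = FALSE)
  list(X = X[ok, , drop = FALSE],
       y = droplevels(factor(df[[classColumn]][ok])))
}

#' Soft-voting fusion of SVM and gradient boosting
#'
#' Trains (a) an RBF-SVM at the supplied `(g, c)` and (b) a gradient-boosted
#' tree classifier with fixed defaults (300 trees, depth 3, learning rate 0.1)
#' on the same standardized features, and combines them by soft voting: the
#' ensemble class probability is the unweighted mean of the two members'
#' probabilities, and the predicted label is its argmax. (With only two
#' voters, hard majority voting cannot break disagreements, hence soft
#' voting.)
#'
#' @inheritParams gridSearchSvm
#' @param g,c RBF-SVM parameters, typically from [gridSearchSvm()].
#' @param nrounds,maxDepth,eta gradient-boosting hyperparameters (fixed
#'   defaults, not tuned).
#' @param seed integer seed for the boosting member.
#' @return list of class `"TrainedModel"` with `kind = "fusion"`.
#' @export
trainFusion <- function(train, features, g, c, classColumn = "species",
                        nrounds = 300, maxDepth = 3, eta = 0.1, seed = 1) {
  dat <- .modelFrame(train, features, classColumn)
  y <- dat$y; X <- dat$X
  if (nlevels(y) < 2) .stopf("training data contain a single class")
  st <- .trainStats(X)
  Xs <- .standardize(X, st$center, st$scale)
  svmFit <- e1071::svm(Xs, y, kernel = "radial", gamma = g, cost = c,
                       scale = FALSE)
  xgbFit <- .withSeed(seed, {
    xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = nlevels(y), max_depth = maxDepth,
                    eta = eta, nthread = 1, seed = as.integer(seed)),
      data = xgboost::xgb.DMatrix(Xs, label = as.integer(y) - 1L,
                                  nthread = 1),
      nrounds = nrounds, verbose = 0)
  })
  structure(list(kind = "fusion", g = g, c = c, features = features,
                 classColumn = classColumn, levels = levels(y),
                 center = st$center, scale = st$scale,
                 fit = svmFit, xgbFit = xgbFit),
            class = "TrainedModel")
}

#' Predict labels and class probabilities
#'
#' Applies a trained model to new samples. Features are standardized with the
#' statistics stored at training time (never refit on test data). Probability
#' rows sum to 1; the label is the argmax, ties broken toward the smallest
#' class index. Extra columns in `newdata` are ignored.
#'
#' @param model a `"TrainedModel"` from [gridSearchSvm()] or [trainFusion()].
#' @param newdata data.frame containing at least the model's feature columns.
#' @return list with `labels` (factor over the model's label space) and
#'   `probabilities` (samples x classes matrix).
#' @export
predictModel <- function(model, newdata) {
  stopifnot(inherits(model, "TrainedModel"))
  miss <- setdiff(model$features, colnames(newdata))
  if (length(miss))
    .stopf("newdata is missing feature column(s): %s",
           paste(miss, collapse = ", "))
  X <- as.matrix(newdata[, model$features, drop = FALSE])
  Xs <- .standardize(X, model$center, model$scale)
  prob <- .svmScores(model$fit, Xs, model$levels)
  if (model$kind == "fusion") {
    xp <- stats::predict(model$xgbFit, xgboost::xgb.DMatrix(Xs, nthread = 1))
    xp <- matrix(xp, nrow = nrow(Xs), byrow = is.null(dim(xp)))
    if (!is.null(dim(xp)) && ncol(xp) != length(model$levels))
      xp <- matrix(as.numeric(xp), nrow = nrow(Xs), byrow = TRUE)
    colnames(xp) <- model$levels
    prob <- (prob + xp) / 2
  }
  labels <- factor(model$levels[max.col(prob, ties.method = "first")],
                   levels = model$levels)
  list(labels = labels, probabilities = prob)
}
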