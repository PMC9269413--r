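# Evaluation: confusion matrix, overall accuracy, one-vs-rest ROC with
# micro/macro averaging, and the per-class first-principal-component
# representation of spectra.

#' Confusion matrix
#'
#' Counts of (true, predicted) label pairs in a fixed label order: rows are
#' true labels, columns predictions.
#'
#' @param yTrue,yPred vectors of equal length.
#' @param levels label order; defaults to the sorted union of observed labels.
#' @return integer matrix with dimnames `true` x `predicted`.
#' @export
confusionMatrix <- function(yTrue, yPred, levels = NULL) {
  if (length(yTrue) != length(yPred))
    .stopf("yTrue and yPred must have equal length")
  if (is.null(levels))
    levels <- sort(unique(c(as.character(yTrue), as.character(yPred))))
  bad <- setdiff(unique(c(as.character(yTrue), as.character(yPred))), levels)
  if (length(bad))
    .stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  tt <- table(factor(yTrue, levels = levels),
              factor(yPred, levels = levels))
  m <- matrix(as.integer(tt), nrow(tt), ncol(tt),
              dimnames = list(true = levels, predicted = levels))
  m
}

#' Overall accuracy from a confusion matrix
#'
#' The standard multiclass overall accuracy, (TP + TN) / total under
#' one-vs-rest marginalization, which for a confusion matrix equals
#' `100 * trace / total` percent.
#'
#' @param cm square count matrix from [confusionMatrix()].
#' @return accuracy in percent.
#' @export
overallAccuracy <- function(cm) {
  if (sum(cm) == 0) .stopf("empty confusion matrix")
  100 * sum(diag(cm)) / sum(cm)
}

# Binary ROC via pROC, returned as increasing-FPR curve with (0,0) and (1,1).
.binaryRoc <- function(truth01, score) {
  r <- pROC::roc(response = truth01, predictor = score, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  fpr <- 1 - r$specificities
  tpr <- r$sensitivities
  o <- order(fpr, tpr)
  list(fpr = fpr[o], tpr = tpr[o], auc = as.numeric(r$auc))
}

#' One-vs-rest ROC with micro and macro averaging
#'
#' Per class, the one-vs-rest ROC is computed by threshold sweep on that
#' class's probability column. The micro-averaged curve pools all
#' (sample, class) indicator/score pairs into one binary problem, weighting
#' every sample equally. The macro-averaged curve averages the per-class
#' curves: each class's TPR is linearly interpolated onto the pooled FPR grid
#' and averaged, weighting every class equally; its AUC is the trapezoid-rule
#' area. Classes absent from `yTrue` are excluded from the macro average with
#' a warning.
#'
#' @param yTrue vector of true labels.
#' @param probMatrix samples x classes probability matrix with class column
#'   names; rows must sum to 1 (tolerance 1e-6).
#' @return list of class `"ROCReport"`: `perClass` (named list of
#'   `fpr`/`tpr`/`auc`), `micro`, `macro`.
#' @export
rocCurves <- function(yTrue, probMatrix) {
  probMatrix <- as.matrix(probMatrix)
  if (is.null(colnames(probMatrix)))
    .stopf("probMatrix needs class column names")
  if (length(yTrue) != nrow(probMatrix))
    .stopf("yTrue and probMatrix sizes disagree")
  if (max(abs(rowSums(probMatrix) - 1)) > 1e-6)
    .stopf("probability rows must sum to 1")
  classes <- colnames(probMatrix)
  present <- classes[classes %in% as.character(yTrue)]
  absent <- setdiff(classes, present)
  if (length(absent))
    warning("class(es) absent from yTrue excluded from ROC: ",
            paste(absent, collapse = ", "), call. = FALSE)
  perClass <- lapply(present, function(cl)
    .binaryRoc(as.integer(as.character(yTrue) == cl), probMatrix[, cl]))
  names(perClass) <- present
  indicator <- vapply(present, function(cl)
    as.integer(as.character(yTrue) == cl), integer(length(yTrue)))
  micro <- .binaryRoc(as.vector(indicator),
                      as.vector(probMatrix[, present, drop = FALSE]))
  grid <- sort(unique(c(0, unlist(lapply(perClass, `[[`, "fpr")), 1)))
  tprAvg <- rowMeans(vapply(perClass, function(pc)
    stats::approx(pc$fpr, pc$tpr, xout = grid, ties = "ordered",
                  rule = 2)$y, numeric(length(grid))))
  macroAuc <- sum(diff(grid) * (utils::head(tprAvg, -1) +
                                  utils::tail(tprAvg, -1)) / 2)
  structure(list(perClass = perClass, micro = micro,
                 macro = list(fpr = grid, tpr = tprAvg, auc = macroAuc)),
            class = "ROCReport")
}

#' First principal component of one class's spectra
#'
#' PCA of the class's samples-by-wavelengths reflectance matrix
#' (column-mean-centered, unscaled). Returns the first principal axis over
#' wavelengths -- sign fixed so its mean is non-negative, making curves
#' comparable across runs -- and the percentage of total spectral variance it
#' explains. Values above 90% indicate the class's spectra vary essentially
#' along a single shape, so the first component represents the class well.
#'
#' @param x a [SpectraSet-class].
#' @param className class value to select.
#' @param classColumn label column to match (default `"species"`).
#' @return list with `pc1` (numeric over wavelengths), `explainedVariance`
#'   (percent) and `className`.
#' @export
pcaClassRepresentation <- function(x, className, classColumn = "species") {
  stopifnot(is(x, "SpectraSet"))
  sel <- as.character(colData(x)[[classColumn]]) == className
  if (sum(sel) < 3)
    .stopf("need at least 3 samples of class '%s' (found %d)",
           className, sum(sel))
  X <- t(reflectance(x)[, sel, drop = FALSE])
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- 100 * p$sdev[1]^2 / sum(p$sdev^2)
  pc1 <- p$rotation[, 1]
  if (mean(pc1) < 0) pc1 <- -pc1
  list(pc1 = unname(pc1), explainedVariance = ev, className = className)
}
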