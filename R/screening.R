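# Variable screening: one-way ANOVA and Tukey HSD star counts per variable,
# then accuracy-driven backward elimination over the resulting ranking.

#' One-way ANOVA for a single variable
#'
#' Classical one-way analysis of variance of `values` across the groups in
#' `groups`. Degenerate inputs are handled explicitly: if every value is
#' identical the test is uninformative and `p = 1` is reported with a
#' zero-variance flag; if groups are internally constant but differ in mean,
#' `F = Inf`, `p = 0` (flagged).
#'
#' @param values numeric vector.
#' @param groups factor or character of the same length, at least 2 groups
#'   with at least 2 values each.
#' @return list with `statistic` (F), `p.value`, and `zeroVariance` flag.
#' @export
anovaOneway <- function(values, groups) {
  groups <- factor(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) .stopf("need at least 2 groups")
  if (any(table(groups) < 2)) .stopf("each group needs at least 2 values")
  if (all(values == values[1]))
    return(list(statistic = 0, p.value = 1, zeroVariance = TRUE))
  withinVar <- tapply(values, groups, stats::var)
  if (all(withinVar == 0))
    return(list(statistic = Inf, p.value = 0, zeroVariance = TRUE))
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p.value = unname(ft$p.value),
       zeroVariance = FALSE)
}

#' Tukey HSD star count
#'
#' Runs Tukey's honestly-significant-difference test on all group pairs after
#' a one-way ANOVA fit and counts the significant pairs ("stars",
#' p <= `alpha`). With zero pooled variance the studentized range is
#' undefined; pairs with distinct means are then counted significant and the
#' result is flagged.
#'
#' @inheritParams anovaOneway
#' @param alpha familywise significance level (default 0.05).
#' @return list with `starCount`, `pairwiseP` (named vector over the
#'   `choose(k, 2)` pairs) and `flagged`.
#' @export
tukeyStarCount <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) .stopf("need at least 2 groups")
  means <- tapply(values, groups, mean)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  pairNames <- paste(pairs[2, ], pairs[1, ], sep = "-")
  withinVar <- tapply(values, groups, stats::var)
  if (all(is.na(withinVar) | withinVar == 0)) {
    distinct <- means[pairs[2, ]] != means[pairs[1, ]]
    p <- ifelse(distinct, 0, 1)
    names(p) <- pairNames
    return(list(starCount = sum(distinct), pairwiseP = p, flagged = TRUE))
  }
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  p <- tk[, "p adj"]
  names(p) <- rownames(tk)
  list(starCount = sum(p <= alpha, na.rm = TRUE), pairwiseP = p,
       flagged = FALSE)
}

#' Rank spectral variables by Tukey star count
#'
#' For each of the 14 variables, runs one-way ANOVA across the classes and
#' Tukey's post hoc test over all class pairs; variables are ranked by the
#' number of significantly different pairs (descending). Ties are broken by a
#' fixed reference ordering -- the conventional significance order of these
#' variables as returned by [spectralVariables()] -- so the ranking is
#' deterministic.
#'
#' Missing feature values are dropped per variable (pairwise complete) with a
#' message giving the count.
#'
#' @param featureTable data.frame from [buildFeatureTable()].
#' @param classColumn label column defining the groups (default `"species"`).
#' @param alpha significance level for a "star" (default 0.05).
#' @return data.frame of class `"VariableRanking"`: columns `variable`,
#'   `starCount`, `anovaP`, `rank`, ordered by rank; attribute `pairwiseP`
#'   holds the per-variable named p-value vectors.
#' @export
rankVariables <- function(featureTable, classColumn = "species",
                          alpha = 0.05) {
  vars <- intersect(.FEATURES, colnames(featureTable))
  if (!length(vars)) .stopf("no spectral variable columns found")
  groups <- featureTable[[classColumn]]
  res <- lapply(vars, function(v) {
    vals <- featureTable[[v]]
    nmiss <- sum(!is.finite(vals))
    if (nmiss > 0)
      message("variable ", v, ": dropping ", nmiss, " missing value(s)")
    an <- anovaOneway(vals, groups)
    tk <- tukeyStarCount(vals, groups, alpha = alpha)
    list(star = tk$starCount, p = an$p.value, pw = tk$pairwiseP)
  })
  out <- data.frame(variable = vars,
                    starCount = vapply(res, `[[`, numeric(1), "star"),
                    anovaP = vapply(res, `[[`, numeric(1), "p"))
  # descending star count; ties follow the fixed reference order, which is
  # the order of `vars` itself
  out <- out[order(-out$starCount, match(out$variable, .FEATURES)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "pairwiseP") <- stats::setNames(lapply(res, `[[`, "pw"), vars)
  attr(out, "alpha") <- alpha
  attr(out, "nPairs") <- choose(nlevels(factor(groups)), 2)
  class(out) <- c("VariableRanking", "data.frame")
  out
}

#' Backward elimination over a variable ranking
#'
#' Starting from the full variable set ordered by `ranking`, repeatedly
#' removes the lowest-ranked (least significant) remaining variable,
#' re-evaluating classification accuracy after each removal, down to a single
#' variable. Returns the full elimination trace and the best subset: maximum
#' accuracy, with ties resolved toward the larger subset (prefer keeping
#' variables when accuracy is equal). An evaluator failure on some subset is
#' recorded as `NA` and elimination continues.
#'
#' @param ranking a `"VariableRanking"` from [rankVariables()], or a character
#'   vector of variable names in descending significance order.
#' @param evaluator function taking a character vector of variable names and
#'   returning a single accuracy in percent; must be deterministic given its
#'   own seeding.
#' @return list of class `"EliminationTrace"`: `trace` (data.frame with
#'   `remainingCount`, `removedVariables`, `accuracy`), `bestSubset`
#'   (character), `bestAccuracy`.
#' @export
backwardEliminate <- function(ranking, evaluator) {
  vars <- if (inherits(ranking, "VariableRanking")) ranking$variable
          else as.character(ranking)
  if (!length(vars)) .stopf("empty ranking")
  evalSafe <- function(subset) {
    tryCatch(as.numeric(evaluator(subset)), error = function(e) {
      warning("evaluator failed on subset of size ", length(subset), ": ",
              conditionMessage(e), call. = FALSE)
      NA_real_
    })
  }
  sizes <- seq(length(vars), 1)
  trace <- data.frame(remainingCount = sizes,
                      removedVariables = NA_character_,
                      accuracy = NA_real_)
  subsets <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    keep <- vars[seq_len(sizes[i])]
    subsets[[i]] <- keep
    trace$removedVariables[i] <-
      paste(setdiff(vars, keep), collapse = ", ")
    trace$accuracy[i] <- evalSafe(keep)
  }
  if (all(is.na(trace$accuracy)))
    .stopf("evaluator failed on every subset")
  best <- which(trace$accuracy == max(trace$accuracy, na.rm = TRUE))[1]
  structure(list(trace = trace, bestSubset = subsets[[best]],
                 bestAccuracy = trace$accuracy[best]),
            class = "EliminationTrace")
}
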