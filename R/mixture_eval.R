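## In silico mixture evaluation: quality filtering, selection scores, ROC
## curves, rare-mixture precision-recall reweighting, confusion matrices and
## operating points.
##
## The central idea: a classifier's TPR/FPR at a threshold are properties of
## the class-conditional score distributions, so the precision expected in a
## mixture with target proportion pi follows by Bayes reweighting,
##   precision(t) = pi * TPR(t) / (pi * TPR(t) + (1 - pi) * FPR(t)),
## without physically subsampling 1:100,000 mixtures.

#' Drop quality-class cells before measuring performance
#'
#' Out-of-focus and debris images are removed from a validation cohort before
#' any performance statistic is computed; they report on sample quality, not
#' on classification.
#'
#' @param cohort A [CellCohort-class].
#' @param qualityClasses Character vector of quality class names; must be
#'   known classes of the cohort.
#' @return The filtered [CellCohort-class]; order preserved, input untouched.
#' @export
filterEvaluable <- function(cohort, qualityClasses = c("debris", "out_of_focus")) {
  stopifnot(is(cohort, "CellCohort"))
  unknown <- setdiff(qualityClasses, classNames(cohort))
  if (length(unknown)) {
    stop("quality classes not among cohort classes: ",
         paste(unknown, collapse = ", "))
  }
  cohort[!(trueLabels(cohort) %in% qualityClasses)]
}

#' Per-cell selection scores for positive or negative gating
#'
#' Positive selection scores a cell by its target-class softmax output;
#' negative selection scores it by one minus the largest background-class
#' output. In both modes a higher score means "more likely sorted".
#'
#' @param cohort A [CellCohort-class].
#' @param mode `"positive"` or `"negative"`.
#' @param targetClass Target class name.
#' @param backgroundClasses Background class names (negative mode); defaults
#'   to all non-target classes. Must not overlap the target.
#' @return Numeric vector, one score per cell.
#' @export
selectionScores <- function(cohort, mode = c("positive", "negative"),
                            targetClass,
                            backgroundClasses = setdiff(classNames(cohort),
                                                        targetClass)) {
  stopifnot(is(cohort, "CellCohort"))
  mode <- match.arg(mode)
  cls <- classNames(cohort)
  if (!targetClass %in% cls) stop("unknown target class: ", targetClass)
  if (!all(backgroundClasses %in% cls)) {
    stop("unknown background class(es)")
  }
  if (targetClass %in% backgroundClasses) {
    stop("target and background class sets overlap")
  }
  s <- scoreMatrix(cohort)
  if (mode == "positive") {
    unname(s[, targetClass])
  } else {
    b <- s[, backgroundClasses, drop = FALSE]
    if (nrow(b) == 0L) return(numeric())
    1 - apply(b, 1L, max)
  }
}

#' Empirical ROC curve from target and background scores
#'
#' Sweeps all distinct score values as thresholds (descending, starting at
#' Inf so the curve begins at (0,0)); tied scores move between thresholds as
#' a block. The AUC is the trapezoidal integral of TPR over FPR, which for a
#' tie-grouped curve equals the Mann-Whitney pair-ordering statistic with
#' half credit for ties.
#'
#' @param targetScores,backgroundScores Non-empty numeric score vectors.
#' @return A [ROCCurve-class].
#' @examples
#' rocCurve(c(0.9, 0.4), c(0.6, 0.1))
#' @export
rocCurve <- function(targetScores, backgroundScores) {
  if (length(targetScores) == 0L || length(backgroundScores) == 0L) {
    stop("both score vectors must be non-empty")
  }
  scores <- c(targetScores, backgroundScores)
  isT <- rep(c(TRUE, FALSE), c(length(targetScores), length(backgroundScores)))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  isT <- isT[o]
  cumT <- cumsum(isT)
  cumF <- cumsum(!isT)
  lastOfGroup <- !duplicated(s, fromLast = TRUE)
  thr <- c(Inf, s[lastOfGroup])
  tpr <- c(0, cumT[lastOfGroup] / length(targetScores))
  fpr <- c(0, cumF[lastOfGroup] / length(backgroundScores))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  new("ROCCurve", thresholds = thr, tpr = tpr, fpr = fpr, auc = auc)
}

#' Reweight a ROC curve to a rare-mixture precision-recall curve
#'
#' For a mixture with target proportion `pi`, precision at a threshold t is
#' `pi * TPR(t) / (pi * TPR(t) + (1 - pi) * FPR(t))` and recall equals
#' TPR(t). At the degenerate all-negative threshold (TPR = FPR = 0) precision
#' is defined as 1 by convention.
#'
#' @param roc A [ROCCurve-class].
#' @param pi Target proportion in (0, 1).
#' @return A [PRCurve-class].
#' @export
mixturePRCurve <- function(roc, pi) {
  stopifnot(is(roc, "ROCCurve"))
  checkFraction(pi, "pi", openLower = TRUE, openUpper = TRUE)
  num <- pi * roc@tpr
  den <- num + (1 - pi) * roc@fpr
  precision <- ifelse(den == 0, 1, num / den)
  new("PRCurve", thresholds = roc@thresholds, precision = precision,
      recall = roc@tpr, fpr = roc@fpr, mixturePi = pi)
}

#' Empirical precision-recall curve of an explicit mixture
#'
#' Direct counting on a physically constructed (or resampled) mixture:
#' at each threshold, precision = collected targets / all collected and
#' recall = collected targets / all targets. This is the cross-validation
#' route for [mixturePRCurve()].
#'
#' @param scores Numeric selection scores of the mixed cohort.
#' @param isTarget Logical vector, TRUE for target cells.
#' @param pi Target proportion recorded on the curve (defaults to the
#'   empirical fraction).
#' @return A [PRCurve-class].
#' @export
empiricalPRCurve <- function(scores, isTarget, pi = mean(isTarget)) {
  stopifnot(length(scores) == length(isTarget), any(isTarget), any(!isTarget))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  t <- isTarget[o]
  cumT <- cumsum(t)
  cumAll <- seq_along(s)
  lastOfGroup <- !duplicated(s, fromLast = TRUE)
  thr <- c(Inf, s[lastOfGroup])
  precision <- c(1, (cumT / cumAll)[lastOfGroup])
  recall <- c(0, cumT[lastOfGroup] / sum(t))
  fpr <- c(0, ((cumAll - cumT) / sum(!t))[lastOfGroup])
  new("PRCurve", thresholds = thr, precision = precision, recall = recall,
      fpr = fpr, mixturePi = pi)
}

#' Resample pure score pools into an explicit mixture
#'
#' Builds a mixture of `n` cells at target proportion `pi` by sampling with
#' replacement from pure target and background score pools, resampling the
#' background to exactly (1 - pi)/pi cells per target — the brute-force
#' counterpart of analytic reweighting, for cross-validation.
#'
#' @param targetScores,backgroundScores Pure score pools.
#' @param pi Target proportion in (0, 1).
#' @param n Mixture size.
#' @param seed Integer seed.
#' @return List with `scores` and logical `isTarget`.
#' @export
resampleMixture <- function(targetScores, backgroundScores, pi, n, seed) {
  checkFraction(pi, "pi", openLower = TRUE, openUpper = TRUE)
  withSeed(seed, {
    nT <- max(1L, round(n * pi))
    sc <- c(sample(targetScores, nT, replace = TRUE),
            sample(backgroundScores, n - nT, replace = TRUE))
    list(scores = sc, isTarget = rep(c(TRUE, FALSE), c(nT, n - nT)))
  })
}

#' Confusion matrix of argmax predictions
#'
#' Quality-class cells are filtered out first; rows are ground truth and
#' columns the argmax prediction. Argmax ties are broken deterministically by
#' class-name sort order.
#'
#' @param cohort A [CellCohort-class].
#' @param qualityClasses Quality classes removed before counting.
#' @return A [ConfusionMatrix-class] over the evaluable classes.
#' @export
confusionCounts <- function(cohort, qualityClasses = c("debris", "out_of_focus")) {
  stopifnot(is(cohort, "CellCohort"))
  keep <- filterEvaluable(cohort, intersect(qualityClasses, classNames(cohort)))
  if (nCells(keep) == 0L) {
    stop("no evaluable cells remain after quality filtering")
  }
  cls <- classNames(keep)
  s <- scoreMatrix(keep)
  ## tie-break by class-name sort order: scan columns alphabetically,
  ## max.col(ties.method = "first") then takes the alphabetically first
  alpha <- sort(cls)
  pred <- alpha[max.col(s[, alpha, drop = FALSE], ties.method = "first")]
  counts <- table(factor(trueLabels(keep), levels = cls),
                  factor(pred, levels = cls))
  counts <- matrix(as.integer(counts), nrow = length(cls),
                   dimnames = list(truth = cls, prediction = cls))
  rs <- rowSums(counts)
  fractions <- counts / ifelse(rs == 0, NA_real_, rs)
  new("ConfusionMatrix", classNames = cls, counts = counts,
      fractions = fractions)
}

#' Maximal-recall operating point at a precision floor
#'
#' Returns the threshold with the largest recall among those whose precision
#' meets `minPrecision`; when no threshold qualifies the result is flagged
#' unattainable rather than raising an error.
#'
#' @param pr A [PRCurve-class].
#' @param minPrecision Required precision in (0, 1].
#' @return An [OperatingPoint-class].
#' @export
operatingPoint <- function(pr, minPrecision) {
  stopifnot(is(pr, "PRCurve"))
  checkFraction(minPrecision, "minPrecision", openLower = TRUE)
  ok <- which(pr@precision >= minPrecision)
  if (length(ok) == 0L) {
    return(new("OperatingPoint", threshold = NA_real_, precision = NA_real_,
               recall = NA_real_, fpr = NA_real_, attainable = FALSE))
  }
  best <- ok[which.max(pr@recall[ok])]
  new("OperatingPoint", threshold = pr@thresholds[best],
      precision = pr@precision[best], recall = pr@recall[best],
      fpr = pr@fpr[best], attainable = TRUE)
}
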