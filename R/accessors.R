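## Accessors and show methods. Slot access from user code should go through
## these, never through @.

#' @rdname ScoreModel
#' @param object,x An icasort S4 object.
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname ScoreModel
#' @export
setMethod("classNames", "ScoreModel", function(x) x@classNames)

#' @rdname CellCohort
#' @export
setMethod("classNames", "CellCohort", function(x) colnames(x@scores))

#' Number of cells in a cohort or session
#' @param x A [CellCohort-class] or [AnnotationSession-class].
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname nCells
#' @export
setMethod("nCells", "CellCohort", function(x) length(x@cellId))

#' @rdname nCells
#' @export
setMethod("nCells", "AnnotationSession", function(x) length(x@cellIds))

#' Cell ids
#' @param x A [CellCohort-class] or [AnnotationSession-class].
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname cellIds
#' @export
setMethod("cellIds", "CellCohort", function(x) x@cellId)

#' @rdname cellIds
#' @export
setMethod("cellIds", "AnnotationSession", function(x) x@cellIds)

#' Ground-truth labels of a cohort
#' @param x A [CellCohort-class].
#' @export
trueLabels <- function(x) {
  stopifnot(is(x, "CellCohort"))
  x@trueLabel
}

#' Softmax score matrix of a cohort
#' @param x A [CellCohort-class].
#' @export
scoreMatrix <- function(x) {
  stopifnot(is(x, "CellCohort"))
  x@scores
}

#' Arrival times (seconds) of a cohort, or NULL
#' @param x A [CellCohort-class].
#' @export
arrivalTimes <- function(x) {
  stopifnot(is(x, "CellCohort"))
  x@arrivalTime
}

#' Embedding matrix of a cohort or session, or NULL
#' @param x A [CellCohort-class] or [AnnotationSession-class].
#' @export
setGeneric("embeddingMatrix", function(x) standardGeneric("embeddingMatrix"))

#' @rdname embeddingMatrix
#' @export
setMethod("embeddingMatrix", "CellCohort", function(x) x@embedding)

#' @rdname embeddingMatrix
#' @export
setMethod("embeddingMatrix", "AnnotationSession", function(x) x@embedding)

#' Subset a cohort by index or logical mask
#'
#' @param x A [CellCohort-class].
#' @param i Integer or logical index.
#' @param j,...,drop Ignored.
#' @return The subset [CellCohort-class]; row order is preserved.
#' @export
setMethod("[", "CellCohort", function(x, i, j, ..., drop = FALSE) {
  CellCohort(
    cellId = x@cellId[i],
    trueLabel = x@trueLabel[i],
    scores = x@scores[i, , drop = FALSE],
    embedding = if (is.null(x@embedding)) NULL else x@embedding[i, , drop = FALSE],
    arrivalTime = if (is.null(x@arrivalTime)) NULL else x@arrivalTime[i])
})

#' Sorting purity of a report
#' @param x A [SortReport-class] or [PurityEstimate-class].
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))

#' @rdname purity
#' @export
setMethod("purity", "SortReport", function(x) x@purity)

#' @rdname purity
#' @export
setMethod("purity", "PurityEstimate", function(x) x@pHat)

#' Sorting yield (collected targets / arrived targets)
#' @param x A [SortReport-class].
#' @export
sortYield <- function(x) {
  stopifnot(is(x, "SortReport"))
  x@yield
}

#' Area under a ROC curve
#' @param x A [ROCCurve-class].
#' @export
aucOf <- function(x) {
  stopifnot(is(x, "ROCCurve"))
  x@auc
}

#' Confidence interval of a purity estimate
#' @param x A [PurityEstimate-class].
#' @return Numeric c(lower, upper).
#' @export
purityCI <- function(x) {
  stopifnot(is(x, "PurityEstimate"))
  c(lower = x@ciLower, upper = x@ciUpper)
}

#' Cluster assignment of a session
#' @param x An [AnnotationSession-class].
#' @export
clusterAssignment <- function(x) {
  stopifnot(is(x, "AnnotationSession"))
  setNames(x@clusters, x@cellIds)
}

#' Per-cell labels of a session (NA where unlabeled)
#' @param x An [AnnotationSession-class].
#' @export
sessionLabels <- function(x) {
  stopifnot(is(x, "AnnotationSession"))
  setNames(x@labels, x@cellIds)
}

#' Per-cell label provenance of a session
#' @param x An [AnnotationSession-class].
#' @export
sessionProvenance <- function(x) {
  stopifnot(is(x, "AnnotationSession"))
  setNames(x@provenance, x@cellIds)
}

setMethod("show", "ScoreModel", function(object) {
  cat("ScoreModel with", length(object@classNames), "classes:",
      paste(object@classNames, collapse = ", "), "\n")
  cat("  separability:", object@separability,
      " logit scale:", object@logitScale, "\n")
})

setMethod("show", "MixtureSpec", function(object) {
  cat("MixtureSpec (target:", object@targetClass, ")\n")
  print(round(object@proportions, 8))
})

setMethod("show", "CellCohort", function(object) {
  cat("CellCohort with", length(object@cellId), "cells over",
      ncol(object@scores), "classes\n")
  tab <- table(factor(object@trueLabel, levels = colnames(object@scores)))
  print(tab)
  if (!is.null(object@embedding)) {
    cat("  embeddings:", ncol(object@embedding), "dimensions\n")
  }
  if (!is.null(object@arrivalTime)) {
    cat(sprintf("  arrival stream: %.3f s\n", max(0, tail(object@arrivalTime, 1))))
  }
})

setMethod("show", "SortReport", function(object) {
  cat("SortReport:", sum(object@nArrived), "cells arrived,",
      object@nTriggers, "valve triggers\n")
  cat(sprintf("  collected: %d target / %d background\n",
              object@nCollectedTarget, object@nCollectedBackground))
  cat(sprintf("  purity: %.4f  yield: %.4f  fold enrichment: %.1f\n",
              object@purity, object@yield, object@foldEnrichment))
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROCCurve with %d thresholds, AUC = %.6f\n",
              length(object@thresholds), object@auc))
})

setMethod("show", "PRCurve", function(object) {
  cat(sprintf("PRCurve at pi = %g with %d thresholds\n",
              object@mixturePi, length(object@thresholds)))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = truth, columns = argmax prediction)\n")
  print(object@counts)
})

setMethod("show", "OperatingPoint", function(object) {
  if (!object@attainable) {
    cat("OperatingPoint: requested precision unattainable\n")
  } else {
    cat(sprintf(
      "OperatingPoint: threshold %.6g, precision %.4f, recall %.4f, FPR %.3g\n",
      object@threshold, object@precision, object@recall, object@fpr))
  }
})

setMethod("show", "GenotypePanel", function(object) {
  cat("GenotypePanel with", length(object@variantId), "variants (",
      sum(isInformative(object)), "informative );",
      object@nSkipped, "records skipped on import\n")
})

setMethod("show", "PurityEstimate", function(object) {
  cat(sprintf("PurityEstimate: p = %.4f (SE %.4g, 95%% CI %.4f-%.4f) from %d informative variants%s\n",
              object@pHat, object@se, object@ciLower, object@ciUpper,
              object@nInformative,
              if (object@clamped) " [clamped to boundary]" else ""))
})

setMethod("show", "EnrichmentReport", function(object) {
  cat(sprintf("EnrichmentReport: %.4f -> %.4f purity, %.1f-fold (95%% CI %.1f-%.1f)\n",
              object@pre@pHat, object@post@pHat, object@foldEnrichment,
              object@ciLower, object@ciUpper))
})

setMethod("show", "AnnotationSession", function(object) {
  n <- length(object@cellIds)
  cat("AnnotationSession:", n, "cells,",
      length(unique(object@clusters)), "clusters,",
      sum(!is.na(object@labels)), "labeled\n")
})
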