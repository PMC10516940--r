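## Central S4 containers. Validity methods enforce the structural invariants
## the downstream operations assume (simplex scores, ordered arrivals,
## dosages in {0, 0.5, 1}, acyclic taxonomies, ...).

setClassUnion("matrixOrNULL", c("matrix", "NULL"))
setClassUnion("numericOrNULL", c("numeric", "NULL"))

SIMPLEX_TOL <- 1e-9

#' ScoreModel: class-conditional softmax score generator
#'
#' Stand-in for a trained image classifier. Softmax score vectors for a cell of
#' true class `c` are drawn by adding Gaussian noise (scale `logitScale`) to a
#' class-specific logit location vector (row `c` of `logitMeans`) and pushing
#' the result through softmax. By default the logit location is
#' `separability` on the own-class coordinate and 0 elsewhere, so
#' `separability` directly controls the inter-class margin: 0 gives
#' exchangeable classes (expected scores 1/K), large values give near-perfect
#' classification.
#'
#' @slot classNames Ordered character vector of K >= 2 output classes
#'   (may include quality classes such as `"debris"`, `"out_of_focus"`).
#' @slot logitMeans K x K numeric matrix; row = true class, column = logit
#'   location of each output class.
#' @slot logitScale Positive scalar, the logit-space noise scale.
#' @slot separability Non-negative scalar margin used to build the default
#'   `logitMeans`.
#' @export
setClass("ScoreModel",
  representation(classNames = "character", logitMeans = "matrix",
                 logitScale = "numeric", separability = "numeric"),
  validity = function(object) {
    msg <- character()
    K <- length(object@classNames)
    if (K < 2L) msg <- c(msg, "at least two output classes are required")
    if (anyDuplicated(object@classNames)) msg <- c(msg, "duplicate class names")
    if (!identical(dim(object@logitMeans), c(K, K))) {
      msg <- c(msg, "logitMeans must be a K x K matrix")
    }
    if (!identical(rownames(object@logitMeans), object@classNames) ||
        !identical(colnames(object@logitMeans), object@classNames)) {
      msg <- c(msg, "logitMeans dimnames must equal classNames")
    }
    if (length(object@logitScale) != 1L || object@logitScale <= 0) {
      msg <- c(msg, "logitScale must be a positive scalar")
    }
    if (length(object@separability) != 1L || object@separability < 0) {
      msg <- c(msg, "separability must be a non-negative scalar")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a ScoreModel
#'
#' @param classNames Character vector of output class names (K >= 2).
#' @param separability Non-negative inter-class logit margin; default 4 gives
#'   a strong but imperfect classifier.
#' @param logitScale Positive logit-noise standard deviation.
#' @param logitMeans Optional custom K x K logit-location matrix (row = true
#'   class); defaults to `separability * I_K`.
#' @return A [ScoreModel-class] object.
#' @examples
#' m <- ScoreModel(c("target", "background"), separability = 6)
#' @export
ScoreModel <- function(classNames, separability = 4, logitScale = 1,
                       logitMeans = NULL) {
  classNames <- as.character(classNames)
  K <- length(classNames)
  if (is.null(logitMeans)) {
    logitMeans <- diag(separability, K)
    dimnames(logitMeans) <- list(classNames, classNames)
  } else {
    logitMeans <- as.matrix(logitMeans)
    dimnames(logitMeans) <- list(classNames, classNames)
  }
  new("ScoreModel", classNames = classNames, logitMeans = logitMeans,
      logitScale = as.numeric(logitScale), separability = as.numeric(separability))
}

#' MixtureSpec: class proportions of a sample
#'
#' Describes the composition of an input sample, e.g. target cells spiked into
#' a background at 1:100,000. The target proportion `proportions[targetClass]`
#' is the quantity usually written as the mixture fraction pi.
#'
#' @slot proportions Named numeric vector of class fractions in (0, 1],
#'   summing to 1 within 1e-9.
#' @slot targetClass Name of the class of interest; must appear in
#'   `proportions`.
#' @export
setClass("MixtureSpec",
  representation(proportions = "numeric", targetClass = "character"),
  validity = function(object) {
    msg <- character()
    p <- object@proportions
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      msg <- c(msg, "proportions must be a named vector")
    }
    if (any(p <= 0) || any(p > 1)) msg <- c(msg, "fractions must lie in (0, 1]")
    if (abs(sum(p) - 1) > SIMPLEX_TOL) {
      msg <- c(msg, sprintf("fractions must sum to 1 (got %.12f)", sum(p)))
    }
    if (length(object@targetClass) != 1L ||
        !(object@targetClass %in% names(p))) {
      msg <- c(msg, "targetClass must name one entry of proportions")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a MixtureSpec
#'
#' @param proportions Named numeric vector of class fractions summing to 1.
#' @param targetClass Name of the target class.
#' @return A [MixtureSpec-class] object.
#' @examples
#' MixtureSpec(c(target = 1e-3, background = 1 - 1e-3), "target")
#' @export
MixtureSpec <- function(proportions, targetClass) {
  new("MixtureSpec", proportions = proportions,
      targetClass = as.character(targetClass))
}

#' Target proportion of a mixture
#' @param mixture A [MixtureSpec-class].
#' @return The target fraction pi.
#' @export
targetFraction <- function(mixture) {
  stopifnot(is(mixture, "MixtureSpec"))
  unname(mixture@proportions[mixture@targetClass])
}

#' CellCohort: a table of imaged cells
#'
#' One row per imaged cell: an opaque id, the ground-truth class, a softmax
#' score vector over the model's output classes, and optionally an embedding
#' vector and an arrival time (seconds, strictly increasing within a stream).
#'
#' @slot cellId Character vector of unique cell ids.
#' @slot trueLabel Character vector of ground-truth classes (each a column
#'   name of `scores`).
#' @slot scores n x K numeric matrix of simplex rows (sum to 1 within 1e-9).
#' @slot embedding Optional n x d numeric matrix.
#' @slot arrivalTime Optional numeric vector of arrival times in seconds,
#'   non-negative and strictly increasing.
#' @export
setClass("CellCohort",
  representation(cellId = "character", trueLabel = "character",
                 scores = "matrix", embedding = "matrixOrNULL",
                 arrivalTime = "numericOrNULL"),
  validity = function(object) {
    msg <- character()
    n <- length(object@cellId)
    if (anyDuplicated(object@cellId)) msg <- c(msg, "duplicate cell ids")
    if (length(object@trueLabel) != n) msg <- c(msg, "trueLabel length mismatch")
    if (nrow(object@scores) != n) msg <- c(msg, "scores row count mismatch")
    if (is.null(colnames(object@scores))) {
      msg <- c(msg, "scores must have class-name column names")
    } else if (!all(object@trueLabel %in% colnames(object@scores))) {
      msg <- c(msg, "every trueLabel must be a score column")
    }
    if (n > 0 && any(abs(rowSums(object@scores) - 1) > SIMPLEX_TOL)) {
      msg <- c(msg, "score rows must sum to 1 within 1e-9")
    }
    if (n > 0 && any(object@scores < 0)) msg <- c(msg, "scores must be non-negative")
    if (!is.null(object@embedding) && nrow(object@embedding) != n) {
      msg <- c(msg, "embedding row count mismatch")
    }
    at <- object@arrivalTime
    if (!is.null(at)) {
      if (length(at) != n) msg <- c(msg, "arrivalTime length mismatch")
      if (n > 0 && (any(at < 0) || any(diff(at) <= 0))) {
        msg <- c(msg, "arrival times must be non-negative and strictly increasing")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a CellCohort
#'
#' @param cellId Character vector of unique ids.
#' @param trueLabel Ground-truth class per cell.
#' @param scores n x K simplex score matrix with class-name columns.
#' @param embedding Optional n x d embedding matrix.
#' @param arrivalTime Optional strictly increasing arrival times (seconds).
#' @return A [CellCohort-class] object.
#' @export
CellCohort <- function(cellId, trueLabel, scores, embedding = NULL,
                       arrivalTime = NULL) {
  new("CellCohort", cellId = as.character(cellId),
      trueLabel = as.character(trueLabel), scores = scores,
      embedding = embedding, arrivalTime = arrivalTime)
}

#' SorterConfig: operating point of the virtual valve sorter
#'
#' @slot cellRate Total cell arrival rate in cells/minute (> 0).
#' @slot valveWindowMs Valve open window w in milliseconds (>= 0).
#' @slot deadTimeMs Refractory time after a window closes before a new
#'   trigger is allowed (>= 0).
#' @slot jitterScaleMs Standard deviation of the arrival-prediction error
#'   (>= 0); the valve opens centred on the predicted arrival, so a triggering
#'   cell is captured iff its prediction error lies within +/- w/2.
#' @slot decisionThreshold Selection-score threshold in [0, 1].
#' @slot mode `"positive"` (gate on the target score) or `"negative"`
#'   (gate out background scores).
#' @slot targetClass Name of the class routed to the collection outlet.
#' @slot triggerOnQuality Whether cells whose true class is a quality class
#'   may trigger the valve (default FALSE: debris/out-of-focus calls report on
#'   sample quality and do not sort).
#' @slot qualityClasses Character vector of quality class names.
#' @export
setClass("SorterConfig",
  representation(cellRate = "numeric", valveWindowMs = "numeric",
                 deadTimeMs = "numeric", jitterScaleMs = "numeric",
                 decisionThreshold = "numeric", mode = "character",
                 targetClass = "character", triggerOnQuality = "logical",
                 qualityClasses = "character"),
  validity = function(object) {
    msg <- character()
    if (object@cellRate <= 0) msg <- c(msg, "cellRate must be positive")
    if (object@valveWindowMs < 0) msg <- c(msg, "valveWindowMs must be >= 0")
    if (object@deadTimeMs < 0) msg <- c(msg, "deadTimeMs must be >= 0")
    if (object@jitterScaleMs < 0) msg <- c(msg, "jitterScaleMs must be >= 0")
    if (object@decisionThreshold < 0 || object@decisionThreshold > 1) {
      msg <- c(msg, "decisionThreshold must lie in [0, 1]")
    }
    if (!object@mode %in% c("positive", "negative")) {
      msg <- c(msg, "mode must be 'positive' or 'negative'")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a SorterConfig
#'
#' @param cellRate Cells per minute.
#' @param valveWindowMs Valve window in ms.
#' @param targetClass Class sorted to the collection outlet.
#' @param deadTimeMs Post-window refractory time in ms (default 0).
#' @param jitterScaleMs Arrival-prediction error scale in ms (default 0).
#' @param decisionThreshold Selection threshold (default 0.5).
#' @param mode `"positive"` or `"negative"` selection.
#' @param triggerOnQuality Allow quality-class cells to trigger (default FALSE).
#' @param qualityClasses Quality class names.
#' @return A [SorterConfig-class] object.
#' @examples
#' SorterConfig(cellRate = 3000, valveWindowMs = 15, targetClass = "target")
#' @export
SorterConfig <- function(cellRate, valveWindowMs, targetClass,
                         deadTimeMs = 0, jitterScaleMs = 0,
                         decisionThreshold = 0.5,
                         mode = c("positive", "negative"),
                         triggerOnQuality = FALSE,
                         qualityClasses = c("debris", "out_of_focus")) {
  mode <- match.arg(mode)
  new("SorterConfig", cellRate = as.numeric(cellRate),
      valveWindowMs = as.numeric(valveWindowMs),
      deadTimeMs = as.numeric(deadTimeMs),
      jitterScaleMs = as.numeric(jitterScaleMs),
      decisionThreshold = as.numeric(decisionThreshold), mode = mode,
      targetClass = as.character(targetClass),
      triggerOnQuality = isTRUE(triggerOnQuality),
      qualityClasses = as.character(qualityClasses))
}

#' SortReport: outcome of one simulated sorting run
#'
#' Every arrived cell is accounted for exactly once: collected (in a valve
#' window), missed (a target not collected), or discarded (a non-target not
#' collected).
#'
#' @slot nArrived Named integer vector of arrivals per class.
#' @slot nTriggers Number of valve openings.
#' @slot nCollectedTarget,nCollectedBackground Collected cell counts.
#' @slot nMissedTarget Targets that arrived but were not collected.
#' @slot purity Collected targets / all collected (NA if nothing collected).
#' @slot yield Collected targets / arrived targets.
#' @slot foldEnrichment Purity divided by the mixture's target fraction.
#' @slot durationS Time of the last arrival, seconds.
#' @slot seed Seed used for the run.
#' @slot config The [SorterConfig-class] used.
#' @export
setClass("SortReport",
  representation(nArrived = "integer", nTriggers = "integer",
                 nCollectedTarget = "integer", nCollectedBackground = "integer",
                 nMissedTarget = "integer", purity = "numeric",
                 yield = "numeric", foldEnrichment = "numeric",
                 durationS = "numeric", seed = "numeric",
                 config = "SorterConfig"),
  validity = function(object) {
    msg <- character()
    tgt <- object@config@targetClass
    if (tgt %in% names(object@nArrived)) {
      if (object@nCollectedTarget + object@nMissedTarget >
          object@nArrived[[tgt]]) {
        msg <- c(msg, "collected + missed targets exceed arrived targets")
      }
    }
    for (s in c("purity", "yield")) {
      v <- slot(object, s)
      if (!is.na(v) && (v < 0 || v > 1)) {
        msg <- c(msg, sprintf("%s must lie in [0, 1]", s))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' ROCCurve: threshold sweep of TPR against FPR
#'
#' @slot thresholds Descending score cutoffs (starting at Inf).
#' @slot tpr,fpr Non-decreasing vectors with endpoints (0,0) and (1,1).
#' @slot auc Trapezoidal area under the curve.
#' @export
setClass("ROCCurve",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 auc = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@thresholds)
    if (length(object@tpr) != n || length(object@fpr) != n) {
      msg <- c(msg, "thresholds, tpr and fpr must have equal length")
    }
    if (is.unsorted(rev(object@thresholds))) {
      msg <- c(msg, "thresholds must be non-increasing")
    }
    if (any(diff(object@tpr) < 0) || any(diff(object@fpr) < 0)) {
      msg <- c(msg, "tpr and fpr must be non-decreasing")
    }
    if (n > 0 && (object@tpr[1] != 0 || object@fpr[1] != 0 ||
                  object@tpr[n] != 1 || object@fpr[n] != 1)) {
      msg <- c(msg, "curve must run from (0,0) to (1,1)")
    }
    trap <- sum(diff(object@fpr) * (head(object@tpr, -1) + tail(object@tpr, -1)) / 2)
    if (abs(trap - object@auc) > 1e-12) {
      msg <- c(msg, "auc must equal the trapezoidal integral within 1e-12")
    }
    if (length(msg)) msg else TRUE
  })

#' PRCurve: precision-recall curve at a mixture proportion
#'
#' @slot thresholds Descending score cutoffs.
#' @slot precision,recall Vectors in [0, 1]; recall equals the source ROC's
#'   TPR pointwise.
#' @slot fpr The source ROC's FPR, carried for operating-point reporting.
#' @slot mixturePi Target proportion pi used for reweighting.
#' @export
setClass("PRCurve",
  representation(thresholds = "numeric", precision = "numeric",
                 recall = "numeric", fpr = "numeric", mixturePi = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@thresholds)
    if (length(object@precision) != n || length(object@recall) != n ||
        length(object@fpr) != n) {
      msg <- c(msg, "component vectors must have equal length")
    }
    if (any(object@precision < 0 | object@precision > 1, na.rm = TRUE) ||
        any(object@recall < 0 | object@recall > 1)) {
      msg <- c(msg, "precision and recall must lie in [0, 1]")
    }
    if (object@mixturePi <= 0 || object@mixturePi >= 1) {
      msg <- c(msg, "mixturePi must lie in (0, 1)")
    }
    if (length(msg)) msg else TRUE
  })

#' ConfusionMatrix: argmax predictions against ground truth
#'
#' @slot classNames Class names (row and column order).
#' @slot counts K x K integer matrix; rows = ground truth, columns = argmax
#'   prediction.
#' @slot fractions Row-normalised counts (NA rows for empty truth classes).
#' @export
setClass("ConfusionMatrix",
  representation(classNames = "character", counts = "matrix",
                 fractions = "matrix"),
  validity = function(object) {
    msg <- character()
    K <- length(object@classNames)
    if (!identical(dim(object@counts), c(K, K))) {
      msg <- c(msg, "counts must be K x K")
    }
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    rs <- rowSums(object@counts)
    ok <- rs == 0 | abs(rowSums(object@fractions) - 1) < 1e-9
    if (!all(ok)) msg <- c(msg, "non-empty rows of fractions must sum to 1")
    if (length(msg)) msg else TRUE
  })

#' OperatingPoint: a chosen threshold on a precision-recall curve
#'
#' @slot threshold Score cutoff.
#' @slot precision,recall,fpr Curve values at the threshold.
#' @slot attainable FALSE when no threshold met the requested precision.
#' @export
setClass("OperatingPoint",
  representation(threshold = "numeric", precision = "numeric",
                 recall = "numeric", fpr = "numeric", attainable = "logical"))

#' GenotypePanel: known genotypes of target and background populations
#'
#' @slot variantId Unique variant identifiers.
#' @slot chrom,pos,ref,alt Variant coordinates (1-based) and alleles.
#' @slot gTarget,gBackground Alternate-allele dosages in {0, 0.5, 1}.
#' @slot nSkipped Records dropped on import (multi-allelic, non-SNV, missing
#'   genotype).
#' @export
setClass("GenotypePanel",
  representation(variantId = "character", chrom = "character",
                 pos = "integer", ref = "character", alt = "character",
                 gTarget = "numeric", gBackground = "numeric",
                 nSkipped = "integer"),
  validity = function(object) {
    msg <- character()
    n <- length(object@variantId)
    if (anyDuplicated(object@variantId)) msg <- c(msg, "variant ids must be unique")
    lens <- c(length(object@chrom), length(object@pos), length(object@ref),
              length(object@alt), length(object@gTarget),
              length(object@gBackground))
    if (any(lens != n)) msg <- c(msg, "field length mismatch")
    if (!all(object@gTarget %in% c(0, 0.5, 1)) ||
        !all(object@gBackground %in% c(0, 0.5, 1))) {
      msg <- c(msg, "dosages must be 0, 0.5 or 1")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a GenotypePanel
#'
#' @param variantId Unique ids.
#' @param gTarget,gBackground Dosages in {0, 0.5, 1}.
#' @param chrom,pos,ref,alt Optional coordinates/alleles.
#' @param nSkipped Import skip count (default 0).
#' @return A [GenotypePanel-class] object.
#' @export
GenotypePanel <- function(variantId, gTarget, gBackground,
                          chrom = rep(NA_character_, length(variantId)),
                          pos = rep(NA_integer_, length(variantId)),
                          ref = rep(NA_character_, length(variantId)),
                          alt = rep(NA_character_, length(variantId)),
                          nSkipped = 0L) {
  new("GenotypePanel", variantId = as.character(variantId),
      chrom = as.character(chrom), pos = as.integer(pos),
      ref = as.character(ref), alt = as.character(alt),
      gTarget = as.numeric(gTarget), gBackground = as.numeric(gBackground),
      nSkipped = as.integer(nSkipped))
}

#' Informative variants of a panel
#'
#' A variant is informative for mixture estimation iff the target and
#' background dosages differ.
#'
#' @param panel A [GenotypePanel-class].
#' @return Logical vector, one entry per variant.
#' @export
isInformative <- function(panel) {
  stopifnot(is(panel, "GenotypePanel"))
  panel@gTarget != panel@gBackground
}

#' AlleleCounts: observed sequencing depths per panel variant
#'
#' @slot variantId Variant ids aligning 1:1 with a panel.
#' @slot refCount,altCount Non-negative integer read counts.
#' @export
setClass("AlleleCounts",
  representation(variantId = "character", refCount = "integer",
                 altCount = "integer"),
  validity = function(object) {
    msg <- character()
    n <- length(object@variantId)
    if (length(object@refCount) != n || length(object@altCount) != n) {
      msg <- c(msg, "count length mismatch")
    }
    if (any(object@refCount < 0) || any(object@altCount < 0)) {
      msg <- c(msg, "counts must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct AlleleCounts
#' @param variantId Variant ids.
#' @param refCount,altCount Non-negative integer read counts.
#' @return An [AlleleCounts-class] object.
#' @export
AlleleCounts <- function(variantId, refCount, altCount) {
  new("AlleleCounts", variantId = as.character(variantId),
      refCount = as.integer(round(refCount)),
      altCount = as.integer(round(altCount)))
}

#' Observed alternate-allele fractions
#' @param counts An [AlleleCounts-class].
#' @return Numeric vector alt/(ref+alt); NA where depth is 0.
#' @export
alleleFractions <- function(counts) {
  stopifnot(is(counts, "AlleleCounts"))
  depth <- counts@refCount + counts@altCount
  ifelse(depth > 0, counts@altCount / depth, NA_real_)
}

#' PurityEstimate: estimated target fraction of a cell pool
#'
#' @slot pHat Maximum-likelihood target fraction in [0, 1].
#' @slot se Standard error from observed Fisher information.
#' @slot ciLower,ciUpper Wald 95% interval truncated to [0, 1].
#' @slot nInformative Number of informative variants used.
#' @slot residuals Per-variant observed minus fitted allele fractions.
#' @slot clamped TRUE when the optimum was clamped to a boundary.
#' @slot logLik Log-likelihood at the optimum.
#' @export
setClass("PurityEstimate",
  representation(pHat = "numeric", se = "numeric", ciLower = "numeric",
                 ciUpper = "numeric", nInformative = "integer",
                 residuals = "data.frame", clamped = "logical",
                 logLik = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@pHat < 0 || object@pHat > 1) msg <- c(msg, "pHat must lie in [0, 1]")
    if (!is.na(object@ciLower) &&
        (object@ciLower > object@pHat || object@ciUpper < object@pHat)) {
      msg <- c(msg, "confidence interval must contain pHat")
    }
    if (length(msg)) msg else TRUE
  })

#' EnrichmentReport: fold change between two purity estimates
#'
#' @slot foldEnrichment post purity / pre purity.
#' @slot ciLower,ciUpper Delta-method 95% interval on the ratio.
#' @slot pre,post The two [PurityEstimate-class] inputs.
#' @export
setClass("EnrichmentReport",
  representation(foldEnrichment = "numeric", ciLower = "numeric",
                 ciUpper = "numeric", pre = "PurityEstimate",
                 post = "PurityEstimate"))

#' LabelTaxonomy: hierarchical annotation vocabulary
#'
#' A cell may carry every annotation on its lineage path, so the taxonomy is a
#' forest: each non-root label has exactly one parent and the parent relation
#' is acyclic.
#'
#' @slot labels Character vector of label identifiers.
#' @slot parent Named character vector mapping each label to its parent
#'   (NA for roots).
#' @export
setClass("LabelTaxonomy",
  representation(labels = "character", parent = "character"),
  validity = function(object) {
    msg <- character()
    if (anyDuplicated(object@labels)) msg <- c(msg, "duplicate labels")
    if (!identical(sort(names(object@parent)), sort(object@labels))) {
      msg <- c(msg, "parent map must cover exactly the labels")
    }
    known <- object@parent[!is.na(object@parent)]
    if (!all(known %in% object@labels)) {
      msg <- c(msg, "parents must be existing labels")
    }
    ## cycle check: walk up from every label
    for (lab in object@labels) {
      seen <- character()
      cur <- lab
      while (!is.na(cur)) {
        if (cur %in% seen) { msg <- c(msg, "lineage contains a cycle"); break }
        seen <- c(seen, cur)
        cur <- object@parent[[cur]]
      }
    }
    if (length(msg)) unique(msg) else TRUE
  })

#' Construct a LabelTaxonomy
#'
#' @param labels Label identifiers.
#' @param parent Named character vector (label -> parent, NA for roots);
#'   defaults to a flat taxonomy of roots.
#' @return A [LabelTaxonomy-class] object.
#' @export
LabelTaxonomy <- function(labels, parent = NULL) {
  labels <- as.character(labels)
  if (is.null(parent)) {
    parent <- setNames(rep(NA_character_, length(labels)), labels)
  } else {
    full <- setNames(rep(NA_character_, length(labels)), labels)
    full[names(parent)] <- parent
    parent <- full
  }
  new("LabelTaxonomy", labels = labels, parent = parent)
}

#' Lineage path of a label
#'
#' @param taxonomy A [LabelTaxonomy-class].
#' @param label A label in the taxonomy.
#' @return Character vector from the label up to its root.
#' @export
lineagePath <- function(taxonomy, label) {
  stopifnot(is(taxonomy, "LabelTaxonomy"))
  if (!label %in% taxonomy@labels) stop("unknown label: ", label)
  path <- character()
  cur <- label
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- taxonomy@parent[[cur]]
  }
  path
}

#' LabelConstraint: metadata-conditional label restriction
#'
#' When every `when` field of the sample metadata matches, the `disallow`
#' labels may not be assigned (e.g. fetal cell classes are disallowed for
#' samples drawn from non-pregnant adult donors). Rules are field-equality
#' matches so sessions serialise losslessly.
#'
#' @slot when Named list of metadata field = value conditions.
#' @slot disallow Labels removed when the condition matches.
#' @export
setClass("LabelConstraint",
  representation(when = "list", disallow = "character"),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@when)) || any(!nzchar(names(object@when)))) {
      msg <- c(msg, "'when' must be a named list of metadata conditions")
    }
    if (length(object@disallow) == 0L) {
      msg <- c(msg, "'disallow' must name at least one label")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a LabelConstraint
#' @param when Named list of metadata conditions (all must match).
#' @param disallow Labels disallowed when the condition matches.
#' @return A [LabelConstraint-class] object.
#' @examples
#' LabelConstraint(when = list(donor_status = "adult_non_pregnant"),
#'                 disallow = "fnRBC")
#' @export
LabelConstraint <- function(when, disallow) {
  new("LabelConstraint", when = as.list(when),
      disallow = as.character(disallow))
}

#' AnnotationSession: state of an expert labeling session
#'
#' @slot cellIds Character ids, one per cell.
#' @slot embedding n x d embedding matrix.
#' @slot clusters Dense integer cluster assignment (1-based).
#' @slot labels Per-cell label or NA.
#' @slot provenance `"batch"`, `"override"` or NA per cell.
#' @slot labeler Labeler id per cell (NA when unlabeled).
#' @slot metadata Named list of sample metadata used by constraints.
#' @slot taxonomy The active [LabelTaxonomy-class].
#' @slot constraints List of [LabelConstraint-class] rules.
#' @export
setClass("AnnotationSession",
  representation(cellIds = "character", embedding = "matrix",
                 clusters = "integer", labels = "character",
                 provenance = "character", labeler = "character",
                 metadata = "list", taxonomy = "LabelTaxonomy",
                 constraints = "list"),
  validity = function(object) {
    msg <- character()
    n <- length(object@cellIds)
    if (anyDuplicated(object@cellIds)) msg <- c(msg, "duplicate cell ids")
    if (nrow(object@embedding) != n) msg <- c(msg, "embedding row mismatch")
    lens <- c(length(object@clusters), length(object@labels),
              length(object@provenance), length(object@labeler))
    if (any(lens != n)) msg <- c(msg, "per-cell field length mismatch")
    if (n > 0) {
      u <- sort(unique(object@clusters))
      if (!identical(u, seq_along(u))) {
        msg <- c(msg, "cluster ids must be dense starting at 1")
      }
    }
    lab <- object@labels[!is.na(object@labels)]
    if (!all(lab %in% object@taxonomy@labels)) {
      msg <- c(msg, "labels must belong to the taxonomy")
    }
    allowed <- tryCatch(
      allowedLabels(object@metadata, object@taxonomy, object@constraints),
      error = function(e) NULL)
    if (!is.null(allowed) && !all(lab %in% allowed)) {
      msg <- c(msg, "a label violates an active constraint")
    }
    pv <- object@provenance[!is.na(object@provenance)]
    if (!all(pv %in% c("batch", "override"))) {
      msg <- c(msg, "provenance must be 'batch' or 'override'")
    }
    if (length(msg)) msg else TRUE
  })
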