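## Synthetic-data module: class-conditional score vectors, cohorts with
## Poisson arrival streams, embedding clouds, and binomial allele counts.
## These generators replace the instrument and the trained classifier; they
## give the downstream modules inputs with the statistical structure those
## modules assume, nothing more.

#' Draw softmax score vectors for one true class
#'
#' Adds Gaussian noise of scale `logitScale` to the class's logit location
#' vector and pushes each draw through softmax, yielding simplex rows. With
#' `separability = 0` all classes are exchangeable (expected scores 1/K);
#' with a large margin the argmax recovers the true class almost surely.
#'
#' @param model A [ScoreModel-class].
#' @param label The true class to condition on.
#' @param n Number of vectors (>= 0).
#' @param seed Integer seed; output is bit-identical for fixed
#'   (model, label, n, seed).
#' @return n x K matrix with class-name columns; rows sum to 1.
#' @examples
#' m <- ScoreModel(c("target", "background"), separability = 6)
#' s <- sampleScoreVectors(m, "target", 5, seed = 1)
#' rowSums(s)
#' @export
sampleScoreVectors <- function(model, label, n, seed) {
  stopifnot(is(model, "ScoreModel"))
  if (!label %in% model@classNames) {
    stop("unknown class label: '", label, "'")
  }
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop("'n' must be a single non-negative count")
  }
  K <- length(model@classNames)
  if (n == 0) {
    return(matrix(numeric(0), 0L, K,
                  dimnames = list(NULL, model@classNames)))
  }
  withSeed(seed, {
    logits <- matrix(rnorm(n * K, sd = model@logitScale), n, K)
    logits <- sweep(logits, 2L, model@logitMeans[label, ], `+`)
    out <- softmaxRows(logits)
    colnames(out) <- model@classNames
    out
  })
}

#' Draw a synthetic cohort from a class mixture
#'
#' Labels are i.i.d. from the mixture proportions; each cell then receives a
#' class-conditional score vector from the model. When `cellRate` is given,
#' arrival times are a homogeneous Poisson-process realisation at that rate
#' (exponential interarrivals), as assumed by the sorter simulation.
#'
#' @param model A [ScoreModel-class].
#' @param mixture A [MixtureSpec-class]; proportions must sum to 1.
#' @param n Number of cells (>= 0).
#' @param seed Integer seed.
#' @param cellRate Optional total arrival rate in cells/minute; when given,
#'   arrival times (seconds) are attached.
#' @return A [CellCohort-class].
#' @export
sampleCohort <- function(model, mixture, n, seed, cellRate = NULL) {
  stopifnot(is(model, "ScoreModel"), is(mixture, "MixtureSpec"))
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop("'n' must be a single non-negative count")
  }
  if (abs(sum(mixture@proportions) - 1) > SIMPLEX_TOL) {
    stop("mixture proportions must sum to 1")
  }
  if (!all(names(mixture@proportions) %in% model@classNames)) {
    stop("mixture classes must be model classes")
  }
  K <- length(model@classNames)
  if (n == 0) {
    return(CellCohort(character(), character(),
                      matrix(numeric(0), 0L, K,
                             dimnames = list(NULL, model@classNames)),
                      arrivalTime = if (is.null(cellRate)) NULL else numeric()))
  }
  withSeed(seed, {
    labels <- sample(names(mixture@proportions), n, replace = TRUE,
                     prob = mixture@proportions)
    logits <- matrix(rnorm(n * K, sd = model@logitScale), n, K) +
      model@logitMeans[labels, , drop = FALSE]
    scores <- softmaxRows(logits)
    dimnames(scores) <- list(NULL, model@classNames)
    arrival <- NULL
    if (!is.null(cellRate)) {
      stopifnot(cellRate > 0)
      arrival <- cumsum(rexp(n, rate = cellRate / 60))
    }
    CellCohort(cellId = sprintf("cell%07d", seq_len(n)), trueLabel = labels,
               scores = scores, arrivalTime = arrival)
  })
}

#' Draw isotropic Gaussian embedding clouds around class centroids
#'
#' @param centroids Matrix with one row per class (row names = class names)
#'   and d columns, or a named list of d-vectors.
#' @param spread Positive isotropic noise scale.
#' @param labels Character vector of class labels, one per cell.
#' @param seed Integer seed.
#' @return length(labels) x d numeric matrix.
#' @export
sampleEmbeddings <- function(centroids, spread, labels, seed) {
  if (is.list(centroids)) {
    centroids <- do.call(rbind, centroids)
  }
  centroids <- as.matrix(centroids)
  if (is.null(rownames(centroids))) {
    stop("centroids must carry class row names")
  }
  if (!is.numeric(spread) || length(spread) != 1L || spread <= 0) {
    stop("'spread' must be a positive scalar")
  }
  labels <- as.character(labels)
  missing <- setdiff(unique(labels), rownames(centroids))
  if (length(missing)) {
    stop("no centroid for label(s): ", paste(missing, collapse = ", "))
  }
  d <- ncol(centroids)
  n <- length(labels)
  if (n == 0L) return(matrix(numeric(0), 0L, d))
  withSeed(seed, {
    out <- centroids[labels, , drop = FALSE] +
      matrix(rnorm(n * d, sd = spread), n, d)
    dimnames(out) <- NULL
    out
  })
}

#' Draw allele counts from a two-population DNA mixture
#'
#' Per variant i, the expected alternate-allele fraction of a pool containing
#' a fraction `purity` of target cells is
#' `f_i = purity * gTarget_i + (1 - purity) * gBackground_i`. Depth is drawn
#' as Poisson(`depth`) per variant and the alternate count as
#' Binomial(depth_i, f_i).
#'
#' @param panel A [GenotypePanel-class]; dosages must be in {0, 0.5, 1}.
#' @param purity Target-cell fraction in [0, 1].
#' @param depth Mean read depth per variant (> 0).
#' @param seed Integer seed.
#' @return An [AlleleCounts-class] aligned with the panel.
#' @export
sampleAlleleCounts <- function(panel, purity, depth, seed) {
  stopifnot(is(panel, "GenotypePanel"))
  checkFraction(purity, "purity")
  if (!is.numeric(depth) || length(depth) != 1L || depth <= 0) {
    stop("'depth' must be a positive mean read count")
  }
  f <- expectedAlleleFraction(purity, panel@gTarget, panel@gBackground)
  n <- length(panel@variantId)
  withSeed(seed, {
    dp <- rpois(n, depth)
    alt <- rbinom(n, dp, f)
    AlleleCounts(panel@variantId, refCount = dp - alt, altCount = alt)
  })
}

#' Class-composition preset mirroring a circulating-cell training set
#'
#' Returns mixture proportions in which out-of-focus images make up 39.01%
#' and debris 6.57% of the stream, with the remainder split between a target
#' class and an evaluable background. Useful for exercising quality-class
#' filtering at a realistic composition.
#'
#' @param targetClass Name of the target class (default `"target"`).
#' @param backgroundClass Name of the evaluable background class.
#' @param targetShare Fraction of the *evaluable* cells that are targets
#'   (default 0.5).
#' @return A [MixtureSpec-class] over target, background, debris and
#'   out_of_focus classes.
#' @export
circulatingPreset <- function(targetClass = "target",
                              backgroundClass = "background",
                              targetShare = 0.5) {
  checkFraction(targetShare, "targetShare", openLower = TRUE, openUpper = TRUE)
  evaluable <- 1 - 0.3901 - 0.0657
  p <- c(evaluable * targetShare, evaluable * (1 - targetShare), 0.0657, 0.3901)
  names(p) <- c(targetClass, backgroundClass, "debris", "out_of_focus")
  MixtureSpec(p, targetClass)
}
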