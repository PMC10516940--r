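## Embedding-based semi-supervised annotation: agglomerative clustering of
## embedding vectors, metadata-constrained label sets, cluster-level batch
## labeling with per-cell overrides, inter-labeler QC and hard-example
## mining.

#' Agglomerative clustering of embedding vectors
#'
#' Deterministic average-linkage hierarchical clustering (Euclidean distance
#' by default; cosine distance available for directionally structured
#' embeddings). Exactly one of `nClusters` or `distanceCut` selects the cut.
#'
#' @param embeddings n x d numeric matrix.
#' @param nClusters Number of clusters to cut the tree into.
#' @param distanceCut Height at which to cut the merge tree; 0 gives one
#'   cluster per distinct point.
#' @param linkage Linkage criterion passed to [stats::hclust()].
#' @param metric `"euclidean"` or `"cosine"`.
#' @return List with `clusters` (dense 1-based integer assignment) and
#'   `tree` (the `hclust` merge tree, NULL when n = 1).
#' @export
hierarchicalClusters <- function(embeddings, nClusters = NULL,
                                 distanceCut = NULL, linkage = "average",
                                 metric = c("euclidean", "cosine")) {
  embeddings <- as.matrix(embeddings)
  metric <- match.arg(metric)
  n <- nrow(embeddings)
  if (n < 1L) stop("at least one cell is required")
  if (is.null(nClusters) == is.null(distanceCut)) {
    stop("give exactly one of 'nClusters' or 'distanceCut'")
  }
  if (!is.null(nClusters) && nClusters > n) {
    stop(sprintf("nClusters = %d exceeds the number of cells (%d)",
                 nClusters, n))
  }
  if (n == 1L) {
    return(list(clusters = 1L, tree = NULL))
  }
  d <- if (metric == "euclidean") {
    dist(embeddings)
  } else {
    nrm <- sqrt(rowSums(embeddings^2))
    nrm[nrm == 0] <- 1
    as.dist(1 - tcrossprod(embeddings / nrm))
  }
  tree <- hclust(d, method = linkage)
  raw <- if (is.null(nClusters)) {
    cutree(tree, h = distanceCut)
  } else {
    cutree(tree, k = nClusters)
  }
  ## dense 1-based ids in order of first appearance
  clusters <- as.integer(factor(raw, levels = unique(raw)))
  list(clusters = clusters, tree = tree)
}

#' Labels permitted for a sample under the active constraints
#'
#' Applies every matching [LabelConstraint-class] and removes the union of
#' their disallowed sets from the taxonomy.
#'
#' @param sampleMetadata Named list of metadata fields (e.g. donor status,
#'   sample source).
#' @param taxonomy A [LabelTaxonomy-class].
#' @param constraints List of [LabelConstraint-class] rules.
#' @return Character vector of allowed labels.
#' @examples
#' tax <- LabelTaxonomy(c("PBMC", "fnRBC", "NSCLC"))
#' con <- LabelConstraint(list(donor = "adult_non_pregnant"), "fnRBC")
#' allowedLabels(list(donor = "adult_non_pregnant"), tax, list(con))
#' @export
allowedLabels <- function(sampleMetadata, taxonomy, constraints = list()) {
  stopifnot(is(taxonomy, "LabelTaxonomy"))
  disallowed <- character()
  for (con in constraints) {
    stopifnot(is(con, "LabelConstraint"))
    bad <- setdiff(con@disallow, taxonomy@labels)
    if (length(bad)) {
      stop("constraint disallows unknown label(s): ",
           paste(bad, collapse = ", "))
    }
    fields <- names(con@when)
    missing <- setdiff(fields, names(sampleMetadata))
    if (length(missing)) {
      stop("constraint references unknown metadata field(s): ",
           paste(missing, collapse = ", "))
    }
    matches <- all(vapply(fields, function(f) {
      identical(sampleMetadata[[f]], con@when[[f]])
    }, logical(1)))
    if (matches) disallowed <- union(disallowed, con@disallow)
  }
  setdiff(taxonomy@labels, disallowed)
}

#' Start an annotation session
#'
#' @param cellIds Unique cell ids.
#' @param embeddings n x d embedding matrix.
#' @param clusters Dense 1-based cluster assignment (e.g. from
#'   [hierarchicalClusters()]).
#' @param taxonomy A [LabelTaxonomy-class].
#' @param constraints List of [LabelConstraint-class] rules.
#' @param metadata Named list of sample metadata.
#' @return An unlabeled [AnnotationSession-class].
#' @export
AnnotationSession <- function(cellIds, embeddings, clusters, taxonomy,
                              constraints = list(), metadata = list()) {
  n <- length(cellIds)
  new("AnnotationSession", cellIds = as.character(cellIds),
      embedding = as.matrix(embeddings), clusters = as.integer(clusters),
      labels = rep(NA_character_, n), provenance = rep(NA_character_, n),
      labeler = rep(NA_character_, n), metadata = metadata,
      taxonomy = taxonomy, constraints = constraints)
}

#' Batch-label clusters with per-cell overrides
#'
#' Every cell of a mapped cluster receives the cluster's label unless an
#' override names it individually. The assignment is atomic: if any affected
#' cell would receive a label disallowed by the active constraints, the whole
#' call fails naming that cell and the session is unchanged.
#'
#' @param session An [AnnotationSession-class].
#' @param clusterLabelMap Named character vector: cluster id (as character)
#'   -> label.
#' @param overrides Named character vector: cell id -> label.
#' @param labeler Labeler identifier recorded on every touched cell.
#' @return The updated [AnnotationSession-class]; labeled + unlabeled counts
#'   always total n.
#' @export
batchAssign <- function(session, clusterLabelMap = character(),
                        overrides = character(), labeler = "expert") {
  stopifnot(is(session, "AnnotationSession"))
  allowed <- allowedLabels(session@metadata, session@taxonomy,
                           session@constraints)
  labels <- session@labels
  prov <- session@provenance
  who <- session@labeler
  if (length(clusterLabelMap)) {
    cl <- as.integer(names(clusterLabelMap))
    if (anyNA(cl)) stop("cluster ids must be integer-valued")
    unknown <- setdiff(cl, unique(session@clusters))
    if (length(unknown)) {
      stop("unknown cluster id(s): ", paste(unknown, collapse = ", "))
    }
    for (k in seq_along(cl)) {
      hit <- session@clusters == cl[k]
      labels[hit] <- clusterLabelMap[[k]]
      prov[hit] <- "batch"
      who[hit] <- labeler
    }
  }
  if (length(overrides)) {
    pos <- match(names(overrides), session@cellIds)
    if (anyNA(pos)) {
      stop("override names unknown cell(s): ",
           paste(names(overrides)[is.na(pos)], collapse = ", "))
    }
    labels[pos] <- unname(overrides)
    prov[pos] <- "override"
    who[pos] <- labeler
  }
  newly <- !is.na(labels)
  badLab <- newly & !(labels %in% allowed)
  if (any(badLab)) {
    first <- which(badLab)[1]
    stop(sprintf("label '%s' is disallowed for cell '%s'; no labels assigned",
                 labels[first], session@cellIds[first]))
  }
  out <- session
  out@labels <- labels
  out@provenance <- prov
  out@labeler <- who
  validObject(out)
  out
}

#' Inter-labeler mismatch rate with QC flag
#'
#' Compares two labelings over their shared cell ids. The QC flag is raised
#' only when the disagreement rate strictly exceeds 5%: 5 disagreements in
#' 100 pass, 6 do not.
#'
#' @param labelsA,labelsB Named character vectors (cell id -> label); both
#'   must label every compared cell.
#' @return List with `rate`, `qcFlag`, and `nCompared`.
#' @export
labelerMismatch <- function(labelsA, labelsB) {
  if (is.null(names(labelsA)) || is.null(names(labelsB))) {
    stop("labelings must be named by cell id")
  }
  shared <- intersect(names(labelsA), names(labelsB))
  a <- labelsA[shared]
  b <- labelsB[shared]
  keep <- !is.na(a) & !is.na(b)
  shared <- shared[keep]
  if (length(shared) == 0L) {
    stop("no labeled cells are shared between the two labelings")
  }
  rate <- mean(a[shared] != b[shared])
  list(rate = rate, qcFlag = rate > 0.05, nCompared = length(shared))
}

#' Mine hard examples from a weaker model's mistakes
#'
#' Per true class, selects cells the weak model misclassified, ranked by the
#' weak model's confidence in its wrong call (most confident first) and
#' truncated to the per-class quota — the active-learning step used to
#' rebalance training sets.
#'
#' @param trueLabels Character vector of ground-truth classes.
#' @param weakScores n x K score matrix from the weak model (class-name
#'   columns); the prediction is the argmax and the confidence its score.
#' @param perClassQuota Non-negative quota; scalar, or named by true class.
#' @param cellIds Optional ids to return (default positional ids).
#' @return Character vector of selected cell ids.
#' @export
mineHardExamples <- function(trueLabels, weakScores, perClassQuota,
                             cellIds = sprintf("cell%07d", seq_along(trueLabels))) {
  weakScores <- as.matrix(weakScores)
  if (length(trueLabels) != nrow(weakScores) ||
      length(cellIds) != nrow(weakScores)) {
    stop("predictions must align with records")
  }
  if (any(perClassQuota < 0)) stop("quota must be non-negative")
  if (nrow(weakScores) == 0L) return(character())
  cls <- colnames(weakScores)
  if (is.null(cls)) stop("weakScores must carry class-name columns")
  predIdx <- max.col(weakScores, ties.method = "first")
  pred <- cls[predIdx]
  conf <- weakScores[cbind(seq_len(nrow(weakScores)), predIdx)]
  wrong <- pred != trueLabels
  selected <- character()
  for (cl in unique(trueLabels)) {
    quota <- if (length(perClassQuota) == 1L && is.null(names(perClassQuota))) {
      perClassQuota
    } else if (cl %in% names(perClassQuota)) {
      perClassQuota[[cl]]
    } else {
      0
    }
    hit <- which(wrong & trueLabels == cl)
    hit <- hit[order(conf[hit], decreasing = TRUE)]
    selected <- c(selected, cellIds[head(hit, quota)])
  }
  selected
}

#' Suggest labels by morphological proximity to labeled cells
#'
#' Nearest-labeled-neighbour suggestions with a distance ceiling: an
#' unlabeled cell inherits a suggestion from its closest labeled cell only
#' when that distance is below the ceiling (default: the 90th percentile of
#' within-cluster pairwise distances). Suggestions are advisory; they carry
#' no provenance until confirmed through [batchAssign()].
#'
#' @param session An [AnnotationSession-class] with at least one labeled
#'   cell.
#' @param maxDistance Optional ceiling; computed from the session when NULL.
#' @return Named character vector of suggestions (NA where none applies).
#' @export
suggestLabels <- function(session, maxDistance = NULL) {
  stopifnot(is(session, "AnnotationSession"))
  labeled <- which(!is.na(session@labels))
  if (length(labeled) == 0L) stop("session has no labeled cells")
  emb <- session@embedding
  if (is.null(maxDistance)) {
    within <- numeric()
    for (k in unique(session@clusters)) {
      idx <- which(session@clusters == k)
      if (length(idx) >= 2L) {
        within <- c(within, as.numeric(dist(emb[idx, , drop = FALSE])))
      }
    }
    maxDistance <- if (length(within)) quantile(within, 0.9, names = FALSE) else Inf
  }
  unlabeled <- which(is.na(session@labels))
  out <- setNames(rep(NA_character_, length(unlabeled)),
                  session@cellIds[unlabeled])
  if (length(unlabeled)) {
    lm <- emb[labeled, , drop = FALSE]
    for (i in seq_along(unlabeled)) {
      dd <- sqrt(colSums((t(lm) - emb[unlabeled[i], ])^2))
      j <- which.min(dd)
      if (dd[j] <= maxDistance) out[i] <- session@labels[labeled[j]]
    }
  }
  out
}
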