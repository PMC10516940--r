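## Independent oracles and small fixture builders shared across tests.

## Mann-Whitney pair-ordering statistic: brute force over all
## (target, background) pairs, half credit for ties.
bruteForceAUC <- function(targetScores, backgroundScores) {
  tot <- 0
  for (t in targetScores) {
    tot <- tot + sum(t > backgroundScores) + 0.5 * sum(t == backgroundScores)
  }
  tot / (length(targetScores) * length(backgroundScores))
}

## Two well-separated Gaussian blobs in d dimensions (default separation
## 20 x spread makes misassignment probability negligible).
twoBlobEmbeddings <- function(nPerBlob = 200, d = 5, spread = 1,
                              separation = 20, seed = 42) {
  centroids <- rbind(A = rep(0, d), B = c(separation * spread, rep(0, d - 1)))
  labels <- rep(c("A", "B"), each = nPerBlob)
  list(embeddings = sampleEmbeddings(centroids, spread, labels, seed),
       labels = labels, centroids = centroids)
}

## A tiny hand-buildable cohort from explicit score rows.
cohortFromScores <- function(trueLabel, scores) {
  CellCohort(sprintf("c%03d", seq_along(trueLabel)), trueLabel, scores)
}

## Small taxonomy + fetal-cell constraint used by annotation tests.
bloodTaxonomy <- function() {
  LabelTaxonomy(c("cell", "PBMC", "fnRBC", "NSCLC", "HCC"),
                parent = c(PBMC = "cell", fnRBC = "cell", NSCLC = "cell",
                           HCC = "cell"))
}

fetalConstraint <- function() {
  LabelConstraint(when = list(donor_status = "adult_non_pregnant"),
                  disallow = "fnRBC")
}
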