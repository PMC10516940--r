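test_that("quality filtering removes exactly the quality-class cells", {
  K <- c("target", "background", "debris", "out_of_focus")
  sc <- matrix(0.25, 10, 4, dimnames = list(NULL, K))
  lab <- c(rep("target", 4), rep("debris", 3), rep("background", 3))
  co <- cohortFromScores(lab, sc)

  kept <- filterEvaluable(co, c("debris", "out_of_focus"))
  expect_equal(nCells(kept), 7L)
  expect_identical(trueLabels(kept), lab[lab != "debris"])
  # order preserved, input untouched
  expect_equal(nCells(co), 10L)

  noQ <- cohortFromScores(rep(c("target", "background"), 3),
                          matrix(0.5, 6, 2, dimnames = list(NULL, c("target", "background"))))
  expect_identical(cellIds(filterEvaluable(noQ, character())), cellIds(noQ))

  expect_error(filterEvaluable(co, "clumps"), "not among cohort classes")
})

test_that("the quality preset yields the expected evaluable fraction", {
  m <- ScoreModel(c("target", "background", "debris", "out_of_focus"),
                  separability = 4)
  co <- sampleCohort(m, circulatingPreset(), 10000, seed = 21)
  kept <- filterEvaluable(co)
  frac <- nCells(kept) / nCells(co)
  expect_lt(abs(frac - 0.5442), 3 * sqrt(0.5442 * (1 - 0.5442) / 10000))
})

test_that("selection scores implement positive and negative gating", {
  K <- c("T", "B")
  co <- cohortFromScores("T", matrix(c(0.8, 0.2), 1, dimnames = list(NULL, K)))
  expect_equal(selectionScores(co, "positive", "T"), 0.8)

  K3 <- c("T", "B1", "B2")
  co3 <- cohortFromScores("T", matrix(c(0.1, 0.6, 0.3), 1,
                                      dimnames = list(NULL, K3)))
  expect_equal(selectionScores(co3, "negative", "T"), 1 - 0.6)

  expect_error(selectionScores(co3, "positive", "T", backgroundClasses = c("T", "B1")),
               "overlap")

  # well-separated cohort: both modes produce the same cell ranking
  m <- ScoreModel(c("T", "B"), separability = 8)
  mix <- MixtureSpec(c(T = 0.5, B = 0.5), "T")
  co4 <- sampleCohort(m, mix, 500, seed = 31)
  pos <- selectionScores(co4, "positive", "T")
  neg <- selectionScores(co4, "negative", "T")
  expect_identical(order(pos), order(neg))  # K = 2: 1 - s_B = s_T
  # and the score supports are disjoint between the classes
  isT <- trueLabels(co4) == "T"
  expect_gt(min(pos[isT]), max(pos[!isT]))
})

test_that("ROC curves match hand-computed and brute-force pair statistics", {
  r <- rocCurve(c(0.9, 0.4), c(0.6, 0.1))
  expect_equal(aucOf(r), 0.75)
  expect_equal(r@tpr[1], 0); expect_equal(r@fpr[1], 0)
  expect_equal(tail(r@tpr, 1), 1); expect_equal(tail(r@fpr, 1), 1)

  # identical score multisets: chance-level AUC
  expect_equal(aucOf(rocCurve(c(0.2, 0.5, 0.9), c(0.2, 0.5, 0.9))), 0.5)
  # perfect separation
  expect_equal(aucOf(rocCurve(c(0.8, 0.9), c(0.1, 0.2))), 1)

  expect_error(rocCurve(numeric(), c(1)), "non-empty")

  # property: trapezoidal AUC equals the Mann-Whitney statistic, with ties
  set.seed(77)
  for (rep in 1:20) {
    nT <- sample(2:60, 1)
    nB <- sample(2:60, 1)
    # coarse rounding forces heavy ties
    tS <- round(runif(nT), 1)
    bS <- round(runif(nB), 1)
    expect_equal(aucOf(rocCurve(tS, bS)), bruteForceAUC(tS, bS),
                 tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(19)
  tS <- rnorm(300, 1); bS <- rnorm(400)
  ours <- aucOf(rocCurve(tS, bS))
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), c(300, 400)), predictor = c(tS, bS),
    quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("mixture reweighting follows the precision formula", {
  # hand-built ROC: TPR=1, FPR=0.001 at one threshold
  r <- new("ROCCurve", thresholds = c(Inf, 0.5, 0), tpr = c(0, 1, 1),
           fpr = c(0, 0.001, 1), auc = 0.9995)
  pr <- mixturePRCurve(r, 1e-5)
  expect_equal(pr@precision[2], 1e-5 / (1e-5 + (1 - 1e-5) * 1e-3),
               tolerance = 1e-12)
  expect_equal(pr@recall, r@tpr)
  # degenerate all-negative threshold: precision 1 by convention
  expect_equal(pr@precision[1], 1)

  # perfect point: TPR=1, FPR=0 -> precision 1, recall 1
  rp <- new("ROCCurve", thresholds = c(Inf, 0.5, 0), tpr = c(0, 1, 1),
            fpr = c(0, 0, 1), auc = 1)
  prp <- mixturePRCurve(rp, 0.01)
  expect_equal(prp@precision[2], 1)
  expect_equal(prp@recall[2], 1)

  expect_error(mixturePRCurve(r, 0), "outside")
  expect_error(mixturePRCurve(r, 1), "outside")

  # precision non-increasing as pi -> 0 wherever FPR > 0
  pis <- c(0.1, 0.01, 0.001)
  prec <- sapply(pis, function(p) mixturePRCurve(r, p)@precision[2])
  expect_true(all(diff(prec) <= 0))
})

test_that("reweighted PR curves match an explicitly constructed mixture", {
  m <- ScoreModel(c("target", "background"), separability = 3)
  tS <- sampleScoreVectors(m, "target", 20000, seed = 51)[, "target"]
  bS <- sampleScoreVectors(m, "background", 20000, seed = 52)[, "target"]
  roc <- rocCurve(tS, bS)

  for (pi in c(1e-2, 1e-3)) {
    reweighted <- mixturePRCurve(roc, pi)
    mixed <- resampleMixture(tS, bS, pi, n = 100000, seed = 53)
    emp <- empiricalPRCurve(mixed$scores, mixed$isTarget, pi)
    # compare precision at matched (realized) recalls
    for (rec in c(0.3, 0.5, 0.7, 0.9)) {
      iE <- which(emp@recall >= rec)[1]
      iR <- which(reweighted@recall >= emp@recall[iE])[1]
      pR <- reweighted@precision[iR]
      pE <- emp@precision[iE]
      nCollected <- sum(mixed$scores >= emp@thresholds[iE])
      se <- sqrt(max(pE * (1 - pE), 1e-6) / nCollected)
      expect_lt(abs(pR - pE), 3 * se + 0.01)
    }
  }
})

test_that("confusion matrices count argmax predictions against truth", {
  K <- c("A", "B")
  sc <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.4, 0.6), c(0.1, 0.9))
  colnames(sc) <- K
  co <- cohortFromScores(c("A", "A", "A", "B"), sc)
  cm <- confusionCounts(co, character())
  expect_identical(unname(cm@counts), rbind(c(2L, 1L), c(0L, 1L)))
  expect_equal(unname(cm@fractions["A", ]), c(2 / 3, 1 / 3))
  expect_equal(sum(cm@counts), nCells(co))

  # identity diagonal when every argmax matches
  perf <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  colnames(perf) <- K
  cmp <- confusionCounts(cohortFromScores(c("A", "B"), perf), character())
  expect_identical(unname(cmp@counts), diag(1L, 2))

  # permutation invariance
  idx <- c(3, 1, 4, 2)
  expect_identical(confusionCounts(co[idx], character())@counts, cm@counts)

  # all cells filtered out -> labeled error
  allQ <- cohortFromScores(rep("debris", 3),
                           matrix(1 / 3, 3, 3,
                                  dimnames = list(NULL, c("A", "B", "debris"))))
  expect_error(confusionCounts(allQ, "debris"), "no evaluable cells")
})

test_that("argmax ties prefer the alphabetically first class", {
  sc <- matrix(c(0.5, 0.5), 2, 2, dimnames = list(NULL, c("zeta", "alpha")))
  co <- cohortFromScores(c("zeta", "alpha"), sc)
  cm <- confusionCounts(co, character())
  expect_equal(sum(cm@counts[, "alpha"]), 2L)
  expect_equal(sum(cm@counts[, "zeta"]), 0L)
})

test_that("operating points maximise recall under a precision floor", {
  perfect <- new("ROCCurve", thresholds = c(Inf, 0.5, 0), tpr = c(0, 1, 1),
                 fpr = c(0, 0, 1), auc = 1)
  op <- operatingPoint(mixturePRCurve(perfect, 0.01), 0.7)
  expect_true(op@attainable)
  expect_equal(op@recall, 1)

  weak <- new("PRCurve", thresholds = 0.5, precision = 0.5, recall = 1,
              fpr = 0.5, mixturePi = 0.5)
  opW <- operatingPoint(weak, 0.7)
  expect_false(opW@attainable)

  # monotonicity: raising the floor never increases recall
  set.seed(123)
  for (rep in 1:10) {
    m <- ScoreModel(c("t", "b"), separability = runif(1, 0.5, 4))
    tS <- sampleScoreVectors(m, "t", 400, seed = rep)[, "t"]
    bS <- sampleScoreVectors(m, "b", 400, seed = rep + 100)[, "t"]
    pr <- mixturePRCurve(rocCurve(tS, bS), 0.05)
    floors <- c(0.2, 0.4, 0.6, 0.8, 0.95)
    recalls <- vapply(floors, function(f) {
      op <- operatingPoint(pr, f)
      if (op@attainable) op@recall else 0
    }, 0)
    expect_true(all(diff(recalls) <= 0))
  }
})
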