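test_that("score vectors live on the simplex, are seeded, and flag bad input", {
  m <- ScoreModel(c("target", "background", "debris"), separability = 4)

  s <- sampleScoreVectors(m, "target", 500, seed = 7)
  expect_equal(dim(s), c(500L, 3L))
  expect_true(all(abs(rowSums(s) - 1) <= 1e-9))
  expect_true(all(s >= 0))

  # bit-identical reproducibility
  expect_identical(s, sampleScoreVectors(m, "target", 500, seed = 7))
  expect_false(identical(s, sampleScoreVectors(m, "target", 500, seed = 8)))

  # empty case keeps K columns
  e <- sampleScoreVectors(m, "target", 0, seed = 1)
  expect_equal(dim(e), c(0L, 3L))
  expect_identical(colnames(e), classNames(m))

  expect_error(sampleScoreVectors(m, "nope", 5, 1), "unknown class label")
  expect_error(sampleScoreVectors(m, "target", -1, 1), "non-negative")
})

test_that("separability 0 makes classes exchangeable; large margins recover the label", {
  m0 <- ScoreModel(c("a", "b", "c", "d"), separability = 0)
  s0 <- sampleScoreVectors(m0, "b", 10000, seed = 3)
  # per-class mean ~ 1/K within 3 Monte-Carlo SE
  mcSE <- apply(s0, 2, sd) / sqrt(nrow(s0))
  expect_true(all(abs(colMeans(s0) - 0.25) <= 3 * mcSE))

  mBig <- ScoreModel(c("target", "b", "c", "d"), separability = 10)
  sBig <- sampleScoreVectors(mBig, "target", 1000, seed = 3)
  hit <- mean(colnames(sBig)[max.col(sBig)] == "target")
  expect_gt(hit, 0.99)
})

test_that("one-vs-rest AUC is non-decreasing in separability (common random numbers)", {
  seps <- c(0, 0.5, 1, 2, 4, 8)
  aucs <- vapply(seps, function(sep) {
    m <- ScoreModel(c("target", "background"), separability = sep)
    tS <- sampleScoreVectors(m, "target", 2000, seed = 101)[, "target"]
    bS <- sampleScoreVectors(m, "background", 2000, seed = 202)[, "target"]
    aucOf(rocCurve(tS, bS))
  }, 0)
  expect_true(all(diff(aucs) >= 0))
  expect_equal(aucs[1], 0.5, tolerance = 0.05)
})

test_that("cohorts follow the mixture proportions and are reproducible", {
  m <- ScoreModel(c("target", "background"), separability = 4)

  expect_equal(nCells(sampleCohort(m, MixtureSpec(c(target = 0.5, background = 0.5),
                                                  "target"), 0, 1)), 0L)

  mixHalf <- MixtureSpec(c(target = 0.5, background = 0.5), "target")
  co <- sampleCohort(m, mixHalf, 100000, seed = 6)
  nT <- sum(trueLabels(co) == "target")
  expect_lt(abs(nT - 50000), 3 * sqrt(100000 * 0.25))

  # 1:1000 rare-target composition
  mixRare <- MixtureSpec(c(target = 1e-3, background = 0.999), "target")
  coR <- sampleCohort(m, mixRare, 100000, seed = 6)
  nTR <- sum(trueLabels(coR) == "target")
  expect_lt(abs(nTR - 100), 3 * sqrt(100000 * 1e-3 * 0.999))

  # reproducible; arrival stream is strictly increasing
  co2 <- sampleCohort(m, mixRare, 1000, seed = 9, cellRate = 3000)
  co3 <- sampleCohort(m, mixRare, 1000, seed = 9, cellRate = 3000)
  expect_identical(scoreMatrix(co2), scoreMatrix(co3))
  expect_identical(arrivalTimes(co2), arrivalTimes(co3))
  expect_true(all(diff(arrivalTimes(co2)) > 0))

  badMix <- MixtureSpec(c(target = 0.5, background = 0.5), "target")
  badMix@proportions <- c(target = 0.5, background = 0.6)
  expect_error(sampleCohort(m, badMix, 10, 1), "sum to 1")
})

test_that("embedding clouds sit on their centroids and separate cleanly", {
  expect_equal(nrow(sampleEmbeddings(rbind(A = c(0, 0)), 1, character(), 1)), 0L)

  blobs <- twoBlobEmbeddings(nPerBlob = 200, d = 4, spread = 1, separation = 20)
  # nearest-centroid assignment recovers all labels
  d2A <- rowSums((blobs$embeddings - matrix(blobs$centroids["A", ],
                                            400, 4, byrow = TRUE))^2)
  d2B <- rowSums((blobs$embeddings - matrix(blobs$centroids["B", ],
                                            400, 4, byrow = TRUE))^2)
  recovered <- ifelse(d2A < d2B, "A", "B")
  expect_identical(recovered, blobs$labels)

  one <- sampleEmbeddings(rbind(A = c(2, -1, 3)), spread = 1,
                          labels = rep("A", 10000), seed = 8)
  expect_true(all(abs(colMeans(one) - c(2, -1, 3)) <= 3 / sqrt(10000)))

  expect_error(sampleEmbeddings(rbind(A = c(0, 0)), 1, c("A", "Z"), 1),
               "no centroid")
  expect_error(sampleEmbeddings(rbind(A = c(0, 0)), 0, "A", 1), "positive")
})

test_that("allele counts match the mixture expectation", {
  pureAlt <- GenotypePanel(paste0("v", 1:20), gTarget = rep(1, 20),
                           gBackground = rep(1, 20))
  cnt <- sampleAlleleCounts(pureAlt, purity = 1, depth = 100, seed = 4)
  expect_true(all(alleleFractions(cnt) == 1, na.rm = TRUE))

  one <- GenotypePanel("v1", gTarget = 1, gBackground = 0)
  cnt1 <- sampleAlleleCounts(one, purity = 0.3, depth = 10000, seed = 12)
  expect_lt(abs(alleleFractions(cnt1) - 0.30), 3 * sqrt(0.3 * 0.7 / 10000))

  # expectation property across all dosage combinations
  g <- expand.grid(gT = c(0, 0.5, 1), gB = c(0, 0.5, 1))
  panel <- GenotypePanel(sprintf("v%d", seq_len(nrow(g))), g$gT, g$gB)
  p <- 0.37
  cnt2 <- sampleAlleleCounts(panel, p, depth = 20000, seed = 5)
  f <- alleleFractions(cnt2)
  expected <- expectedAlleleFraction(p, g$gT, g$gB)
  se <- sqrt(pmax(expected * (1 - expected), 1e-12) / 20000)
  expect_true(all(abs(f - expected) <= pmax(3 * se, 1e-12) + 1e-9))

  # the printed-style 23% allele-fraction configuration
  hom <- GenotypePanel("tp53", gTarget = 1, gBackground = 0)
  cnt3 <- sampleAlleleCounts(hom, purity = 0.23, depth = 50000, seed = 6)
  expect_lt(abs(alleleFractions(cnt3) - 0.23), 3 * sqrt(0.23 * 0.77 / 50000))

  expect_error(GenotypePanel("v1", gTarget = 0.3, gBackground = 0),
               "dosages")
})

test_that("the circulating-cell preset carries the documented quality fractions", {
  mix <- circulatingPreset()
  expect_equal(unname(mix@proportions[["out_of_focus"]]), 0.3901)
  expect_equal(unname(mix@proportions[["debris"]]), 0.0657)
  expect_equal(sum(mix@proportions), 1)
})
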