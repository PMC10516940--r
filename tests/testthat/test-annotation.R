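test_that("agglomerative clustering separates well-spaced blobs perfectly", {
  skip_if_not_installed("mclust")
  blobs <- twoBlobEmbeddings(nPerBlob = 200, d = 5, spread = 1, separation = 20)
  cl <- hierarchicalClusters(blobs$embeddings, nClusters = 2)
  ari <- mclust::adjustedRandIndex(cl$clusters, blobs$labels)
  expect_equal(ari, 1)
  expect_identical(sort(unique(cl$clusters)), 1:2)
})

test_that("clustering handles degenerate cuts, sizes and bad input", {
  expect_identical(hierarchicalClusters(matrix(1, 1, 3), nClusters = 1)$clusters, 1L)

  emb <- matrix(rnorm(30), 10, 3)
  # distance cut at 0: every distinct point its own cluster
  cl0 <- hierarchicalClusters(emb, distanceCut = 0)
  expect_equal(length(unique(cl0$clusters)), 10L)

  expect_error(hierarchicalClusters(emb, nClusters = 11), "exceeds")
  expect_error(hierarchicalClusters(emb), "exactly one")
  expect_error(hierarchicalClusters(emb, nClusters = 2, distanceCut = 1),
               "exactly one")

  # determinism
  expect_identical(hierarchicalClusters(emb, nClusters = 3)$clusters,
                   hierarchicalClusters(emb, nClusters = 3)$clusters)

  # cosine metric runs and yields a dense assignment
  clC <- hierarchicalClusters(emb, nClusters = 3, metric = "cosine")
  expect_identical(sort(unique(clC$clusters)), 1:3)
})

test_that("metadata constraints restrict the allowed label set", {
  tax <- bloodTaxonomy()
  con <- fetalConstraint()

  allowed <- allowedLabels(list(donor_status = "adult_non_pregnant"), tax,
                           list(con))
  expect_false("fnRBC" %in% allowed)
  expect_true(all(c("PBMC", "NSCLC", "HCC") %in% allowed))

  # non-matching metadata: full taxonomy
  expect_setequal(allowedLabels(list(donor_status = "pregnant"), tax,
                                list(con)), tax@labels)
  expect_setequal(allowedLabels(list(), tax), tax@labels)

  # overlapping disallowed sets: union semantics
  con2 <- LabelConstraint(list(donor_status = "adult_non_pregnant"),
                          c("fnRBC", "HCC"))
  a2 <- allowedLabels(list(donor_status = "adult_non_pregnant"), tax,
                      list(con, con2))
  expect_setequal(a2, setdiff(tax@labels, c("fnRBC", "HCC")))

  expect_error(allowedLabels(list(site = "x"), tax, list(con)),
               "unknown metadata field")
  expect_error(allowedLabels(list(donor_status = "x"), tax,
                             list(LabelConstraint(list(donor_status = "x"),
                                                  "made_up"))),
               "unknown label")
})

test_that("taxonomies know their lineage and reject cycles", {
  tax <- bloodTaxonomy()
  expect_identical(lineagePath(tax, "fnRBC"), c("fnRBC", "cell"))
  expect_error(lineagePath(tax, "zzz"), "unknown label")
  expect_error(LabelTaxonomy(c("a", "b"), parent = c(a = "b", b = "a")),
               "cycle")
})

newSession <- function(n = 60, seed = 91) {
  blobs <- twoBlobEmbeddings(nPerBlob = n / 2, d = 3, spread = 1,
                             separation = 20, seed = seed)
  cl <- hierarchicalClusters(blobs$embeddings, nClusters = 2)
  AnnotationSession(sprintf("cell%03d", seq_len(n)), blobs$embeddings,
                    cl$clusters, bloodTaxonomy(),
                    constraints = list(fetalConstraint()),
                    metadata = list(donor_status = "adult_non_pregnant"))
}

test_that("batch assignment labels clusters, honors overrides, and is atomic", {
  s <- newSession()
  k1 <- sum(s@clusters == 1)

  s1 <- batchAssign(s, clusterLabelMap = c("1" = "PBMC"))
  expect_equal(sum(sessionLabels(s1) == "PBMC", na.rm = TRUE), k1)
  expect_equal(sum(sessionProvenance(s1) == "batch", na.rm = TRUE), k1)
  expect_equal(sum(!is.na(sessionLabels(s1))) + sum(is.na(sessionLabels(s1))),
               nCells(s1))

  # one override inside the batch
  victim <- cellIds(s)[which(s@clusters == 1)[1]]
  s2 <- batchAssign(s, clusterLabelMap = c("1" = "PBMC"),
                    overrides = setNames("NSCLC", victim))
  expect_equal(unname(sessionLabels(s2)[victim]), "NSCLC")
  expect_equal(sum(sessionProvenance(s2) == "batch", na.rm = TRUE), k1 - 1)
  expect_equal(sum(sessionProvenance(s2) == "override", na.rm = TRUE), 1L)

  # constrained label rejected atomically, naming the cell
  expect_error(batchAssign(s, clusterLabelMap = c("1" = "fnRBC")),
               "disallowed for cell 'cell001'")
  expect_error(batchAssign(s, overrides = setNames("fnRBC", victim)),
               "disallowed")
  # the failed call left no partial assignment
  expect_true(all(is.na(sessionLabels(s))))

  # idempotence
  s3 <- batchAssign(s1, clusterLabelMap = c("1" = "PBMC"))
  expect_identical(sessionLabels(s3), sessionLabels(s1))
  expect_identical(sessionProvenance(s3), sessionProvenance(s1))

  expect_error(batchAssign(s, clusterLabelMap = c("9" = "PBMC")),
               "unknown cluster")
})

test_that("no emitted annotation ever violates an active constraint", {
  tax <- bloodTaxonomy()
  withSeed(97, {
    for (trial in 1:15) {
      n <- sample(10:40, 1)
      emb <- matrix(rnorm(n * 3), n, 3)
      k <- sample(1:4, 1)
      cl <- hierarchicalClusters(emb, nClusters = min(k, n))
      s <- AnnotationSession(sprintf("c%02d", 1:n), emb, cl$clusters, tax,
                             constraints = list(fetalConstraint()),
                             metadata = list(donor_status = "adult_non_pregnant"))
      labs <- sample(tax@labels, length(unique(cl$clusters)), replace = TRUE)
      map <- setNames(labs, as.character(seq_along(labs)))
      res <- try(batchAssign(s, map), silent = TRUE)
      if (inherits(res, "try-error")) {
        expect_true(any(labs == "fnRBC"))
      } else {
        got <- sessionLabels(res)
        expect_false(any(got == "fnRBC", na.rm = TRUE))
      }
    }
  })
})

test_that("labeler mismatch applies the strict 5% rule and is symmetric", {
  ids <- sprintf("c%03d", 1:100)
  a <- setNames(rep("PBMC", 100), ids)

  bSame <- a
  expect_equal(labelerMismatch(a, bSame), list(rate = 0, qcFlag = FALSE,
                                               nCompared = 100L))

  b5 <- a; b5[1:5] <- "NSCLC"
  r5 <- labelerMismatch(a, b5)
  expect_equal(r5$rate, 0.05)
  expect_false(r5$qcFlag)

  b6 <- a; b6[1:6] <- "NSCLC"
  r6 <- labelerMismatch(a, b6)
  expect_equal(r6$rate, 0.06)
  expect_true(r6$qcFlag)

  expect_identical(labelerMismatch(b6, a), r6)

  expect_error(labelerMismatch(a, setNames("PBMC", "other")), "no labeled cells")
})

test_that("hard-example mining ranks confident mistakes first", {
  K <- c("A", "B")
  expect_identical(
    mineHardExamples(c("A", "B"),
                     rbind(c(0.9, 0.1), c(0.2, 0.8)) |> `colnames<-`(K), 5),
    character())

  # 10 wrong of 100, quota 5: five most confident mistakes selected
  withSeed(98, {
    truth <- rep("A", 100)
    conf <- runif(100, 0.5, 1)
    scores <- cbind(A = 1 - conf, B = conf)       # all predict B
    scores[11:100, ] <- cbind(conf[11:100], 1 - conf[11:100])  # 90 correct
    colnames(scores) <- K
    ids <- sprintf("c%03d", 1:100)
    sel <- mineHardExamples(truth, scores, 5, cellIds = ids)
    expect_length(sel, 5)
    wrongIdx <- 1:10
    expect_true(all(sel %in% ids[wrongIdx]))
    selConf <- conf[match(sel, ids)]
    expect_true(all(diff(selConf) <= 0))
    expect_setequal(sel, ids[wrongIdx][rank(-conf[wrongIdx]) <= 5])
  })

  expect_error(mineHardExamples("A", matrix(1, 1, 2,
                                            dimnames = list(NULL, K)), -1),
               "non-negative")
})

test_that("label suggestions respect the distance ceiling", {
  s <- newSession()
  s1 <- batchAssign(s, clusterLabelMap = c("1" = "PBMC"))
  sug <- suggestLabels(s1)
  # cluster 2 sits 20 spreads away: no suggestion crosses the ceiling
  expect_true(all(is.na(sug)))
  sugWide <- suggestLabels(s1, maxDistance = Inf)
  expect_true(all(sugWide == "PBMC"))
})
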