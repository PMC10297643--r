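test_that("fold sizes, disjointness and stratification follow the protocol", {
  f10 <- makeFolds(rep(0:1, 5), k = 5, seed = 1)
  expect_equal(unname(lengths(f10$folds)), rep(2L, 5))
  # 1396 cases with the study's 716/680 class split
  labels <- c(rep(0L, 716), rep(1L, 680))
  fs <- makeFolds(labels, k = 5, seed = 9)
  expect_equal(sort(unname(lengths(fs$folds)), decreasing = TRUE),
               c(280L, 279L, 279L, 279L, 279L))
  expect_equal(sort(unname(unlist(fs$folds))), 1:1396)
  counts <- sapply(fs$folds, function(ids) sum(labels[ids]))
  expect_lte(max(counts) - min(counts), 1L)
  # reproducible per seed, different across seeds
  expect_identical(fs$folds, makeFolds(labels, k = 5, seed = 9)$folds)
  expect_false(identical(fs$folds, makeFolds(labels, k = 5, seed = 10)$folds))
  expect_error(makeFolds(c(0, 1), k = 5), "at least")
})

test_that("6 positives and 4 negatives at k = 2 stratify exactly", {
  labels <- c(rep(1L, 6), rep(0L, 4))
  fs <- makeFolds(labels, k = 2, seed = 3)
  for (ids in fs$folds) {
    expect_equal(sum(labels[ids] == 1), 3L)
    expect_equal(sum(labels[ids] == 0), 2L)
  }
})

test_that("confusion metrics reproduce the published count-derived values", {
  # cascade model row: tp 548, tn 654, fp 62, fn 132
  m <- computeMetrics(confusionCounts(548, 654, 62, 132))
  r4 <- function(x) cpcnn:::roundHalfUp(x, 4)
  expect_equal(r4(m$acc), 0.861)
  expect_equal(r4(m$pre), 0.8984)
  expect_equal(r4(m$recall), 0.8059)
  expect_equal(r4(m$spe), 0.9134)
  expect_equal(r4(m$f1), 0.8496)
  # low-resolution single-tier row: tp 558 / fn 122, tn 627 / fp 89
  m2 <- computeMetrics(confusionCounts(558, 627, 89, 122))
  expect_equal(r4(m2$recall), 0.8206)
  expect_equal(r4(m2$spe), 0.8757)
  expect_equal(r4(m2$pre), 0.8624)
  expect_equal(cpcnn:::roundHalfUp(m2$f1, 3), 0.841)
  # mid-resolution single-tier row: only tn 633 / fp 83 are self-consistent
  expect_equal(r4(computeMetrics(confusionCounts(1, 633, 83, 1))$spe), 0.8841)
})

test_that("published baseline-network rows with consistent counts reproduce all five metrics", {
  rows <- list(  #        tp   tn   fp   fn   acc    pre    rec    spe    f1
    efficientnet_b0 = c(581, 489, 227,  99, 0.7665, 0.7191, 0.8544, 0.683, 0.7809),
    efficientnet_b1 = c(584, 482, 234,  96, 0.7636, 0.7139, 0.8588, 0.6732, 0.7797),
    mobilenet       = c(536, 552, 164, 144, 0.7794, 0.7657, 0.7882, 0.7709, 0.7768),
    resnet34        = c(574, 556, 160, 106, 0.8095, 0.782,  0.8441, 0.7765, 0.8119),
    vgg             = c(560, 572, 144, 120, 0.8109, 0.7955, 0.8235, 0.7989, 0.8092))
  for (nm in names(rows)) {
    r <- rows[[nm]]
    expect_equal(r[1] + r[2] + r[3] + r[4], 1396, label = nm)
    m <- computeMetrics(confusionCounts(r[1], r[2], r[3], r[4]))
    got <- cpcnn:::roundHalfUp(unlist(m[c("acc", "pre", "recall", "spe", "f1")]), 4)
    expect_equal(unname(got), unname(round(r[5:9], 4)), label = nm)
  }
})

test_that("degenerate counts yield symmetric or undefined metrics, never 0 by fiat", {
  m <- computeMetrics(confusionCounts(1, 1, 1, 1))
  expect_equal(unlist(m[c("acc", "pre", "recall", "spe", "f1")]),
               c(acc = 0.5, pre = 0.5, recall = 0.5, spe = 0.5, f1 = 0.5))
  expect_equal(m$undefined, character(0))
  noPos <- computeMetrics(confusionCounts(0, 5, 0, 0))
  expect_true(is.na(noPos$pre))
  expect_true(is.na(noPos$recall))
  expect_setequal(noPos$undefined, c("pre", "recall", "f1"))
})

test_that("reader precision is the exact percentage of correct reads", {
  expect_equal(precisionFromCounts(181, 200), 90.5)
  expect_equal(precisionFromCounts(195, 200), 97.5)
  expect_equal(precisionFromCounts(191, 200), 95.5)
  expect_equal(precisionFromCounts(0, 200), 0)
  expect_error(precisionFromCounts(201, 200), "correct <= total")
  expect_error(precisionFromCounts(1, 0), "total > 0")
})

test_that("trapezoid AUC equals the pairwise Mann-Whitney oracle", {
  mannWhitney <- function(labels, scores) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  expect_equal(rocAuc(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2))$auc, 0.75)
  expect_equal(rocAuc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(rocAuc(c(0, 1, 0, 1), rep(0.4, 4))$auc, 0.5)
  withSeed(77, {
    for (i in 1:200) {
      n <- sample(4:30, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
      expect_lt(abs(rocAuc(labels, scores)$auc - mannWhitney(labels, scores)),
                1e-9)
    }
  })
})

test_that("the ROC curve runs from (0,0) to (1,1) with non-decreasing rates", {
  withSeed(5, {
    roc <- rocAuc(sample(0:1, 50, replace = TRUE, prob = c(.4, .6)), runif(50))
    expect_equal(unlist(roc$points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(roc$points[nrow(roc$points), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(roc$points$fpr) >= 0))
    expect_true(all(diff(roc$points$tpr) >= 0))
  })
  expect_error(rocAuc(c(1, 1), c(0.3, 0.4)), "negative")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withSeed(31, {
    for (i in 1:5) {
      labels <- c(0, 1, sample(0:1, 40, replace = TRUE))
      scores <- round(runif(42), 2)
      ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                   direction = "<")))
      expect_equal(rocAuc(labels, scores)$auc, ref, tolerance = 1e-12)
    }
  })
})

test_that("localization hits require the peak inside the dilated mask", {
  mask <- matrix(0L, 40, 80); mask[20, 30:40] <- 1L
  hitMap <- matrix(0, 40, 80); hitMap[22, 35] <- 1
  expect_true(localizationScore(hitMap, mask))
  nearMap <- matrix(0, 40, 80); nearMap[28, 35] <- 1   # 8 px away
  expect_true(localizationScore(nearMap, mask))
  farMap <- matrix(0, 40, 80); farMap[35, 70] <- 1
  expect_false(localizationScore(farMap, mask))
  # uniform map: argmax ties break to the first column-major index (1, 1)
  expect_false(localizationScore(matrix(1, 40, 80), mask))
  maskAtOrigin <- matrix(0L, 40, 80); maskAtOrigin[3, 4] <- 1L
  expect_true(localizationScore(matrix(1, 40, 80), maskAtOrigin))
  expect_error(localizationScore(hitMap, matrix(0L, 40, 80)), "empty")
})

test_that("random-map hit rate matches the dilated-mask area fraction", {
  mask <- matrix(0L, 30, 60)
  mask[14:16, 20:35] <- 1L
  # oracle: fraction of pixels within 9 px (Euclidean) of the mask
  fg <- which(mask > 0, arr.ind = TRUE)
  inside <- outer(seq_len(30), seq_len(60), function(r, c) {
    m <- Inf
    for (k in seq_len(nrow(fg)))
      m <- pmin(m, (r - fg[k, 1])^2 + (c - fg[k, 2])^2)
    m <= 81
  })
  pHit <- mean(inside)
  hits <- withSeed(99, vapply(1:1000, function(i)
    localizationScore(matrix(runif(30 * 60), 30, 60), mask), logical(1)))
  se <- sqrt(pHit * (1 - pHit) / 1000)
  expect_lt(abs(mean(hits) - pHit), 3 * se)
})

test_that("cross-validation rotates folds, pools the whole dataset, and averages", {
  labels <- rep(c(0L, 1L), 30)
  # score oracle: a fixed noisy linear readout of the label, no training
  trainFun <- function(idx) idx
  withSeed(7, {
    noise <- runif(60, -0.3, 0.3)
    scoreFun <- function(model, idx) {
      expect_length(intersect(model, idx), 0)  # never tested on training cases
      pmin(1, pmax(0, labels[idx] * 0.6 + 0.2 + noise[idx]))
    }
    rep <- crossValidate(labels, trainFun, scoreFun, k = 5, seed = 2)
  })
  expect_s3_class(rep, "MetricsReport")
  expect_equal(nrow(rep), 6L)
  per <- rep[rep$fold != "mean", ]
  expect_equal(sum(per$tp + per$tn + per$fp + per$fn), 60)
  expect_equal(rep$acc[rep$fold == "mean"], mean(per$acc))
  expect_equal(rep$auc[rep$fold == "mean"], mean(per$auc))
})

test_that("a constant positive classifier has recall 1 and specificity 0 on every fold", {
  labels <- rep(c(0L, 1L), 10)
  rep <- crossValidate(labels, function(idx) NULL,
                       function(model, idx) rep(1, length(idx)),
                       k = 5, seed = 4)
  per <- rep[rep$fold != "mean", ]
  expect_true(all(per$recall == 1))
  expect_true(all(per$spe == 0))
  expect_true(all(per$auc == 0.5))  # all ties: half credit
})
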