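test_that("confusion counts partition the samples", {
  cc <- confusionCounts(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
                        c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
  expect_identical(cc[c("n_pos", "n_neg", "fn", "fp")],
                   list(n_pos = 5L, n_neg = 5L, fn = 0L, fp = 0L))
  allPos <- confusionCounts(rep(c(1, 0), each = 5), rep(1, 10))
  expect_identical(allPos$fp, 5L)
  expect_identical(allPos$fn, 0L)
  cc3 <- confusionCounts(c(1, 1, 0), c(1, 0, 0))
  expect_identical(cc3[c("n_pos", "n_neg", "fn", "fp")],
                   list(n_pos = 2L, n_neg = 1L, fn = 1L, fp = 0L))
  expect_identical(cc3$n_pos + cc3$n_neg, 3L)
  expect_error(confusionCounts(c(1, 0), c(1)), "length")
  expect_error(confusionCounts(c(1, 2), c(1, 0)), "binary")
})

test_that("metric values match hand-computed confusion cases", {
  perfect <- metricsFromConfusion(confusionCounts(rep(c(1, 0), 5),
                                                  rep(c(1, 0), 5)))
  expect_equal(unlist(perfect[c("Sn", "Sp", "Acc", "MCC", "precision", "F1")]),
               c(Sn = 1, Sp = 1, Acc = 1, MCC = 1, precision = 1, F1 = 1))

  # degenerate all-positive predictor: MCC hits its zero-denominator branch
  expect_warning(
    degen <- metricsFromConfusion(confusionCounts(rep(c(1, 0), each = 5),
                                                  rep(1, 10))),
    "MCC")
  expect_equal(unlist(degen[c("Sn", "Sp", "Acc", "MCC")]),
               c(Sn = 1, Sp = 0, Acc = 0.5, MCC = 0))

  # 32 pos / 34 neg with one error on each side
  cc <- structure(list(n_pos = 32L, n_neg = 34L, fn = 1L, fp = 1L,
                       tp = 31L, tn = 33L), class = "dsite_confusion")
  m <- metricsFromConfusion(cc)
  expect_equal(m$Sn, 0.96875)
  expect_equal(m$Sp, 33 / 34)
  expect_equal(m$Acc, 64 / 66)
  expect_equal(m$MCC, (31 * 33 - 1) / sqrt(32 * 32 * 34 * 34))

  expect_error(metricsFromConfusion(confusionCounts(c(1, 1), c(1, 1))),
               "each class")
})

test_that("count-based metrics equal the standard TP/TN formulation", {
  set.seed(21)
  for (i in 1:200) {
    nPos <- sample(1:60, 1); nNeg <- sample(1:60, 1)
    fn <- sample(0:nPos, 1); fp <- sample(0:nNeg, 1)
    cc <- structure(list(n_pos = nPos, n_neg = nNeg, fn = fn, fp = fp,
                         tp = nPos - fn, tn = nNeg - fp),
                    class = "dsite_confusion")
    std <- standardMetrics(tp = nPos - fn, tn = nNeg - fp, fp = fp, fn = fn)
    m <- suppressWarnings(metricsFromConfusion(cc))
    expect_equal(m$Sn, std$Sn, tolerance = 1e-12)
    expect_equal(m$Sp, std$Sp, tolerance = 1e-12)
    expect_equal(m$Acc, std$Acc, tolerance = 1e-12)
    if (is.finite(std$MCC)) expect_equal(m$MCC, std$MCC, tolerance = 1e-12)
  }
})

test_that("accuracy is the class-weighted mean of Sn and Sp", {
  set.seed(30)
  for (i in 1:50) {
    nPos <- sample(1:50, 1); nNeg <- sample(1:50, 1)
    cc <- structure(list(n_pos = nPos, n_neg = nNeg,
                         fn = sample(0:nPos, 1), fp = sample(0:nNeg, 1)),
                    class = "dsite_confusion")
    cc$tp <- cc$n_pos - cc$fn; cc$tn <- cc$n_neg - cc$fp
    m <- suppressWarnings(metricsFromConfusion(cc))
    expect_equal(m$Acc, (nPos * m$Sn + nNeg * m$Sp) / (nPos + nNeg),
                 tolerance = 1e-12)
  }
})

test_that("ROC/AUC anchors and the pair-counting identity hold", {
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))$auc, 1)
  expect_equal(rocAuc(c(1, 1, 0, 0), rep(0.5, 4))$auc, 0.5)  # no-skill anchor
  expect_equal(rocAuc(c(1, 1, 0, 0), c(0.8, 0.3, 0.5, 0.1))$auc, 0.75)
  expect_error(rocAuc(c(1, 1), c(0.4, 0.2)), "both classes")

  roc <- rocAuc(c(1, 0, 1, 0, 1), c(0.9, 0.9, 0.4, 0.2, 0.2))
  expect_true(all(diff(roc$curve$fpr) >= 0))
  expect_true(all(diff(roc$curve$tpr) >= 0))
  expect_equal(roc$curve$fpr[1], 0)
  expect_equal(roc$curve$tpr[nrow(roc$curve)], 1)

  set.seed(14)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    y <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
    sc <- round(runif(n), sample(1:3, 1))  # rounding forces ties
    expect_equal(rocAuc(y, sc)$auc, aucMannWhitney(y, sc), tolerance = 1e-12)
  }
})

test_that("trapezoid AUC matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (i in 1:10) {
    y <- c(1L, 0L, sample(0:1, 40, replace = TRUE))
    sc <- round(runif(42), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(y, sc)$auc, ref, tolerance = 1e-12)
  }
})

test_that("cross-validation partitions correctly and is replayable", {
  toy <- separableToy(100L, seed = 5L)
  cv <- crossValidate(toy$X, toy$y, modelSpec("RF", seed = 1L),
                      k = 5L, repeats = 5L, seed = 2L)
  expect_identical(nrow(cv$folds), 25L)
  expect_equal(cv$mean[["Acc"]], 1)
  # every sample tested exactly once per repeat
  for (r in 1:5) {
    folds <- cv$assignments[[r]]
    expect_identical(sort(names(folds)), sort(rownames(toy$X)))
    expect_identical(unname(table(factor(folds, 1:5))), rep(20L, 5L),
                     ignore_attr = TRUE)
  }
  expect_identical(cv$config$repeat_seeds, 2L + 0:4)
  cv2 <- crossValidate(toy$X, toy$y, modelSpec("RF", seed = 1L),
                       k = 5L, repeats = 5L, seed = 2L)
  expect_equal(cv$mean, cv2$mean, tolerance = 1e-12)
  expect_equal(cv$folds, cv2$folds, tolerance = 1e-12)
})

test_that("CV aggregate is invariant to input sample order", {
  toy <- separableToy(60L, seed = 8L)
  cv1 <- crossValidate(toy$X, toy$y, modelSpec("LR"), k = 5L, repeats = 2L,
                       seed = 3L)
  perm <- sample(nrow(toy$X))
  cv2 <- crossValidate(toy$X[perm, ], toy$y[perm], modelSpec("LR"), k = 5L,
                       repeats = 2L, seed = 3L)
  # same ids end up in the same folds regardless of presentation order
  expect_identical(cv1$assignments[[1]][sort(names(cv1$assignments[[1]]))],
                   cv2$assignments[[1]][sort(names(cv2$assignments[[1]]))])
  expect_equal(cv1$mean, cv2$mean, tolerance = 1e-12)
})

test_that("CV oversampling expands training folds only", {
  d <- generateDataset(smallSynthConfig(nPos = 15L, nNeg = 30L,
                                        nSpecies = 1L, seed = 3L))
  X <- encodeDataset(d, "NCP")
  cv <- crossValidate(X, siteLabels(d), modelSpec("RF"), k = 3L,
                      repeats = 1L, seed = 1L,
                      oversample = oversampleSpec(seed = 2L))
  # test folds still partition the original 45 samples
  expect_identical(sum(cv$folds$n_test), length(d))
  expect_identical(sort(names(cv$assignments[[1]])), sort(names(d)))
})

test_that("insufficient class support for stratified CV errors", {
  toy <- separableToy(10L)
  expect_error(crossValidate(toy$X, toy$y, "RF", k = 6L), "per class")
})

test_that("independent test guards against training leakage", {
  toy <- separableToy(40L, seed = 4L)   # rows 1:20 positive, 21:40 negative
  trainIdx <- c(1:15, 21:35)
  testIdx <- c(16:20, 36:40)
  m <- fitModel(modelSpec("RF", seed = 1L),
                toy$X[trainIdx, ], toy$y[trainIdx])
  clean <- independentTest(m, toy$X[testIdx, ], toy$y[testIdx])
  expect_true(all(unlist(clean[c("Sn", "Sp", "Acc", "AUC")]) == 1))
  overlap <- c(14:20, 34:40)
  expect_error(independentTest(m, toy$X[overlap, ], toy$y[overlap]),
               "leakage")
  # oversampling provenance is traced back to the ancestor id
  Xdup <- toy$X[testIdx, ]
  rownames(Xdup)[1] <- paste0(rownames(toy$X)[1], "#dup1")
  expect_error(independentTest(m, Xdup, toy$y[testIdx]), "leakage")
})

test_that("null-labelled test sets score near-chance AUC", {
  toy <- separableToy(200L, seed = 10L)   # 1:100 positive, 101:200 negative
  trainIdx <- c(1:50, 101:150)
  testIdx <- c(51:100, 151:200)
  m <- fitModel(modelSpec("RF", seed = 1L),
                toy$X[trainIdx, ], toy$y[trainIdx])
  set.seed(33)
  yShuffled <- sample(toy$y[testIdx])
  res <- suppressWarnings(independentTest(m, toy$X[testIdx, ], yShuffled))
  expect_lt(abs(res$AUC - 0.5), 0.12)   # 3 sigma of the Mann-Whitney null
})
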