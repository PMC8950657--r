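## shared small dataset: two species, clear signal, quick to fit
expDataset <- function(seed = 21L)
  generateDataset(smallSynthConfig(nPos = 20L, nNeg = 30L, nSpecies = 3L,
                                   length = 21L, effectSize = 2,
                                   seed = seed))

test_that("benchmark grid produces one row per encoder-algorithm pair", {
  d <- expDataset()
  g <- gridBenchmark(d, encoders = list("NAC", "NCP"),
                     algorithms = list("RF", "LR"),
                     split = splitSpec(0.2, seed = 3L), seed = 1L)
  expect_identical(nrow(g), 4L)
  expect_setequal(paste(g$encoder, g$algorithm),
                  c("NAC RF", "NAC LR", "NCP RF", "NCP LR"))
  expect_true(all(g$Acc >= 0 & g$Acc <= 1))
  # confusion counts are reported explicitly per cell
  expect_true(all(g$n_pos + g$n_neg == attr(g, "config")$test_n))
  cfg <- attr(g, "config")
  expect_identical(cfg$test_n, as.integer(floor(0.2 * length(d))))

  # replaying from the embedded config reproduces every number
  g2 <- gridBenchmark(d, encoders = list("NAC", "NCP"),
                      algorithms = list("RF", "LR"),
                      split = cfg$split, seed = cfg$seed)
  expect_equal(as.data.frame(g), as.data.frame(g2), tolerance = 1e-12)
})

test_that("oversampling in the grid expands training data only", {
  d <- expDataset()
  split <- splitSpec(0.2, seed = 5L)
  ov <- oversampleSpec(passes = 2L, p = 1, seed = 7L)
  g <- gridBenchmark(d, list("NCP"), list("RF"), split, oversample = ov)
  gPlain <- gridBenchmark(d, list("NCP"), list("RF"), split)
  # test-side geometry identical; only the training side was expanded
  expect_identical(g$n_pos, gPlain$n_pos)
  expect_identical(g$n_neg, gPlain$n_neg)
  part <- partitionDataset(d, split)
  expanded <- oversamplePositives(d[part$train_ids], ov)
  nPosTrain <- sum(siteLabels(d[part$train_ids]) == 1L)
  expect_identical(sum(siteLabels(expanded) == 1L), 3L * nPosTrain)
})

test_that("partition-rate study covers the rate ladder with the floor rule", {
  d <- generateDataset(syntheticConfig(seed = 31L, effectSize = 2))
  for (rateCase in list(c(0.30, 165), c(0.20, 110), c(0.10, 55))) {
    part <- partitionDataset(d, splitSpec(rateCase[1], seed = 1L))
    expect_identical(length(part$test_ids), as.integer(rateCase[2]))
  }
  small <- expDataset()
  # small test sides can produce degenerate predictors (zero MCC
  # denominators); those warnings are expected here
  study <- suppressWarnings(
    partitionRateStudy(small, rates = c(0.3, 0.2),
                       encoders = list("NAC", "NCP"),
                       algorithm = "LR", seed = 2L))
  expect_identical(nrow(study), 4L)
  expect_identical(unique(study$rate), c(0.3, 0.2))
  # no monotonicity in the rate is asserted: it is an empirical tendency
})

test_that("experiment I trains on one species and tests on the rest", {
  d <- expDataset()
  res <- experimentOne(d, holdoutSpecies = "H.sapiens",
                       spec = modelSpec("RF", seed = 1L), encoder = "NCP",
                       k = 3L, repeats = 2L, seed = 5L)
  expect_s3_class(res$cv, "dsite_cv")
  expect_identical(nrow(res$cv$folds), 6L)
  expect_true(is.numeric(res$test$AUC))
  expect_s3_class(res$test$roc, "dsite_roc")
  expect_identical(res$config$holdoutSpecies, "H.sapiens")
  expect_error(experimentOne(d, holdoutSpecies = "X.laevis"), "absent")

  onlyPos <- d[siteLabels(d) == 1L | species(d) != "H.sapiens"]
  onlyPos <- onlyPos[!(species(onlyPos) == "H.sapiens" &
                       siteLabels(onlyPos) == 0L)]
  expect_error(experimentOne(onlyPos, holdoutSpecies = "H.sapiens"),
               "single class")
})

test_that("experiment II yields one disjoint evaluation per species", {
  d <- expDataset()
  g <- experimentTwo(d, spec = modelSpec("RF", seed = 1L), encoder = "NCP",
                     seed = 2L)
  expect_identical(nrow(g), 3L)
  expect_setequal(g$test_species, unique(species(d)))
  # every species' test block has exactly its own records
  for (i in seq_len(nrow(g))) {
    s <- g$test_species[i]
    expect_identical(g$n_pos[i] + g$n_neg[i], sum(species(d) == s))
  }
  # all species share the generative motif, so transfer succeeds
  expect_true(all(g$AUC >= 0.8))
})

test_that("experiment III produces a full cross-species accuracy matrix", {
  d <- expDataset()
  m <- experimentThree(d, spec = modelSpec("RF", seed = 1L), encoder = "NCP",
                       k = 3L, seed = 9L)
  expect_identical(dim(m), c(3L, 3L))
  expect_identical(rownames(m), unique(species(d)))
  expect_true(all(m >= 0 & m <= 1))
  # diagonal is the within-species CV accuracy, reproducible independently
  s <- rownames(m)[1]
  dS <- d[species(d) == s]
  cv <- crossValidate(encodeDataset(dS, "NCP"), siteLabels(dS),
                      modelSpec("RF", seed = 1L), k = 3L, repeats = 1L,
                      seed = 9L)
  expect_equal(m[s, s], cv$mean[["Acc"]], tolerance = 1e-12)
})

test_that("single-class species are rejected with the species named", {
  d <- expDataset()
  crippled <- d[!(species(d) == "M.musculus" & siteLabels(d) == 1L)]
  expect_error(experimentThree(crippled), "M.musculus")
})

test_that("small species fall back to fewer CV folds with a warning", {
  tiny <- generateDataset(syntheticConfig(
    counts = data.frame(species = c("H.sapiens", "E.coli"),
                        positive = c(3L, 20L), negative = c(20L, 20L)),
    length = 21L, effectSize = 2, seed = 2L))
  expect_warning(m <- experimentThree(tiny, spec = modelSpec("RF", seed = 1L),
                                      k = 5L, seed = 1L),
                 "3-fold")
  expect_identical(dim(m), c(2L, 2L))
})

test_that("null data scores at the majority-class rate, within noise", {
  d0 <- generateDataset(smallSynthConfig(nPos = 60L, nNeg = 140L,
                                         nSpecies = 1L, length = 21L,
                                         effectSize = 0, seed = 13L))
  g <- gridBenchmark(d0, list("NCP"), list(modelSpec("RF", seed = 1L)),
                     split = splitSpec(0.25, seed = 2L))
  majority <- max(g$n_pos[1], g$n_neg[1]) / (g$n_pos[1] + g$n_neg[1])
  sigma <- sqrt(majority * (1 - majority) / (g$n_pos[1] + g$n_neg[1]))
  expect_lt(abs(g$Acc[1] - majority), 4 * sigma)
})
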