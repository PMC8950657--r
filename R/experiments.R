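## Experiment drivers: encoder x classifier benchmark grids, the test-rate
## partition study, and the three cross-species generalization designs
## (single-species training, leave-one-species-out, all-pairs matrix).
## Every driver embeds its full configuration in its result, and every
## train/test boundary is guarded mechanically: no test id (or oversampling
## ancestor) ever reaches a training set.

.metricRow <- function(m) {
  data.frame(Sn = m$Sn, Sp = m$Sp, Acc = m$Acc, MCC = m$MCC,
             precision = m$precision, F1 = m$F1, AUC = m$AUC,
             n_pos = m$counts$n_pos, n_neg = m$counts$n_neg,
             fn = m$counts$fn, fp = m$counts$fp)
}

.assertDisjoint <- function(trainIds, testIds) {
  leaked <- intersect(ancestorIds(trainIds), ancestorIds(testIds))
  if (length(leaked))
    .dataError("leakage: id(s) on both sides of a split: %s",
               paste(head(leaked, 3L), collapse = ", "))
  invisible(TRUE)
}

## one partition -> optional oversample -> encode each side -> fit -> test
.runCell <- function(d, split, encoder, mspec, oversample = NULL) {
  train <- d[split$train_ids]
  test <- d[split$test_ids]
  .assertDisjoint(names(train), names(test))
  if (!is.null(oversample)) train <- oversamplePositives(train, oversample)
  .assertDisjoint(names(train), names(test))
  Xtr <- encodeDataset(train, encoder)
  Xte <- encodeDataset(test, encoder)
  fitted <- fitModel(mspec, Xtr, siteLabels(train))
  list(metrics = independentTest(fitted, Xte, siteLabels(test)),
       fitted = fitted)
}

.asEncoderList <- function(encoders) {
  if (inherits(encoders, "dsite_encoder_spec")) encoders <- list(encoders)
  lapply(encoders, function(e) if (is.character(e)) encoderSpec(e) else e)
}

.asModelList <- function(algorithms, seed) {
  lapply(algorithms, function(a)
    if (is.character(a)) modelSpec(a, seed = seed) else a)
}

#' Encoder x classifier benchmark grid
#'
#' One shared train/test partition (for comparability across cells); for
#' each (encoder, algorithm) pair: optional positive oversampling of the
#' training side, encoding of each side separately, fit, and an independent
#' test. Encoders are sample-local, so encoding after the split is
#' equivalent to encoding before it — the order is kept to make the
#' no-leakage argument structural.
#'
#' @param d a [DSiteDataset-class].
#' @param encoders list of [encoderSpec()]s (or scheme names).
#' @param algorithms list of [modelSpec()]s (or algorithm names).
#' @param split a [splitSpec()].
#' @param oversample optional [oversampleSpec()] for the training side.
#' @param seed seed given to models created from bare algorithm names.
#' @return A data.frame of class `dsite_grid`: one row per pair with the
#'   full metric family and confusion counts; the run configuration is in
#'   `attr(, "config")`.
#' @export
gridBenchmark <- function(d, encoders, algorithms, split,
                          oversample = NULL, seed = 1L) {
  encoders <- .asEncoderList(encoders)
  algorithms <- .asModelList(algorithms, seed)
  part <- partitionDataset(d, split)
  rows <- list()
  for (enc in encoders) {
    for (mspec in algorithms) {
      cell <- .runCell(d, part, enc, mspec, oversample)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(encoder = enc$name, algorithm = mspec$algorithm,
                   stringsAsFactors = FALSE),
        .metricRow(cell$metrics))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- list(split = part$spec, oversample = oversample,
                              seed = seed,
                              train_n = length(part$train_ids),
                              test_n = length(part$test_ids))
  class(out) <- c("dsite_grid", class(out))
  out
}

#' Partition-rate study
#'
#' Repeats the benchmark grid at several test-set rates (the protocol's
#' 30/20/10% ladder) under a common seed policy, one algorithm across a set
#' of encoders. No monotonicity in the rate is asserted anywhere — the
#' improvement toward smaller test rates is an empirical observation about
#' training-set size, not a law.
#'
#' @param d a [DSiteDataset-class].
#' @param rates numeric vector of test rates (default `c(0.30, 0.20, 0.10)`).
#' @param encoders list of encoder specs or scheme names.
#' @param algorithm one model spec or algorithm name.
#' @param seed shared split seed.
#' @param oversample optional [oversampleSpec()].
#' @return A `dsite_grid` data.frame with a leading `rate` column.
#' @export
partitionRateStudy <- function(d, rates = c(0.30, 0.20, 0.10), encoders,
                               algorithm, seed = 1L, oversample = NULL) {
  out <- do.call(rbind, lapply(rates, function(rt) {
    g <- gridBenchmark(d, encoders, list(algorithm),
                       splitSpec(rt, seed = seed), oversample, seed)
    cbind(data.frame(rate = rt), as.data.frame(g))
  }))
  rownames(out) <- NULL
  attr(out, "config") <- list(rates = rates, seed = seed,
                              oversample = oversample)
  class(out) <- c("dsite_grid", class(out))
  out
}

.checkSpeciesClasses <- function(d, where) {
  if (length(unique(siteLabels(d))) < 2L)
    .dataError("%s contains a single class only", where)
}

#' Experiment I: train on one species, test on all others
#'
#' Cross-validates on the training species (by default S. cerevisiae, the
#' largest contributor) and independently tests on the pooled remaining
#' species; both results carry ROC curves.
#'
#' @param d a [DSiteDataset-class].
#' @param holdoutSpecies the single training species.
#' @param spec a [modelSpec()] or algorithm name.
#' @param encoder an [encoderSpec()] or scheme name.
#' @param k,repeats,seed cross-validation controls.
#' @param oversample optional [oversampleSpec()] (applied to the training
#'   species before fitting the transfer model, and within CV folds).
#' @return List of class `dsite_experiment1`: `cv` (a `dsite_cv`), `test`
#'   (a `dsite_metrics` with ROC), and `config`.
#' @export
experimentOne <- function(d, holdoutSpecies = "S.cerevisiae", spec = "RF",
                          encoder = "NCP", k = 5L, repeats = 5L, seed = 1L,
                          oversample = NULL) {
  if (!holdoutSpecies %in% species(d))
    .dataError("species '%s' absent from the dataset", holdoutSpecies)
  if (is.character(spec)) spec <- modelSpec(spec, seed = seed)
  encoder <- .asEncoderList(list(encoder))[[1L]]
  trainD <- d[species(d) == holdoutSpecies]
  testD <- d[species(d) != holdoutSpecies]
  .checkSpeciesClasses(trainD, sprintf("training species %s", holdoutSpecies))
  .checkSpeciesClasses(testD, "pooled test species")
  .assertDisjoint(names(trainD), names(testD))
  cv <- crossValidate(encodeDataset(trainD, encoder), siteLabels(trainD),
                      spec, k = k, repeats = repeats, seed = seed,
                      oversample = oversample)
  fitTrain <- trainD
  if (!is.null(oversample)) fitTrain <- oversamplePositives(fitTrain, oversample)
  .assertDisjoint(names(fitTrain), names(testD))
  fitted <- fitModel(spec, encodeDataset(fitTrain, encoder),
                     siteLabels(fitTrain))
  test <- independentTest(fitted, encodeDataset(testD, encoder),
                          siteLabels(testD))
  structure(list(cv = cv, test = test,
                 config = list(holdoutSpecies = holdoutSpecies,
                               algorithm = spec$algorithm,
                               encoder = encoder, k = k, repeats = repeats,
                               seed = seed, oversample = oversample)),
            class = "dsite_experiment1")
}

#' Experiment II: leave one species out
#'
#' Each species in turn serves as the test set while all remaining species
#' train the model; one full metric set per species (the radar-chart view).
#'
#' @inheritParams experimentOne
#' @return A data.frame of class `dsite_grid` with one row per species;
#'   config in `attr(, "config")`.
#' @export
experimentTwo <- function(d, spec = "RF", encoder = "NCP", seed = 1L,
                          oversample = NULL) {
  sps <- unique(species(d))
  if (length(sps) < 2L) .dataError("need >= 2 species")
  if (is.character(spec)) spec <- modelSpec(spec, seed = seed)
  encoder <- .asEncoderList(list(encoder))[[1L]]
  rows <- lapply(sps, function(s) {
    testD <- d[species(d) == s]
    trainD <- d[species(d) != s]
    .checkSpeciesClasses(trainD, sprintf("training pool excluding %s", s))
    .checkSpeciesClasses(testD, sprintf("test species %s", s))
    .assertDisjoint(names(trainD), names(testD))
    if (!is.null(oversample)) trainD <- oversamplePositives(trainD, oversample)
    fitted <- fitModel(spec, encodeDataset(trainD, encoder),
                       siteLabels(trainD))
    m <- independentTest(fitted, encodeDataset(testD, encoder),
                         siteLabels(testD))
    cbind(data.frame(test_species = s, stringsAsFactors = FALSE),
          .metricRow(m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "config") <- list(algorithm = spec$algorithm, encoder = encoder,
                              seed = seed, oversample = oversample)
  class(out) <- c("dsite_grid", class(out))
  out
}

#' Experiment III: all-pairs cross-species accuracy matrix
#'
#' Row species trains, column species tests. Off-diagonal entry (r, c) is
#' the accuracy of a model trained on all records of species r and tested
#' on all of species c; the diagonal holds the within-species stratified
#' k-fold CV mean accuracy. Species with fewer than k records in a class
#' fall back to `k = min(k, smallest class)` with a warning rather than
#' failing.
#'
#' @inheritParams experimentOne
#' @param k folds for the diagonal within-species CV (default 5).
#' @return A numeric species-by-species matrix of class
#'   `dsite_crossspecies`; config in `attr(, "config")`.
#' @export
experimentThree <- function(d, spec = "RF", encoder = "NCP", k = 5L,
                            seed = 1L, oversample = NULL) {
  sps <- unique(species(d))
  if (is.character(spec)) spec <- modelSpec(spec, seed = seed)
  encoder <- .asEncoderList(list(encoder))[[1L]]
  perSpecies <- lapply(sps, function(s) d[species(d) == s])
  names(perSpecies) <- sps
  for (s in sps)
    if (length(unique(siteLabels(perSpecies[[s]]))) < 2L)
      .dataError("species '%s' has a single class; cannot train or CV it", s)
  enc <- lapply(perSpecies, encodeDataset, spec = encoder)
  acc <- matrix(NA_real_, length(sps), length(sps),
                dimnames = list(train = sps, test = sps))
  for (r in sps) {
    trainD <- perSpecies[[r]]
    y <- siteLabels(trainD)
    kUse <- min(k, min(table(y)))
    if (kUse < k)
      warning(sprintf(
        "species %s: smallest class has %d records; using %d-fold CV",
        r, min(table(y)), kUse))
    cv <- crossValidate(enc[[r]], y, spec, k = kUse, repeats = 1L,
                        seed = seed, oversample = oversample)
    acc[r, r] <- cv$mean[["Acc"]]
    fitTrain <- trainD
    if (!is.null(oversample))
      fitTrain <- oversamplePositives(fitTrain, oversample)
    fitted <- fitModel(spec, encodeDataset(fitTrain, encoder),
                       siteLabels(fitTrain))
    for (cc in setdiff(sps, r)) {
      .assertDisjoint(names(fitTrain), names(perSpecies[[cc]]))
      m <- independentTest(fitted, enc[[cc]], siteLabels(perSpecies[[cc]]))
      acc[r, cc] <- m$Acc
    }
  }
  attr(acc, "config") <- list(algorithm = spec$algorithm, encoder = encoder,
                              k = k, seed = seed, oversample = oversample)
  class(acc) <- c("dsite_crossspecies", class(acc))
  acc
}

#' @export
print.dsite_crossspecies <- function(x, digits = 3, ...) {
  cat("cross-species accuracy (rows train, columns test; diagonal = CV)\n")
  m <- x
  attributes(m) <- attributes(x)[c("dim", "dimnames")]
  print(round(m, digits))
  invisible(x)
}

#' Write a grid result as TSV
#'
#' @param g a `dsite_grid` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGrid <- function(g, path) {
  write.table(as.data.frame(g), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
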