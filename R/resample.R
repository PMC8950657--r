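## Train/test partitioning and the two-pass probabilistic oversampling of
## positive training windows. Partition and oversampling draw from
## independently seeded streams so either can be varied alone.

#' Train/test split specification
#'
#' @param testRate fraction of records assigned to the test side, in (0, 1).
#'   The test side receives `floor(testRate * n)` records; the remainder
#'   trains.
#' @param seed RNG seed for the split.
#' @param stratified preserve the class ratio within +/- 1 record per class
#'   (default off: a simple random split, matching the benchmark's "randomly
#'   separate" protocol).
#' @return An object of class `dsite_split_spec`.
#' @export
splitSpec <- function(testRate, seed = 1L, stratified = FALSE) {
  if (!is.numeric(testRate) || length(testRate) != 1L ||
      testRate <= 0 || testRate >= 1)
    .configError("testRate must lie strictly between 0 and 1")
  structure(list(testRate = testRate, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "dsite_split_spec")
}

#' Partition a dataset into train and test id sets
#'
#' Draws `floor(testRate * n)` test records (simple random by default;
#' stratified by class when requested, distributing the remainder by largest
#' fractional part so each class is within one record of its proportional
#' share). Deterministic given the spec's seed; the two id sets are disjoint
#' and jointly exhaust the dataset.
#'
#' @param d a [DSiteDataset-class].
#' @param spec a [splitSpec()].
#' @return A list of class `dsite_split` with elements `train_ids`,
#'   `test_ids` and `spec`.
#' @export
partitionDataset <- function(d, spec) {
  stopifnot(is(d, "DSiteDataset"), inherits(spec, "dsite_split_spec"))
  n <- length(d)
  if (n == 0L) .dataError("cannot partition an empty dataset")
  nTest <- floor(spec$testRate * n)
  if (nTest < 1L || nTest >= n)
    .dataError(paste0("test rate %.3f on %d records leaves an empty ",
                      "train or test side"), spec$testRate, n)
  ids <- names(d)
  testIds <- .withSeed(spec$seed, {
    if (!spec$stratified) {
      sample(ids, nTest)
    } else {
      lab <- siteLabels(d)
      byClass <- split(ids, lab)
      exact <- vapply(byClass, length, 0L) * spec$testRate
      take <- floor(exact)
      short <- nTest - sum(take)
      if (short > 0L) {
        order_frac <- order(exact - take, decreasing = TRUE)
        take[order_frac[seq_len(short)]] <- take[order_frac[seq_len(short)]] + 1L
      }
      unlist(lapply(seq_along(byClass),
                    function(i) sample(byClass[[i]], take[i])),
             use.names = FALSE)
    }
  })
  structure(list(train_ids = setdiff(ids, testIds),
                 test_ids = testIds, spec = spec),
            class = "dsite_split")
}

#' Write a train/test partition as two-column TSV
#'
#' @param split a `dsite_split` from [partitionDataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSplit <- function(split, path) {
  df <- data.frame(
    id = c(split$train_ids, split$test_ids),
    partition = rep(c("train", "test"),
                    c(length(split$train_ids), length(split$test_ids))),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Oversampling specification
#'
#' The rebalancing rule applied to the positive class of the training
#' partition: in each of `passes` independent passes, every positive record
#' is duplicated with probability `p`. The benchmark protocol uses two
#' passes at p = 0.5, so each positive is expected to appear twice in the
#' expanded training data.
#'
#' @param passes number of independent duplication passes (>= 0, default 2).
#' @param p per-record duplication probability in each pass (default 0.5).
#' @param seed RNG seed for the duplication draws.
#' @return An object of class `dsite_oversample_spec`.
#' @export
oversampleSpec <- function(passes = 2L, p = 0.5, seed = 1L) {
  passes <- as.integer(passes)
  if (is.na(passes) || passes < 0L) .configError("passes must be >= 0")
  if (!is.numeric(p) || p < 0 || p > 1) .configError("p must lie in [0, 1]")
  structure(list(passes = passes, p = p, seed = as.integer(seed)),
            class = "dsite_oversample_spec")
}

## the pass-level duplication draws, shared with row-level oversampling in
## cross-validation: returns indices (into the positive subset) to duplicate,
## one list element per pass
.oversampleDraws <- function(nPos, spec) {
  lapply(seq_len(spec$passes), function(pass)
    which(runif(nPos) < spec$p))
}

#' Probabilistic oversampling of positive training records
#'
#' Returns every input record once plus, for each pass, each positive record
#' duplicated with probability `p`. Duplicates keep their sequence, species
#' and label unchanged and carry provenance ids `"<origid>#dup<pass>"`, so
#' leakage checks downstream are mechanical and removing duplicates recovers
#' the input exactly. Negatives are never duplicated. Must only be applied
#' to the training side, after partitioning.
#'
#' @param train a [DSiteDataset-class] holding training records only.
#' @param spec an [oversampleSpec()].
#' @return A [DSiteDataset-class] with duplicates appended after the
#'   originals.
#' @export
oversamplePositives <- function(train, spec) {
  stopifnot(is(train, "DSiteDataset"),
            inherits(spec, "dsite_oversample_spec"))
  posIdx <- which(siteLabels(train) == 1L)
  if (spec$passes == 0L || length(posIdx) == 0L || spec$p == 0) return(train)
  draws <- .withSeed(spec$seed, .oversampleDraws(length(posIdx), spec))
  out <- train
  for (pass in seq_along(draws)) {
    take <- posIdx[draws[[pass]]]
    if (length(take) == 0L) next
    dup <- train[take]
    names(dup@sequences) <- sprintf("%s#dup%d", names(train)[take], pass)
    out <- c(out, dup)
  }
  out
}

#' Strip oversampling provenance from record ids
#'
#' Maps `"id#dupk"` back to `"id"`; ids without provenance pass through.
#' Used by the leakage guards to trace duplicates to their ancestors.
#'
#' @param ids character vector of record ids.
#' @return Character vector of ancestor ids.
#' @export
ancestorIds <- function(ids) sub("#dup[0-9]+$", "", ids)
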