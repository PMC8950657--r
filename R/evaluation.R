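## Evaluation: confusion counts, the Sn/Sp/Acc/MCC metric family in its
## count-based formulation, ROC/AUC, repeated stratified k-fold
## cross-validation, and leakage-guarded independent testing.

#' Confusion counts for binary site prediction
#'
#' The four counts of the count-based metric formulation: `n_pos` and
#' `n_neg` are the numbers of true D-site and non-D windows; `fn` the
#' D-site windows predicted negative; `fp` the non-D windows predicted
#' positive.
#'
#' @param yTrue,yPred equal-length binary label vectors.
#' @return A list of class `dsite_confusion` with elements `n_pos`, `n_neg`,
#'   `fn`, `fp` (and the derived `tp`, `tn`).
#' @export
#' @examples
#' confusionCounts(c(1, 1, 0), c(1, 0, 0))  # n_pos 2, n_neg 1, fn 1, fp 0
confusionCounts <- function(yTrue, yPred) {
  yTrue <- .asLabels(yTrue)
  yPred <- .asLabels(yPred)
  if (length(yTrue) != length(yPred))
    .dataError("label vectors differ in length (%d vs %d)",
               length(yTrue), length(yPred))
  out <- list(n_pos = sum(yTrue == 1L), n_neg = sum(yTrue == 0L),
              fn = sum(yTrue == 1L & yPred == 0L),
              fp = sum(yTrue == 0L & yPred == 1L))
  out$tp <- out$n_pos - out$fn
  out$tn <- out$n_neg - out$fp
  structure(out, class = "dsite_confusion")
}

#' @export
print.dsite_confusion <- function(x, ...) {
  cat(sprintf("confusion: %d pos (%d missed), %d neg (%d false alarms)\n",
              x$n_pos, x$fn, x$n_neg, x$fp))
  invisible(x)
}

#' Metrics from confusion counts
#'
#' The count-based formulation: `Sn = 1 - fn/n_pos`, `Sp = 1 - fp/n_neg`,
#' `Acc = 1 - (fn + fp)/(n_pos + n_neg)`, with MCC in its standard
#' correlation form, precision `tp/(tp + fp)` and F1 the harmonic mean of
#' precision and Sn. A zero denominator in MCC or precision yields 0 with a
#' warning (the convention for degenerate predictors).
#'
#' @param cc a `dsite_confusion` from [confusionCounts()].
#' @return Named list of class `dsite_metrics`: `Sn`, `Sp`, `Acc`, `MCC`,
#'   `precision`, `F1` (no AUC — that needs scores, see [rocAuc()]).
#' @export
metricsFromConfusion <- function(cc) {
  stopifnot(inherits(cc, "dsite_confusion"))
  if (cc$n_pos == 0L || cc$n_neg == 0L)
    .dataError("Sn/Sp undefined: need at least one sample of each class")
  sn <- 1 - cc$fn / cc$n_pos
  sp <- 1 - cc$fp / cc$n_neg
  acc <- 1 - (cc$fn + cc$fp) / (cc$n_pos + cc$n_neg)
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  mccDen <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mccDen == 0) {
    warning("MCC denominator is zero; returning 0")
    0
  } else (tp * tn - fp * fn) / mccDen
  precision <- if (tp + fp == 0L) {
    warning("precision denominator is zero; returning 0")
    0
  } else tp / (tp + fp)
  f1 <- if (precision + sn == 0) 0 else 2 * precision * sn / (precision + sn)
  structure(list(Sn = sn, Sp = sp, Acc = acc, MCC = mcc,
                 precision = precision, F1 = f1),
            class = "dsite_metrics")
}

#' @export
print.dsite_metrics <- function(x, digits = 4, ...) {
  keep <- intersect(c("Sn", "Sp", "Acc", "MCC", "precision", "F1", "AUC"),
                    names(x))
  vals <- unlist(x[keep])
  cat(paste(sprintf("%s=%.*f", names(vals), digits, vals), collapse = "  "),
      "\n")
  invisible(x)
}

#' Metrics from labels and scores in one call
#'
#' Convenience wrapper: hard labels by thresholding at 0.5, count-based
#' metrics, plus trapezoid AUC.
#'
#' @param yTrue binary truth labels.
#' @param scores positive-class scores in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return A `dsite_metrics` list including `AUC` and the underlying
#'   `counts`.
#' @export
evaluateScores <- function(yTrue, scores, threshold = 0.5) {
  cc <- confusionCounts(yTrue, as.integer(scores >= threshold))
  m <- metricsFromConfusion(cc)
  m$AUC <- rocAuc(yTrue, scores)$auc
  m$counts <- cc
  m
}

#' ROC curve and AUC
#'
#' Sweeps the score thresholds to build the ROC curve — false-positive rate
#' `1 - Sp` against true-positive rate `Sn` — from (0, 0) to (1, 1), and
#' integrates it by the trapezoid rule. The result equals the Mann-Whitney
#' pair statistic (ties counted one half, see [aucMannWhitney()]); a model
#' with no discrimination scores 0.5.
#'
#' @param yTrue binary truth labels (both classes required).
#' @param scores positive-class scores.
#' @return A list of class `dsite_roc`: `curve` (data.frame `threshold`,
#'   `fpr`, `tpr`, coordinates non-decreasing) and `auc`.
#' @export
#' @examples
#' rocAuc(c(1, 1, 0, 0), c(0.8, 0.3, 0.5, 0.1))$auc  # 0.75
rocAuc <- function(yTrue, scores) {
  yTrue <- .asLabels(yTrue)
  stopifnot(length(yTrue) == length(scores))
  nPos <- sum(yTrue == 1L); nNeg <- sum(yTrue == 0L)
  if (nPos == 0L || nNeg == 0L)
    .dataError("ROC undefined: need both classes present")
  thr <- sort(unique(scores), decreasing = TRUE)
  ## cumulative tp/fp as the threshold sweeps down through the unique scores
  ord <- order(scores, decreasing = TRUE)
  ys <- yTrue[ord]
  grp <- match(scores[ord], thr)            # which threshold admits each sample
  tpCum <- cumsum(ys == 1L)
  fpCum <- cumsum(ys == 0L)
  last <- vapply(seq_along(thr), function(i) max(which(grp == i)), 0L)
  curve <- data.frame(threshold = c(Inf, thr),
                      fpr = c(0, fpCum[last] / nNeg),
                      tpr = c(0, tpCum[last] / nPos))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  structure(list(curve = curve, auc = auc), class = "dsite_roc")
}

#' AUC as the Mann-Whitney pair statistic
#'
#' Fraction of (positive, negative) score pairs ranked correctly, ties
#' counted one half. Serves as the independent formulation against which
#' the trapezoid AUC is checked.
#'
#' @inheritParams rocAuc
#' @return AUC in `[0, 1]`.
#' @export
aucMannWhitney <- function(yTrue, scores) {
  yTrue <- .asLabels(yTrue)
  pos <- scores[yTrue == 1L]
  neg <- scores[yTrue == 0L]
  if (length(pos) == 0L || length(neg) == 0L)
    .dataError("AUC undefined: need both classes present")
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

#' Write ROC points as two-column TSV
#'
#' @param roc a `dsite_roc` from [rocAuc()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRoc <- function(roc, path) {
  write.table(roc$curve[, c("fpr", "tpr")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Repeated stratified k-fold cross-validation
#'
#' Per repeat, samples are shuffled (seed `seed + r - 1` for repeat `r`,
#' recorded for replay) into k class-stratified folds; each fold is scored
#' by a model trained on the remaining folds. When an [oversampleSpec()] is
#' given, positive-row duplication is applied inside each training fold
#' only — test folds never contain duplicates. The aggregate is the mean
#' (and SD) over all `k * repeats` folds.
#'
#' @param X a [FeatureMatrix-class] or matrix.
#' @param y binary labels, one per row.
#' @param spec a [modelSpec()] (or algorithm name).
#' @param k folds (default 5).
#' @param repeats repetitions of the whole CV (default 5).
#' @param seed base seed for fold shuffling.
#' @param oversample optional [oversampleSpec()] applied within training
#'   folds.
#' @param stratified stratify folds by class (default TRUE; turning it off
#'   risks single-class training folds, which error).
#' @return A list of class `dsite_cv`: `folds` (one row per fold with all
#'   metrics), `mean`, `sd`, `assignments` (per-repeat fold membership) and
#'   `config`.
#' @export
crossValidate <- function(X, y, spec, k = 5L, repeats = 5L, seed = 1L,
                          oversample = NULL, stratified = TRUE) {
  if (is.character(spec)) spec <- modelSpec(spec)
  Xm <- .asMatrix(X)
  y <- .asLabels(y)
  stopifnot(nrow(Xm) == length(y))
  if (is.null(rownames(Xm))) rownames(Xm) <- sprintf("s%d", seq_len(nrow(Xm)))
  ## canonical (id-sorted) sample order: the whole CV becomes a function of
  ## (ids, labels, seed), invariant to presentation order
  ord <- order(rownames(Xm))
  Xm <- Xm[ord, , drop = FALSE]
  y <- y[ord]
  k <- as.integer(k); repeats <- as.integer(repeats)
  if (min(table(y)) < k)
    .dataError("need at least k = %d samples per class for stratified %d-fold CV",
               k, k)
  metricNames <- c("Sn", "Sp", "Acc", "MCC", "precision", "F1", "AUC")
  rows <- list(); assignments <- list()
  for (r in seq_len(repeats)) {
    repSeed <- seed + r - 1L
    folds <- .withSeed(repSeed,
                       if (stratified) .stratifiedFolds(y, k)
                       else sample(rep_len(seq_len(k), length(y))))
    assignments[[r]] <- setNames(folds, rownames(Xm))
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L)
        .dataError("training fold %d lost a class; use stratified folds", f)
      Xtr <- Xm[tr, , drop = FALSE]; ytr <- y[tr]
      if (!is.null(oversample)) {
        posIdx <- which(ytr == 1L)
        draws <- .withSeed(oversample$seed + r * 100L + f,
                           .oversampleDraws(length(posIdx), oversample))
        for (pass in seq_along(draws)) {
          take <- posIdx[draws[[pass]]]
          if (length(take) == 0L) next
          Xdup <- Xtr[take, , drop = FALSE]
          rownames(Xdup) <- sprintf("%s#dup%d", rownames(Xtr)[take], pass)
          Xtr <- rbind(Xtr, Xdup); ytr <- c(ytr, ytr[take])
        }
      }
      fitted <- fitModel(modelSpec(spec$algorithm, spec$hyperparams,
                                   seed = spec$seed + r * 1000L + f),
                         Xtr, ytr)
      sc <- predictScores(fitted, Xm[!tr, , drop = FALSE])
      m <- evaluateScores(y[!tr], sc)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = r, fold = f, n_test = sum(!tr),
        as.data.frame(m[metricNames]))
    }
  }
  folds <- do.call(rbind, rows)
  structure(list(
    folds = folds,
    mean = colMeans(folds[metricNames]),
    sd = vapply(folds[metricNames], sd, 0),
    assignments = assignments,
    config = list(algorithm = spec$algorithm, k = k, repeats = repeats,
                  seed = seed, repeat_seeds = seed + seq_len(repeats) - 1L,
                  oversample = oversample, stratified = stratified)),
    class = "dsite_cv")
}

#' @export
print.dsite_cv <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation [%s]\n",
              x$config$repeats, x$config$k, x$config$algorithm))
  agg <- rbind(mean = x$mean, sd = x$sd)
  print(round(agg, 4))
  invisible(x)
}

#' Independent test with a structural leakage guard
#'
#' Scores a held-out set and computes the full metric family including AUC.
#' Errors if any test sample id — or its oversampling ancestor — appears in
#' the model's training ids.
#'
#' @param trained a `dsite_trained_model`.
#' @param XTest features of the held-out set.
#' @param yTest its binary labels.
#' @return A `dsite_metrics` list including `AUC`, the underlying `counts`,
#'   and the `roc` curve.
#' @export
independentTest <- function(trained, XTest, yTest) {
  Xm <- .asMatrix(XTest)
  if (!is.null(rownames(Xm)) && !is.null(trained$trainIds)) {
    leaked <- intersect(ancestorIds(rownames(Xm)),
                        ancestorIds(trained$trainIds))
    if (length(leaked))
      .dataError("leakage: test record(s) present in training set: %s",
                 paste(head(leaked, 3L), collapse = ", "))
  }
  sc <- predictScores(trained, Xm)
  m <- evaluateScores(yTest, sc)
  m$roc <- rocAuc(yTest, sc)
  m
}
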