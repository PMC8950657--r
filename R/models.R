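## Uniform train/score interface over the five classifier families. The
## backends are the established R implementations (randomForest, e1071 SVM,
## class::knn, glmnet ridge logistic regression, nnet); this layer fixes
## documented defaults, seeds every fit for determinism, and returns
## positive-class scores in [0, 1] from every family.

.DSITE_ALGORITHMS <- c("RF", "SVM", "KNN", "LR", "MLP")

## documented defaults for hyperparameters the protocol leaves unstated
.algorithmDefaults <- function(algorithm) {
  switch(algorithm,
    RF  = list(ntree = 100L, mtry = NA),        # mtry NA -> floor(sqrt(d))
    SVM = list(kernel = "radial", cost = 1, gamma = NA),  # gamma NA -> 1/d
    KNN = list(k = NA, kGrid = c(1L, 3L, 5L, 7L, 9L), innerFolds = 5L),
    LR  = list(lambda = NA, alpha = 0),         # lambda NA -> 1/n (ridge)
    MLP = list(size = 100L, decay = 1e-4, maxit = 200L))
}

#' Classifier specification
#'
#' Names one of the five classifier families with its hyperparameters and a
#' seed. Unstated hyperparameters take documented defaults: RF grows 100
#' trees with `floor(sqrt(d))` candidate features per split; SVM uses the
#' RBF kernel with library-default cost and gamma; KNN selects K from
#' \{1, 3, 5, 7, 9\} by inner cross-validation on the training data only; LR
#' is ridge-penalized logistic regression at a fixed default strength
#' (`lambda = 1/n`); MLP is a single hidden layer of 100 units with logistic
#' (sigmoid) activation. All defaults are overridable via `hyperparams`.
#'
#' @param algorithm one of `"RF"`, `"SVM"`, `"KNN"`, `"LR"`, `"MLP"`.
#' @param hyperparams named list overriding the defaults above.
#' @param seed RNG seed used for every stochastic element of the fit.
#' @return An object of class `dsite_model_spec`.
#' @export
#' @examples
#' modelSpec("RF")
modelSpec <- function(algorithm, hyperparams = list(), seed = 1L) {
  if (length(algorithm) != 1L || !algorithm %in% .DSITE_ALGORITHMS)
    .configError("unknown algorithm '%s'; valid algorithms: %s",
                 as.character(algorithm)[1L],
                 paste(.DSITE_ALGORITHMS, collapse = ", "))
  defaults <- .algorithmDefaults(algorithm)
  unknown <- setdiff(names(hyperparams), names(defaults))
  if (length(unknown))
    .configError("invalid hyperparameter(s) for %s: %s (valid: %s)",
                 algorithm, paste(unknown, collapse = ", "),
                 paste(names(defaults), collapse = ", "))
  structure(list(algorithm = algorithm,
                 hyperparams = modifyList(defaults, hyperparams),
                 seed = as.integer(seed)),
            class = "dsite_model_spec")
}

#' Create an untrained model handle
#'
#' Resolves the spec against the family's documented defaults and returns a
#' handle that [fitModel()] accepts; printing the handle echoes the resolved
#' configuration.
#'
#' @param spec a [modelSpec()] (or an algorithm name, taken with defaults).
#' @return An object of class `dsite_model`.
#' @export
#' @examples
#' makeModel("SVM")  # reports the RBF kernel
makeModel <- function(spec) {
  if (is.character(spec)) spec <- modelSpec(spec)
  stopifnot(inherits(spec, "dsite_model_spec"))
  structure(list(spec = spec), class = "dsite_model")
}

#' @export
print.dsite_model <- function(x, ...) {
  hp <- x$spec$hyperparams
  desc <- switch(x$spec$algorithm,
    RF  = sprintf("random forest, %d trees", hp$ntree),
    SVM = sprintf("SVM, %s kernel", hp$kernel),
    KNN = sprintf("KNN, K grid {%s}", paste(hp$kGrid, collapse = ", ")),
    LR  = "ridge-penalized logistic regression",
    MLP = sprintf("MLP, 1 hidden layer of %d sigmoid units", hp$size))
  cat(sprintf("dsite model [%s]: %s (seed %d, untrained)\n",
              x$spec$algorithm, desc, x$spec$seed))
  invisible(x)
}

## coerce labels to integer 0/1
.asLabels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.logical(y)) y <- as.integer(y)
  if (is.character(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (any(!y %in% c(0L, 1L))) .dataError("labels must be binary 0/1")
  y
}

## stratified fold assignment, shared by KNN inner selection and crossValidate
.stratifiedFolds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

.selectKnnK <- function(X, y, hp) {
  grid <- hp$kGrid[hp$kGrid < length(y)]
  if (length(grid) == 0L) grid <- 1L
  nf <- min(hp$innerFolds, min(table(y)))
  if (nf < 2L) return(grid[1L])
  folds <- .stratifiedFolds(y, nf)
  err <- vapply(grid, function(kk) {
    mean(vapply(seq_len(nf), function(f) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) return(NA_real_)
      pred <- class::knn(X[tr, , drop = FALSE], X[!tr, , drop = FALSE],
                         cl = factor(y[tr], levels = c(0L, 1L)), k = kk)
      mean(as.integer(as.character(pred)) != y[!tr])
    }, 0), na.rm = TRUE)
  }, 0)
  grid[which.min(err)]   # ties resolve to the smallest K
}

#' Fit a classifier
#'
#' Trains the family named by the handle's spec on a feature matrix and
#' binary labels. Fits are deterministic given `spec$seed`; KNN's K is
#' selected by inner cross-validation carved from the training data only.
#'
#' @param model a `dsite_model` handle from [makeModel()] (or a
#'   [modelSpec()], or an algorithm name).
#' @param X a [FeatureMatrix-class] or numeric matrix (samples in rows; row
#'   names are sample ids).
#' @param y binary labels, one per row of `X`; both classes must be present.
#' @return An object of class `dsite_trained_model`.
#' @export
fitModel <- function(model, X, y) {
  if (is.character(model) || inherits(model, "dsite_model_spec"))
    model <- makeModel(model)
  stopifnot(inherits(model, "dsite_model"))
  Xm <- .asMatrix(X)
  y <- .asLabels(y)
  if (nrow(Xm) != length(y))
    .dataError("X has %d rows but y has %d labels", nrow(Xm), length(y))
  if (length(unique(y)) < 2L)
    .dataError("training labels contain a single class; need both 0 and 1")
  spec <- model$spec
  hp <- spec$hyperparams
  yf <- factor(y, levels = c(0L, 1L))
  fitObj <- .withSeed(spec$seed, switch(spec$algorithm,
    RF = {
      mtry <- if (is.na(hp$mtry)) max(1L, floor(sqrt(ncol(Xm)))) else hp$mtry
      randomForest::randomForest(x = Xm, y = yf, ntree = hp$ntree,
                                 mtry = mtry)
    },
    SVM = {
      gamma <- if (is.na(hp$gamma)) 1 / ncol(Xm) else hp$gamma
      e1071::svm(x = Xm, y = yf, kernel = hp$kernel, cost = hp$cost,
                 gamma = gamma, probability = TRUE, scale = FALSE)
    },
    KNN = {
      k <- if (is.na(hp$k)) .selectKnnK(Xm, y, hp) else as.integer(hp$k)
      list(trainX = Xm, trainY = yf, k = k)
    },
    LR = {
      lambda <- if (is.na(hp$lambda)) 1 / nrow(Xm) else hp$lambda
      glmnet::glmnet(x = Xm, y = yf, family = "binomial",
                     alpha = hp$alpha, lambda = lambda)
    },
    MLP = {
      nnet::nnet(x = Xm, y = matrix(as.numeric(y), ncol = 1L),
                 size = hp$size, decay = hp$decay, maxit = hp$maxit,
                 entropy = TRUE, trace = FALSE,
                 MaxNWts = (ncol(Xm) + 2L) * hp$size + hp$size + 10L)
    }))
  structure(list(spec = spec, fit = fitObj, featureDim = ncol(Xm),
                 featureNames = colnames(Xm),
                 trainIds = rownames(Xm), nSamples = nrow(Xm),
                 classCounts = c(neg = sum(y == 0L), pos = sum(y == 1L))),
            class = "dsite_trained_model")
}

#' @export
print.dsite_trained_model <- function(x, ...) {
  cat(sprintf(
    "trained dsite model [%s]: %d features, %d samples (%d pos / %d neg)\n",
    x$spec$algorithm, x$featureDim, x$nSamples,
    x$classCounts[["pos"]], x$classCounts[["neg"]]))
  if (x$spec$algorithm == "KNN")
    cat(sprintf("  selected K = %d\n", x$fit$k))
  invisible(x)
}

.checkProbe <- function(trained, Xm) {
  if (ncol(Xm) != trained$featureDim)
    .dataError("feature dimension mismatch: model expects %d, input has %d",
               trained$featureDim, ncol(Xm))
}

#' Positive-class scores
#'
#' Per-sample probability-like score of the positive (D-site) class, in
#' `[0, 1]` for every family; hard labels follow by thresholding at 0.5
#' (see [predictLabels()]). For RF the score is the fraction of trees voting
#' positive.
#'
#' @param trained a `dsite_trained_model` from [fitModel()].
#' @param X a [FeatureMatrix-class] or matrix with matching feature
#'   dimension.
#' @return Numeric vector of scores named by sample id.
#' @export
predictScores <- function(trained, X) {
  stopifnot(inherits(trained, "dsite_trained_model"))
  Xm <- .asMatrix(X)
  .checkProbe(trained, Xm)
  if (nrow(Xm) == 0L) return(setNames(numeric(0), character(0)))
  scores <- .withSeed(trained$spec$seed + 1L, switch(trained$spec$algorithm,
    RF = predict(trained$fit, Xm, type = "prob")[, "1"],
    SVM = {
      pr <- predict(trained$fit, Xm, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    KNN = {
      pred <- class::knn(trained$fit$trainX, Xm, cl = trained$fit$trainY,
                         k = trained$fit$k, prob = TRUE)
      winShare <- attr(pred, "prob")
      ifelse(pred == "1", winShare, 1 - winShare)
    },
    LR = as.numeric(predict(trained$fit, newx = Xm, type = "response")),
    MLP = as.numeric(predict(trained$fit, Xm, type = "raw"))))
  scores <- pmin(pmax(as.numeric(scores), 0), 1)
  names(scores) <- rownames(Xm)
  scores
}

#' Hard class labels by thresholding scores
#'
#' @inheritParams predictScores
#' @param threshold decision threshold on the positive-class score
#'   (default 0.5).
#' @return Integer 0/1 vector named by sample id.
#' @export
predictLabels <- function(trained, X, threshold = 0.5) {
  scores <- predictScores(trained, X)
  out <- as.integer(scores >= threshold)
  names(out) <- names(scores)
  out
}

#' Persist / restore a trained model
#'
#' The artifact is a single file embedding the spec, feature geometry and
#' training metadata alongside the fitted state.
#'
#' @param trained a `dsite_trained_model`.
#' @param path file path.
#' @return `path` (save) or the restored `dsite_trained_model` (load).
#' @export
saveModel <- function(trained, path) {
  stopifnot(inherits(trained, "dsite_trained_model"))
  saveRDS(trained, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "dsite_trained_model"))
    .dataError("'%s' is not a dsite model artifact", path)
  obj
}
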