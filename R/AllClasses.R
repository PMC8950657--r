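#' Default species set of the five-species dihydrouridine benchmark
#'
#' The benchmark this package emulates pools D-site windows from five species.
#' Species labels use the dotted short form, e.g. `"S.cerevisiae"`.
#'
#' @return Character vector of the five species labels.
#' @export
#' @examples
#' dsiteSpecies()
dsiteSpecies <- function() {
  c("H.sapiens", "M.musculus", "D.melanogaster", "S.cerevisiae", "E.coli")
}

## internal error helpers: classed conditions so the CLI can map them to
## distinct exit codes (config vs data vs runtime).
.configError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("dsite_config_error", "dsite_error")))
}
.dataError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("dsite_data_error", "dsite_error")))
}

## seed hygiene: run expr under a local RNG stream without touching the
## caller's .Random.seed.
.withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' DSiteDataset: labelled fixed-length RNA windows
#'
#' Container for a set of candidate dihydrouridine windows: an
#' [Biostrings::RNAStringSet] of equal-width sequences (names are the record
#' ids), a species label and a binary class label per record (1 = true D-site
#' window, 0 = non-D U window). All windows share one length; when the length
#' is odd the centre position (`(length + 1) / 2`, 1-based) carries the
#' candidate site.
#'
#' @slot sequences [Biostrings::RNAStringSet]; names are unique record ids.
#' @slot species character vector, one label per record.
#' @slot labels integer vector of 0/1 class labels.
#' @slot seqLength integer scalar, the common window length (kept explicitly
#'   so an empty dataset still knows its geometry).
#'
#' @aliases DSiteDataset-class
#' @export
setClass("DSiteDataset",
  slots = c(sequences = "RNAStringSet",
            species   = "character",
            labels    = "integer",
            seqLength = "integer"))

setValidity("DSiteDataset", function(object) {
  n <- length(object@sequences)
  msgs <- character()
  if (length(object@species) != n || length(object@labels) != n)
    msgs <- c(msgs, "species and labels must have one entry per sequence")
  ids <- names(object@sequences)
  if (n > 0L && (is.null(ids) || anyDuplicated(ids) || any(ids == "")))
    msgs <- c(msgs, "record ids (sequence names) must be present and unique")
  if (length(object@seqLength) != 1L || is.na(object@seqLength) ||
      object@seqLength < 1L)
    msgs <- c(msgs, "seqLength must be a single positive integer")
  if (n > 0L && any(Biostrings::width(object@sequences) != object@seqLength))
    msgs <- c(msgs, "all sequences must have width equal to seqLength")
  if (any(!object@labels %in% c(0L, 1L)))
    msgs <- c(msgs, "labels must be 0 or 1")
  if (length(msgs)) msgs else TRUE
})

## canonical sequence form: uppercase, DNA alphabet mapped to RNA (T -> U)
.normalizeSeq <- function(x) chartr("acgut T", "ACGUU U",
                                    gsub(" ", "", toupper(x), fixed = TRUE))

#' Construct a DSiteDataset
#'
#' Sequences are normalized to canonical form: uppercased, with `T` mapped to
#' `U` (benchmark files in this field are often distributed in the DNA
#' alphabet). Characters outside `A/C/G/U` that survive normalization (such
#' as `N`) are accepted by the container but reported by [validateDataset()]
#' and rejected by every encoder.
#'
#' @param sequences character vector or [Biostrings::RNAStringSet] of
#'   equal-length RNA windows.
#' @param species character vector of species labels (recycled if scalar).
#' @param labels binary class labels: 0/1, logical, or a factor with levels
#'   `c("0", "1")`.
#' @param ids record identifiers; defaults to the names of `sequences`.
#' @param seqLength window length; required only for an empty dataset
#'   (default 41).
#' @return A [DSiteDataset-class] object.
#' @export
#' @examples
#' d <- DSiteDataset(c(a = "GAGACU", b = "AAUUGG"),
#'                   species = "S.cerevisiae", labels = c(1, 0))
#' d
DSiteDataset <- function(sequences = character(), species = character(),
                         labels = integer(), ids = NULL, seqLength = 41L) {
  if (is(sequences, "XStringSet")) {
    if (is.null(ids)) ids <- names(sequences)
    sequences <- as.character(sequences)
  }
  n <- length(sequences)
  if (is.null(ids)) ids <- names(sequences)
  if (is.null(ids) && n > 0L) ids <- sprintf("seq%d", seq_len(n))
  sequences <- .normalizeSeq(unname(sequences))
  if (n > 0L) seqLength <- unique(nchar(sequences))
  if (length(seqLength) != 1L)
    .dataError("all sequences in a dataset must share one length; found {%s}",
               paste(sort(seqLength), collapse = ", "))
  species <- as.character(species)
  if (n > 0L && length(species) == 1L) species <- rep(species, n)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) labels <- as.integer(labels)
  labels <- as.integer(labels)
  seqs <- Biostrings::RNAStringSet(sequences)
  names(seqs) <- ids
  new("DSiteDataset", sequences = seqs, species = species, labels = labels,
      seqLength = as.integer(seqLength))
}

#' @describeIn DSiteDataset number of records.
#' @param x a `DSiteDataset`.
#' @export
setMethod("length", "DSiteDataset", function(x) length(x@sequences))

#' @describeIn DSiteDataset record ids.
#' @export
setMethod("names", "DSiteDataset", function(x) names(x@sequences))

#' Accessors for DSiteDataset
#'
#' `sequences()` returns the [Biostrings::RNAStringSet]; `species()` the
#' per-record species labels; `siteLabels()` the 0/1 class labels;
#' `seqLength()` the common window length; `centrePosition()` the 1-based
#' centre index (21 for the default 41-nt windows).
#'
#' @param x a [DSiteDataset-class].
#' @return See the individual descriptions.
#' @name dataset-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname dataset-accessors
#' @export
setMethod("sequences", "DSiteDataset", function(x) x@sequences)

#' @rdname dataset-accessors
#' @export
setGeneric("species", function(x) standardGeneric("species"))

#' @rdname dataset-accessors
#' @export
setMethod("species", "DSiteDataset", function(x) x@species)

#' @rdname dataset-accessors
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname dataset-accessors
#' @export
setMethod("siteLabels", "DSiteDataset", function(x) x@labels)

#' @rdname dataset-accessors
#' @export
setGeneric("seqLength", function(x) standardGeneric("seqLength"))

#' @rdname dataset-accessors
#' @export
setMethod("seqLength", "DSiteDataset", function(x) x@seqLength)

#' @rdname dataset-accessors
#' @export
centrePosition <- function(x) {
  L <- seqLength(x)
  if (L %% 2L == 0L)
    .dataError("window length %d is even: no unique centre position", L)
  (L + 1L) %/% 2L
}

#' @describeIn DSiteDataset subset by index, logical mask or record id.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "DSiteDataset", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    idx <- match(i, names(x))
    if (anyNA(idx))
      .dataError("unknown record id(s): %s",
                 paste(head(i[is.na(idx)], 3L), collapse = ", "))
    i <- idx
  }
  new("DSiteDataset", sequences = x@sequences[i], species = x@species[i],
      labels = x@labels[i], seqLength = x@seqLength)
})

#' @describeIn DSiteDataset concatenate datasets of equal window length.
#' @export
setMethod("c", "DSiteDataset", function(x, ...) {
  rest <- list(...)
  for (y in rest) {
    if (seqLength(y) != seqLength(x))
      .dataError("cannot combine datasets of lengths %d and %d",
                 seqLength(x), seqLength(y))
    x <- new("DSiteDataset",
             sequences = c(x@sequences, y@sequences),
             species = c(x@species, y@species),
             labels = c(x@labels, y@labels),
             seqLength = x@seqLength)
  }
  x
})

setMethod("show", "DSiteDataset", function(object) {
  n <- length(object)
  cat(sprintf("DSiteDataset: %d record%s, %d nt window%s\n",
              n, if (n == 1L) "" else "s", object@seqLength,
              if (object@seqLength %% 2L == 1L)
                sprintf(" (centre position %d)", (object@seqLength + 1L) %/% 2L)
              else ""))
  if (n > 0L) {
    cat(sprintf("  %d positive / %d negative across %d species\n",
                sum(object@labels == 1L), sum(object@labels == 0L),
                length(unique(object@species))))
  }
})

#' FeatureMatrix: encoded samples-by-features matrix
#'
#' Numeric matrix produced by one of the eleven encoders; row names are the
#' sample ids (input record order preserved), column names are
#' scheme-specific feature names, and the generating [encoderSpec()] travels
#' with the matrix so it is self-describing.
#'
#' @slot values numeric matrix, samples in rows.
#' @slot encoder the `dsite_encoder_spec` that produced it.
#'
#' @aliases FeatureMatrix-class
#' @export
setClass("FeatureMatrix",
  slots = c(values = "matrix", encoder = "list"))

setValidity("FeatureMatrix", function(object) {
  msgs <- character()
  if (!is.numeric(object@values))
    msgs <- c(msgs, "values must be a numeric matrix")
  if (is.null(colnames(object@values)))
    msgs <- c(msgs, "feature names (column names) are required")
  if (nrow(object@values) > 0L && is.null(rownames(object@values)))
    msgs <- c(msgs, "sample ids (row names) are required")
  if (is.null(object@encoder$name))
    msgs <- c(msgs, "encoder spec must carry a scheme name")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn FeatureMatrix underlying numeric matrix.
#' @param x a `FeatureMatrix`.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @describeIn FeatureMatrix the generating encoder spec.
#' @export
setGeneric("encoderOf", function(x) standardGeneric("encoderOf"))

#' @rdname FeatureMatrix-class
#' @export
setMethod("encoderOf", "FeatureMatrix", function(x) x@encoder)

#' @describeIn FeatureMatrix dimensions of the value matrix.
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d sample%s x %d feature%s [%s]\n",
              nrow(object@values),
              if (nrow(object@values) == 1L) "" else "s",
              ncol(object@values),
              if (ncol(object@values) == 1L) "" else "s",
              object@encoder$name))
})

## tolerant coercion used throughout the model/evaluation layer
.asMatrix <- function(X) {
  if (is(X, "FeatureMatrix")) featureValues(X) else as.matrix(X)
}
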