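#' Read a labelled window dataset from FASTA
#'
#' Headers follow the convention `>id<delim>species<delim>label` with label 1
#' (D-site window) or 0 (non-D U window); the default delimiter is `|`.
#' Sequences are normalized on input: uppercased and `T` mapped to `U`.
#' Multi-line (wrapped) FASTA is accepted.
#'
#' @param path path to a FASTA file.
#' @param delim single-character field delimiter in headers.
#' @param speciesSet optional character vector; when given, any record whose
#'   species is not in the set is rejected with an error naming it.
#' @return A [DSiteDataset-class]; record order is file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1|H.sapiens|1", "GAGACU", ">s2|E.coli|0", "AAUUGG"), f)
#' readFastaDataset(f)
readFastaDataset <- function(path, delim = "|", speciesSet = NULL) {
  if (!file.exists(path)) .dataError("file not found: %s", path)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    .dataError("cannot parse FASTA '%s': %s",
                               path, conditionMessage(e)))
  if (length(raw) == 0L)
    .dataError("empty dataset: no FASTA records in %s", path)
  fields <- strsplit(names(raw), delim, fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L))
    .dataError(
      "malformed header '%s': expected id%sspecies%slabel",
      names(raw)[which(nf != 3L)[1L]], delim, delim)
  ids <- vapply(fields, `[[`, "", 1L)
  sp  <- vapply(fields, `[[`, "", 2L)
  lab <- vapply(fields, `[[`, "", 3L)
  if (any(!lab %in% c("0", "1")))
    .dataError("malformed header for record '%s': label '%s' is not 0/1",
               ids[which(!lab %in% c("0", "1"))[1L]],
               lab[which(!lab %in% c("0", "1"))[1L]])
  if (!is.null(speciesSet) && any(!sp %in% speciesSet)) {
    bad <- which(!sp %in% speciesSet)[1L]
    .dataError("record '%s' has species '%s' outside the allowed set {%s}",
               ids[bad], sp[bad], paste(speciesSet, collapse = ", "))
  }
  DSiteDataset(as.character(raw), species = sp, labels = as.integer(lab),
               ids = ids)
}

#' Write a dataset to FASTA
#'
#' Inverse of [readFastaDataset()]: headers are `id<delim>species<delim>label`
#' and sequences are written in canonical (uppercase RNA) form, so
#' `readFastaDataset(writeFastaDataset(d, f))` reproduces `d` exactly.
#'
#' @param d a [DSiteDataset-class].
#' @param path output path.
#' @param delim header field delimiter.
#' @return `path`, invisibly.
#' @export
writeFastaDataset <- function(d, path, delim = "|") {
  stopifnot(is(d, "DSiteDataset"))
  out <- sequences(d)
  names(out) <- paste(names(d), species(d), siteLabels(d), sep = delim)
  ok <- tryCatch({
    Biostrings::writeXStringSet(out, filepath = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .dataError("cannot write FASTA to '%s'", path)
  invisible(path)
}

#' Validate a window dataset
#'
#' Reporting (never-throwing) check of the dataset against the window
#' contract: expected length, RNA alphabet, and — when `requireCentreU` —
#' a `U` at the centre position. Positions are 1-based; the centre of a 41-nt
#' window is position 21. The centre-base rule is reported at warning level:
#' negative windows are biologically candidate U sites, but input sources do
#' not all guarantee it, so it should not hard-fail a dataset.
#'
#' @param d a [DSiteDataset-class].
#' @param expectedLength required window length (default: the dataset's own).
#' @param requireCentreU also check that the centre base is `U`.
#' @return A data.frame with columns `id`, `rule` (`length`, `alphabet`,
#'   `centre_base`), `level` (`error`/`warning`) and `message`; zero rows iff
#'   the dataset is clean.
#' @export
validateDataset <- function(d, expectedLength = seqLength(d),
                            requireCentreU = FALSE) {
  stopifnot(is(d, "DSiteDataset"))
  rep0 <- data.frame(id = character(), rule = character(),
                     level = character(), message = character(),
                     stringsAsFactors = FALSE)
  if (length(d) == 0L) return(rep0)
  seqs <- as.character(sequences(d))
  reports <- list(rep0)
  wrong <- nchar(seqs) != expectedLength
  if (any(wrong))
    reports[["len"]] <- data.frame(
      id = names(d)[wrong], rule = "length", level = "error",
      message = sprintf("length %d, expected %d",
                        nchar(seqs)[wrong], expectedLength))
  badAlpha <- grepl("[^ACGU]", seqs)
  if (any(badAlpha))
    reports[["alpha"]] <- data.frame(
      id = names(d)[badAlpha], rule = "alphabet", level = "error",
      message = "contains characters outside A/C/G/U")
  if (requireCentreU && expectedLength %% 2L == 1L) {
    centre <- (expectedLength + 1L) %/% 2L
    checkable <- !wrong & !badAlpha
    ctr <- substr(seqs, centre, centre)
    badCentre <- checkable & ctr != "U"
    if (any(badCentre))
      reports[["centre"]] <- data.frame(
        id = names(d)[badCentre], rule = "centre_base", level = "warning",
        message = sprintf("centre position %d is '%s', expected 'U'",
                          centre, ctr[badCentre]))
  }
  out <- do.call(rbind, reports)
  rownames(out) <- NULL
  out
}

#' Per-species class composition of a dataset
#'
#' One row per species present, with positive and negative window counts
#' (the benchmark composition table of the five-species D-site data).
#'
#' @param d a [DSiteDataset-class].
#' @return data.frame with columns `species`, `positive`, `negative`,
#'   `total`; zero rows for an empty dataset. Species appear in
#'   [dsiteSpecies()] order when applicable, otherwise alphabetically last.
#' @export
datasetSummary <- function(d) {
  stopifnot(is(d, "DSiteDataset"))
  if (length(d) == 0L)
    return(data.frame(species = character(), positive = integer(),
                      negative = integer(), total = integer(),
                      stringsAsFactors = FALSE))
  sp <- unique(species(d))
  known <- intersect(dsiteSpecies(), sp)
  sp <- c(known, sort(setdiff(sp, known)))
  pos <- vapply(sp, function(s)
    sum(species(d) == s & siteLabels(d) == 1L), 0L)
  neg <- vapply(sp, function(s)
    sum(species(d) == s & siteLabels(d) == 0L), 0L)
  data.frame(species = sp, positive = unname(pos), negative = unname(neg),
             total = unname(pos + neg), stringsAsFactors = FALSE)
}

#' Write a dataset composition summary as TSV
#'
#' @param d a [DSiteDataset-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDatasetSummary <- function(d, path) {
  write.table(datasetSummary(d), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
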