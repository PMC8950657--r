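## Feature encoders: eleven schemes turning a fixed-length RNA window into a
## numeric vector. All encoders are pure (same input, bit-identical output)
## and sample-local: no training-set statistics enter any encoding, so
## encoding commutes with data splitting.

.RNA_BASES <- c("A", "C", "G", "U")

## Per-nucleotide chemistry bits, one column per base, rows in the fixed
## order (ring, functional group, hydrogen bond):
##   ring: purine {G, A} = 1, pyrimidine {U, C} = 0
##   functional group: amino {C, A} = 1, keto {U, G} = 0
##   hydrogen bond: weak {U, A} = 1, strong {G, C} = 0
.NCP_CODES <- matrix(
  c(1, 1, 1,   # A
    0, 1, 0,   # C
    1, 0, 0,   # G
    0, 0, 1),  # U
  nrow = 3L, dimnames = list(c("ring", "amino", "hbond"), .RNA_BASES))

## one-hot coordinates follow the scheme's conventional base order A,G,C,U
.BINARY_ORDER <- c("A", "G", "C", "U")

## electron-ion interaction potential; U inherits the T value. Standard
## published constants, kept in one editable table.
.EIIP_TABLE <- c(A = 0.1260, C = 0.1340, G = 0.0806, U = 0.1335)

#' Nucleotide chemistry and EIIP lookup tables
#'
#' `chemistryTable()` returns the 3-bit-per-nucleotide chemical property
#' codes (rows: ring structure, functional group, hydrogen bond; purine,
#' amino and weak-bond bases score 1). `eiipTable()` returns the
#' electron-ion interaction potential constants (U inherits the T value).
#'
#' @return `chemistryTable()`: a 3 x 4 0/1 matrix; `eiipTable()`: a named
#'   numeric vector over A, C, G, U.
#' @export
#' @examples
#' chemistryTable()["ring", "G"]  # purine -> 1
chemistryTable <- function() .NCP_CODES

#' @rdname chemistryTable
#' @export
eiipTable <- function() .EIIP_TABLE

## split + validate a sequence; every encoder funnels through this guard
.seqChars <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!ch %in% .RNA_BASES)
  if (length(bad))
    .dataError("invalid character '%s' at position %d (alphabet is A/C/G/U)",
               ch[bad[1L]], bad[1L])
  ch
}

## all 4^k k-mers in lexicographic order over A < C < G < U
.allKmers <- function(k) {
  out <- ""
  for (i in seq_len(k)) out <- paste0(rep(out, each = 4L), .RNA_BASES)
  out
}

#' Nucleotide chemical property (NCP) encoding
#'
#' Each position contributes three bits — ring structure (purine = 1),
#' functional group (amino = 1) and hydrogen bond (weak = 1) — giving
#' A = (1,1,1), C = (0,1,0), G = (1,0,0), U = (0,0,1) and a vector of length
#' `3 * nchar(seq)` (123 for a 41-nt window).
#'
#' @param seq a single RNA string over A/C/G/U.
#' @return Named numeric vector of 0/1 values.
#' @export
#' @examples
#' encodeNCP("A")  # 1 1 1
encodeNCP <- function(seq) {
  ch <- .seqChars(seq)
  out <- as.vector(.NCP_CODES[, ch, drop = FALSE])
  names(out) <- sprintf("P%02d.%s", rep(seq_along(ch), each = 3L),
                        rownames(.NCP_CODES))
  out
}

#' One-hot (BINARY) encoding
#'
#' Each position becomes a 4-bit one-hot block in the fixed base order
#' A, G, C, U: A = 1000, G = 0100, C = 0010, U = 0001. Length is
#' `4 * nchar(seq)` (164 for a 41-nt window); `"GAGACU"` begins `01001000`
#' and ends `0001`.
#'
#' @inheritParams encodeNCP
#' @return Named numeric 0/1 vector with exactly one 1 per 4-bit block.
#' @export
encodeBinary <- function(seq) {
  ch <- .seqChars(seq)
  out <- as.vector(vapply(ch, function(b) as.numeric(.BINARY_ORDER == b),
                          numeric(4L)))
  names(out) <- sprintf("P%02d.%s", rep(seq_along(ch), each = 4L),
                        .BINARY_ORDER)
  out
}

#' Enhanced nucleic acid composition (ENAC)
#'
#' A window of size `w` slides 5' to 3' with step 1; each window contributes
#' the four nucleotide frequencies within it (order A, C, G, U, summing to 1
#' per window). Length is `4 * (nchar(seq) - w + 1)` (148 for 41 nt, w = 5).
#'
#' @inheritParams encodeNCP
#' @param w sliding-window size (default 5, the scheme's conventional value).
#' @return Named numeric vector of window-local frequencies.
#' @export
encodeENAC <- function(seq, w = 5L) {
  ch <- .seqChars(seq)
  N <- length(ch)
  w <- as.integer(w)
  if (w < 1L || w > N)
    .configError("ENAC window %d invalid for sequence of length %d", w, N)
  starts <- seq_len(N - w + 1L)
  out <- vapply(starts, function(s) {
    win <- ch[s:(s + w - 1L)]
    vapply(.RNA_BASES, function(b) sum(win == b), 0L) / w
  }, numeric(4L))
  out <- as.vector(out)
  names(out) <- sprintf("W%02d.%s", rep(starts, each = 4L), .RNA_BASES)
  out
}

#' k-mer frequency encoding
#'
#' Counts every overlapping k-mer and normalizes: by the number of k-mer
#' positions `L - k + 1` (`denom = "kmer_count"`, the default; entries sum
#' to 1) or by the sequence length `L` (`denom = "seq_length"`). Entries are
#' ordered lexicographically over A < C < G < U; dimension `4^k`.
#'
#' @inheritParams encodeNCP
#' @param k k-mer size (>= 1; default 3).
#' @param denom denominator mode, `"kmer_count"` or `"seq_length"`.
#' @return Named numeric vector of length `4^k`.
#' @export
#' @examples
#' encodeKmer("GAGACU", k = 1)  # A C G U = 1/3 1/6 1/3 1/6
encodeKmer <- function(seq, k = 3L, denom = c("kmer_count", "seq_length")) {
  denom <- match.arg(denom)
  ch <- .seqChars(seq)
  L <- length(ch)
  k <- as.integer(k)
  if (k < 1L || k > L)
    .configError("k = %d invalid for sequence of length %d", k, L)
  kmers <- .allKmers(k)
  obs <- vapply(seq_len(L - k + 1L),
                function(i) paste(ch[i:(i + k - 1L)], collapse = ""), "")
  counts <- tabulate(match(obs, kmers), nbins = length(kmers))
  d <- if (denom == "kmer_count") L - k + 1L else L
  out <- counts / d
  names(out) <- kmers
  out
}

#' Mono-, di- and tri-nucleotide composition
#'
#' [encodeKmer()] with k fixed to 1 (NAC, length 4), 2 (DNC, length 16) or
#' 3 (TNC, length 64).
#'
#' @inheritParams encodeKmer
#' @return Named numeric vector.
#' @export
encodeNAC <- function(seq, denom = c("kmer_count", "seq_length"))
  encodeKmer(seq, k = 1L, denom = match.arg(denom))

#' @rdname encodeNAC
#' @export
encodeDNC <- function(seq, denom = c("kmer_count", "seq_length"))
  encodeKmer(seq, k = 2L, denom = match.arg(denom))

#' @rdname encodeNAC
#' @export
encodeTNC <- function(seq, denom = c("kmer_count", "seq_length"))
  encodeKmer(seq, k = 3L, denom = match.arg(denom))

#' Reverse complement of an RNA string
#'
#' RNA base pairing: A-U and C-G.
#'
#' @inheritParams encodeNCP
#' @return The reverse-complement string.
#' @export
reverseComplement <- function(seq) {
  ch <- .seqChars(seq)
  paste(rev(chartr("ACGU", "UGCA", ch)), collapse = "")
}

#' Canonical form of a k-mer under reverse complementation
#'
#' The lexicographic minimum of a k-mer and its RNA reverse complement;
#' idempotent. Collapsing all `4^k` k-mers yields 10 classes for k = 2 and
#' 32 for k = 3 (no odd-length k-mer is self reverse-complementary).
#'
#' @param m a k-mer string over A/C/G/U.
#' @return The canonical k-mer.
#' @export
#' @examples
#' canonicalKmer("UU")  # "AA"
canonicalKmer <- function(m) {
  rc <- reverseComplement(m)
  if (rc < m) rc else m
}

#' Reverse-complement k-mer (RCKmer) encoding
#'
#' k-mer counts pooled by [canonicalKmer()], so a sequence and its reverse
#' complement encode identically. Dimension is the number of canonical
#' classes (10 for k = 2, 32 for k = 3); denominators as in [encodeKmer()].
#'
#' @inheritParams encodeKmer
#' @return Named numeric vector over canonical k-mer classes.
#' @export
encodeRCKmer <- function(seq, k = 3L, denom = c("kmer_count", "seq_length")) {
  denom <- match.arg(denom)
  raw <- encodeKmer(seq, k = k, denom = denom)
  canon <- vapply(names(raw), canonicalKmer, "")
  classes <- sort(unique(vapply(.allKmers(as.integer(k)), canonicalKmer, "")))
  out <- vapply(classes, function(cl) sum(raw[canon == cl]), 0)
  names(out) <- classes
  out
}

#' Accumulated nucleotide frequency (ANF)
#'
#' Entry i is the density of the nucleotide at position i within the prefix
#' ending there: `count(seq[i] in seq[1..i]) / i`. Length equals the sequence
#' length; the first entry is always 1.
#'
#' @inheritParams encodeNCP
#' @return Named numeric vector with entries in (0, 1].
#' @export
#' @examples
#' encodeANF("GAGACU")  # 1 1/2 2/3 1/2 1/5 1/6
encodeANF <- function(seq) {
  ch <- .seqChars(seq)
  out <- vapply(seq_along(ch),
                function(i) sum(ch[seq_len(i)] == ch[i]) / i, 0)
  names(out) <- sprintf("P%02d.anf", seq_along(ch))
  out
}

#' Electron-ion interaction potential (EIIP) encoding
#'
#' Position i carries the EIIP constant of its nucleotide (see
#' [eiipTable()]); length equals the sequence length.
#'
#' @inheritParams encodeNCP
#' @param table EIIP constants to use (named over A, C, G, U).
#' @return Named numeric vector.
#' @export
encodeEIIP <- function(seq, table = eiipTable()) {
  ch <- .seqChars(seq)
  out <- unname(table[ch])
  names(out) <- sprintf("P%02d.eiip", seq_along(ch))
  out
}

#' Pseudo-EIIP trinucleotide encoding (PseEIIP)
#'
#' Entry for trinucleotide xyz is `(EIIP_x + EIIP_y + EIIP_z) * f_xyz`, where
#' `f_xyz` is the trinucleotide frequency over the `L - 2` positions; 64
#' entries in lexicographic order.
#'
#' @inheritParams encodeEIIP
#' @return Named numeric vector of length 64.
#' @export
encodePseEIIP <- function(seq, table = eiipTable()) {
  ch <- .seqChars(seq)
  if (length(ch) < 3L)
    .configError("PseEIIP requires length >= 3, got %d", length(ch))
  f <- encodeKmer(seq, k = 3L, denom = "kmer_count")
  tri <- names(f)
  eiipSum <- vapply(strsplit(tri, "", fixed = TRUE),
                    function(b) sum(table[b]), 0)
  out <- eiipSum * f
  names(out) <- tri
  out
}

#' Encoder specification
#'
#' Names one of the eleven encoding schemes together with its parameters;
#' unknown schemes and parameters invalid for the named scheme are rejected.
#'
#' @param name one of `encoderNames()`.
#' @param k k-mer size, only for `Kmer` / `RCKmer` (default 3).
#' @param window sliding-window size, only for `ENAC` (default 5).
#' @param denom k-mer denominator mode (`"kmer_count"` or `"seq_length"`),
#'   only for the Kmer family.
#' @return An object of class `dsite_encoder_spec`.
#' @export
#' @examples
#' encoderSpec("ENAC", window = 5)
encoderSpec <- function(name, k = NULL, window = NULL, denom = NULL) {
  if (length(name) != 1L || !name %in% encoderNames())
    .configError("unknown encoding scheme '%s'; valid schemes: %s",
                 as.character(name)[1L],
                 paste(encoderNames(), collapse = ", "))
  params <- list()
  if (name %in% c("Kmer", "RCKmer")) {
    params$k <- as.integer(if (is.null(k)) 3L else k)
    if (params$k < 1L) .configError("k must be >= 1")
    params$denom <- if (is.null(denom)) "kmer_count"
                    else match.arg(denom, c("kmer_count", "seq_length"))
  } else if (name %in% c("NAC", "DNC", "TNC")) {
    params$denom <- if (is.null(denom)) "kmer_count"
                    else match.arg(denom, c("kmer_count", "seq_length"))
    if (!is.null(k)) .configError("%s has fixed k; do not pass k", name)
  } else if (name == "ENAC") {
    params$window <- as.integer(if (is.null(window)) 5L else window)
    if (params$window < 1L) .configError("ENAC window must be >= 1")
  } else {
    if (!is.null(k) || !is.null(window) || !is.null(denom))
      .configError("scheme %s takes no parameters", name)
  }
  structure(c(list(name = name), params), class = "dsite_encoder_spec")
}

#' @export
print.dsite_encoder_spec <- function(x, ...) {
  ps <- x[setdiff(names(x), "name")]
  cat(sprintf("encoder %s%s\n", x$name,
              if (length(ps)) paste0(" (", paste(names(ps), unlist(ps),
                                                 sep = "=", collapse = ", "),
                                     ")") else ""))
  invisible(x)
}

#' The eleven encoding scheme names
#'
#' @return Character vector of valid scheme names.
#' @export
encoderNames <- function() {
  c("NCP", "BINARY", "ENAC", "Kmer", "RCKmer", "NAC", "DNC", "TNC",
    "ANF", "EIIP", "PseEIIP")
}

## dispatch one sequence through the scheme named by a spec
.encodeOne <- function(seq, spec) {
  switch(spec$name,
    NCP     = encodeNCP(seq),
    BINARY  = encodeBinary(seq),
    ENAC    = encodeENAC(seq, w = spec$window),
    Kmer    = encodeKmer(seq, k = spec$k, denom = spec$denom),
    RCKmer  = encodeRCKmer(seq, k = spec$k, denom = spec$denom),
    NAC     = encodeNAC(seq, denom = spec$denom),
    DNC     = encodeDNC(seq, denom = spec$denom),
    TNC     = encodeTNC(seq, denom = spec$denom),
    ANF     = encodeANF(seq),
    EIIP    = encodeEIIP(seq),
    PseEIIP = encodePseEIIP(seq),
    .configError("unknown scheme '%s'", spec$name))
}

#' Expected feature dimension of a scheme for a given window length
#'
#' @param spec an [encoderSpec()].
#' @param seqLen sequence length in nt.
#' @return Integer dimension (e.g. 123 for NCP at 41 nt).
#' @export
encoderDim <- function(spec, seqLen) {
  seqLen <- as.integer(seqLen)
  switch(spec$name,
    NCP     = 3L * seqLen,
    BINARY  = 4L * seqLen,
    ENAC    = 4L * (seqLen - spec$window + 1L),
    Kmer    = as.integer(4L^spec$k),
    RCKmer  = length(unique(vapply(.allKmers(spec$k), canonicalKmer, ""))),
    NAC     = 4L,
    DNC     = 16L,
    TNC     = 64L,
    ANF     = seqLen,
    EIIP    = seqLen,
    PseEIIP = 64L)
}

#' Encode every record of a dataset
#'
#' Applies the scheme named by `spec` to each record, preserving record
#' order; per-record encoding errors are re-raised with the offending record
#' id. An empty dataset yields a 0-row matrix with the correct feature names
#' for the dataset's window length.
#'
#' @param d a [DSiteDataset-class].
#' @param spec an [encoderSpec()] (or a scheme name, taken with defaults).
#' @return A [FeatureMatrix-class] (rows = records, columns = features).
#' @export
#' @examples
#' d <- DSiteDataset(c(a = "GAGACU", b = "ACGUAC"),
#'                   species = "E.coli", labels = c(1, 0))
#' dim(encodeDataset(d, encoderSpec("NCP")))
encodeDataset <- function(d, spec) {
  stopifnot(is(d, "DSiteDataset"))
  if (is.character(spec)) spec <- encoderSpec(spec)
  stopifnot(inherits(spec, "dsite_encoder_spec"))
  if (length(d) == 0L) {
    template <- .encodeOne(paste(rep("A", seqLength(d)), collapse = ""), spec)
    vals <- matrix(numeric(0), nrow = 0L, ncol = length(template),
                   dimnames = list(NULL, names(template)))
    return(new("FeatureMatrix", values = vals, encoder = unclass(spec)))
  }
  seqs <- as.character(sequences(d))
  rows <- lapply(seq_along(seqs), function(i)
    tryCatch(.encodeOne(seqs[[i]], spec), error = function(e)
      .dataError("record '%s': %s", names(d)[i], conditionMessage(e))))
  vals <- do.call(rbind, rows)
  rownames(vals) <- names(d)
  new("FeatureMatrix", values = vals, encoder = unclass(spec))
}

#' Write a FeatureMatrix as TSV with a JSON sidecar
#'
#' The TSV has the sample id as its first column and feature names as the
#' header; the sidecar (`<path>.json`) records the generating encoder spec so
#' matrices remain self-describing on disk.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path) {
  stopifnot(is(fm, "FeatureMatrix"))
  vals <- featureValues(fm)
  df <- data.frame(id = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(encoderOf(fm), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}
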