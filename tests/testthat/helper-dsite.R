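## shared fixture builders (everything is generated in code at test time)

randomRnaSeq <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

## small labelled dataset with U-centred windows of odd length
toyDataset <- function(n = 10L, len = 11L, seed = 42L,
                       speciesLabels = "S.cerevisiae") {
  set.seed(seed)
  centre <- (len + 1L) %/% 2L
  seqs <- vapply(seq_len(n), function(i) {
    s <- strsplit(randomRnaSeq(len), "")[[1L]]
    s[centre] <- "U"
    paste(s, collapse = "")
  }, "")
  DSiteDataset(seqs, species = rep_len(speciesLabels, n),
               labels = rep_len(c(1L, 0L), n),
               ids = sprintf("toy%02d", seq_len(n)))
}

## linearly separable two-feature toy: positives around (3, 3), negatives
## around (0, 0)
separableToy <- function(n = 20L, seed = 7L) {
  set.seed(seed)
  half <- n %/% 2L
  X <- rbind(matrix(rnorm(half * 2L, mean = 3, sd = 0.3), ncol = 2L),
             matrix(rnorm((n - half) * 2L, mean = 0, sd = 0.3), ncol = 2L))
  colnames(X) <- c("f1", "f2")
  rownames(X) <- sprintf("t%02d", seq_len(n))
  list(X = X, y = rep(c(1L, 0L), c(half, n - half)))
}

## independent brute-force k-mer counter: explicit position loop with
## substring comparison (never shares code with the encoder under test)
bruteKmerFreq <- function(seq, k, denom = c("kmer_count", "seq_length")) {
  denom <- match.arg(denom)
  L <- nchar(seq)
  bases <- c("A", "C", "G", "U")
  kmers <- ""
  for (i in seq_len(k)) kmers <- paste0(rep(kmers, each = 4L), bases)
  counts <- setNames(integer(length(kmers)), kmers)
  for (pos in seq_len(L - k + 1L)) {
    m <- substr(seq, pos, pos + k - 1L)
    counts[m] <- counts[m] + 1L
  }
  counts / if (denom == "kmer_count") L - k + 1L else L
}

## standard TP/TN/FP/FN metric formulation, independent of the package's
## count-based implementation
standardMetrics <- function(tp, tn, fp, fn) {
  list(Sn = tp / (tp + fn), Sp = tn / (tn + fp),
       Acc = (tp + tn) / (tp + tn + fp + fn),
       MCC = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

## quick composition config for small synthetic datasets
smallSynthConfig <- function(nPos = 30L, nNeg = 30L, nSpecies = 2L, ...) {
  sp <- dsiteSpecies()[seq_len(nSpecies)]
  syntheticConfig(counts = data.frame(species = sp,
                                      positive = rep(nPos, nSpecies),
                                      negative = rep(nNeg, nSpecies)),
                  ...)
}
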