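## Synthetic benchmark generator: datasets shaped like the five-species
## dihydrouridine benchmark (550 windows of 41 nt, 176 positive / 374
## negative) with a controllable positional motif so every pipeline stage is
## testable without downloading the real data.

## per-species positive/negative composition of the emulated benchmark
.TABLE5_COUNTS <- data.frame(
  species = c("H.sapiens", "M.musculus", "D.melanogaster",
              "S.cerevisiae", "E.coli"),
  positive = c(29L, 13L, 9L, 91L, 34L),
  negative = c(68L, 48L, 38L, 93L, 127L),
  stringsAsFactors = FALSE)

## fixed preferred-base profile on the 10 positions flanking the centre
## (offsets -5..-1, +1..+5); chosen once, position-specific so that both
## position-aware (NCP/BINARY/ENAC) and composition-aware (Kmer family)
## encoders can see it
.MOTIF_OFFSETS <- c(-5:-1, 1:5)
.MOTIF_PREFS <- c("G", "A", "U", "C", "G", "A", "U", "G", "C", "A")

#' Synthetic dataset configuration
#'
#' Defaults emulate the five-species benchmark composition exactly:
#' H.sapiens 29/68, M.musculus 13/48, D.melanogaster 9/38, S.cerevisiae
#' 91/93, E.coli 34/127 positive/negative 41-nt windows (550 in total, 176
#' positive / 374 negative), every window U-centred.
#'
#' Negatives are drawn i.i.d. from the background composition; positives
#' share the background except on the ten positions flanking the centre,
#' where a fixed preferred-base profile is tilted with log-odds
#' `effectSize`: the probability of base b at a motif position is
#' proportional to `background[b] * exp(effectSize * [b is preferred])`.
#' `effectSize = 0` makes the two classes identically distributed (a null
#' dataset); the documented reference "strong" value is 2 (preferred-base
#' probability about 0.71 on uniform background).
#'
#' @param counts data.frame with columns `species`, `positive`, `negative`.
#' @param length window length in nt (odd; default 41).
#' @param effectSize motif log-odds tilt, >= 0 (default 2).
#' @param background named base probabilities over A, C, G, U (default
#'   uniform; must sum to 1).
#' @param divergentSpecies optional species whose positives use an unrelated
#'   (complemented) preferred-base profile — used to plant a
#'   cross-species-divergent signal.
#' @param seed RNG seed.
#' @return An object of class `dsite_synth_config`.
#' @export
syntheticConfig <- function(counts = .TABLE5_COUNTS, length = 41L,
                            effectSize = 2,
                            background = c(A = .25, C = .25, G = .25, U = .25),
                            divergentSpecies = NULL, seed = 1L) {
  length <- as.integer(length)
  if (length < 11L || length %% 2L == 0L)
    .configError("window length must be odd and >= 11, got %d", length)
  stopifnot(is.data.frame(counts),
            all(c("species", "positive", "negative") %in% names(counts)))
  if (any(counts$positive < 0L) || any(counts$negative < 0L))
    .configError("species counts must be non-negative")
  if (!is.numeric(effectSize) || effectSize < 0)
    .configError("effectSize must be >= 0")
  background <- background[.RNA_BASES]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-8)
    .configError("background must be named over A,C,G,U and sum to 1")
  if (!is.null(divergentSpecies) && !divergentSpecies %in% counts$species)
    .configError("divergentSpecies '%s' not in the species table",
                 divergentSpecies)
  structure(list(counts = counts, length = length, effectSize = effectSize,
                 background = background, divergentSpecies = divergentSpecies,
                 seed = as.integer(seed)),
            class = "dsite_synth_config")
}

## base probabilities at one motif position given the preferred base
.motifProbs <- function(background, preferred, effectSize) {
  w <- background * exp(effectSize * (.RNA_BASES == preferred))
  w / sum(w)
}

#' Generate a synthetic benchmark-shaped dataset
#'
#' Deterministic given the config's seed: per-species positive and negative
#' counts match the config exactly, every window carries `U` at the centre,
#' and positives carry the positional motif at strength `effectSize` (see
#' [syntheticConfig()]). Species listed as `divergentSpecies` plant their
#' positives on the complemented profile instead.
#'
#' @param cfg a [syntheticConfig()].
#' @return A [DSiteDataset-class].
#' @export
#' @examples
#' d <- generateDataset(syntheticConfig(seed = 7))
#' datasetSummary(d)
generateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "dsite_synth_config"))
  L <- cfg$length
  centre <- (L + 1L) %/% 2L
  motifPos <- centre + .MOTIF_OFFSETS
  .withSeed(cfg$seed, {
    seqs <- character(); sp <- character(); lab <- integer(); ids <- character()
    for (i in seq_len(nrow(cfg$counts))) {
      s <- cfg$counts$species[i]
      prefs <- if (!is.null(cfg$divergentSpecies) &&
                   s %in% cfg$divergentSpecies)
        chartr("ACGU", "UGCA", .MOTIF_PREFS) else .MOTIF_PREFS
      tag <- gsub("[^A-Za-z]", "", s)
      for (cls in c(1L, 0L)) {
        n <- if (cls == 1L) cfg$counts$positive[i] else cfg$counts$negative[i]
        if (n == 0L) next
        mat <- matrix(sample(.RNA_BASES, n * L, replace = TRUE,
                             prob = cfg$background), nrow = n)
        if (cls == 1L && cfg$effectSize > 0) {
          for (j in seq_along(motifPos)) {
            p <- .motifProbs(cfg$background, prefs[j], cfg$effectSize)
            mat[, motifPos[j]] <- sample(.RNA_BASES, n, replace = TRUE,
                                         prob = p)
          }
        }
        mat[, centre] <- "U"
        seqs <- c(seqs, apply(mat, 1L, paste, collapse = ""))
        sp <- c(sp, rep(s, n))
        lab <- c(lab, rep(cls, n))
        ids <- c(ids, sprintf("%s_%s_%03d", tag,
                              if (cls == 1L) "pos" else "neg", seq_len(n)))
      }
    }
    DSiteDataset(seqs, species = sp, labels = lab, ids = ids,
                 seqLength = L)
  })
}

#' Write the generating config as a JSON manifest
#'
#' @param cfg a [syntheticConfig()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSyntheticManifest <- function(cfg, path) {
  out <- unclass(cfg)
  out$background <- as.list(out$background)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Frozen worked-example fixtures for the encoders
#'
#' The small sequences the encoding schemes are conventionally illustrated
#' on, with their expected feature vectors attached as golden values:
#' `"GAGACU"` (NCP, one-hot, mono-nucleotide composition, accumulated
#' frequency), the `"AAAAA"` homopolymer (single sliding window), the
#' reverse-complement pair `("UU", "AA")` (canonical k-mer pooling), and
#' `"ACG"` (single-trinucleotide PseEIIP).
#'
#' @return Named list of fixtures; each has `seq` and an `expect` list of
#'   golden vectors keyed by scheme.
#' @export
generateWorkedExample <- function() {
  eiip <- eiipTable()
  pse <- setNames(numeric(64), .allKmers(3L))
  pse["ACG"] <- sum(eiip[c("A", "C", "G")])
  list(
    gagacu = list(
      seq = "GAGACU",
      expect = list(
        NCP = c(1, 0, 0,  1, 1, 1,  1, 0, 0,  1, 1, 1,  0, 1, 0,  0, 0, 1),
        BINARY = c(0, 1, 0, 0,  1, 0, 0, 0,  0, 1, 0, 0,  1, 0, 0, 0,
                   0, 0, 1, 0,  0, 0, 0, 1),
        NAC = c(A = 1 / 3, C = 1 / 6, G = 1 / 3, U = 1 / 6),
        ANF = c(1, 1 / 2, 2 / 3, 1 / 2, 1 / 5, 1 / 6))),
    homopolymerA5 = list(
      seq = "AAAAA",
      expect = list(ENAC = c(1, 0, 0, 0))),
    homopolymerA4 = list(
      seq = "AAAA",
      expect = list(
        EIIP = rep(unname(eiip["A"]), 4L),
        Kmer2_seq_length = 0.75,       # AA entry under the seq-length denominator
        PseEIIP_AAA = 3 * unname(eiip["A"]))),
    rcPair = list(
      seq = c("UU", "AA"),
      expect = list(canonical = "AA")),
    acg = list(
      seq = "ACG",
      expect = list(PseEIIP = pse)))
}
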