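test_that("worked-example golden vectors are reproduced by every scheme", {
  wx <- generateWorkedExample()

  g <- wx$gagacu
  expect_equal(unname(encodeNCP(g$seq)), g$expect$NCP)
  expect_equal(unname(encodeBinary(g$seq)), g$expect$BINARY)
  expect_equal(encodeNAC(g$seq), g$expect$NAC, ignore_attr = TRUE)
  expect_equal(unname(encodeANF(g$seq)), g$expect$ANF)
  # one-hot worked string: begins 01001000, ends 0001
  bits <- paste(encodeBinary(g$seq), collapse = "")
  expect_identical(substr(bits, 1, 8), "01001000")
  expect_identical(substr(bits, nchar(bits) - 3, nchar(bits)), "0001")

  expect_equal(unname(encodeENAC(wx$homopolymerA5$seq, w = 5)),
               wx$homopolymerA5$expect$ENAC)
  expect_equal(unname(encodeEIIP(wx$homopolymerA4$seq)),
               wx$homopolymerA4$expect$EIIP)
  expect_equal(encodeKmer(wx$homopolymerA4$seq, k = 2,
                          denom = "seq_length")[["AA"]],
               wx$homopolymerA4$expect$Kmer2_seq_length)
  pse <- encodePseEIIP(wx$homopolymerA4$seq)
  expect_equal(pse[["AAA"]], wx$homopolymerA4$expect$PseEIIP_AAA)
  expect_true(all(pse[names(pse) != "AAA"] == 0))
  expect_equal(encodePseEIIP(wx$acg$seq), wx$acg$expect$PseEIIP,
               ignore_attr = TRUE)

  # per-nucleotide chemistry codes
  expect_equal(unname(encodeNCP("A")), c(1, 1, 1))
  expect_equal(unname(encodeNCP("U")), c(0, 0, 1))
  expect_equal(unname(encodeNCP("C")), c(0, 1, 0))
  expect_equal(unname(encodeNCP("G")), c(1, 0, 0))
  expect_equal(unname(encodeBinary("C")), c(0, 0, 1, 0))
  expect_equal(unname(encodeBinary("U")), c(0, 0, 0, 1))
})

test_that("feature dimensions match the scheme formulas at 41 nt", {
  expected <- list(
    list(encoderSpec("NCP"), 123L), list(encoderSpec("BINARY"), 164L),
    list(encoderSpec("ENAC"), 148L), list(encoderSpec("NAC"), 4L),
    list(encoderSpec("DNC"), 16L), list(encoderSpec("TNC"), 64L),
    list(encoderSpec("Kmer", k = 3), 64L),
    list(encoderSpec("RCKmer", k = 2), 10L),
    list(encoderSpec("RCKmer", k = 3), 32L),
    list(encoderSpec("ANF"), 41L), list(encoderSpec("EIIP"), 41L),
    list(encoderSpec("PseEIIP"), 64L))
  d <- toyDataset(3L, len = 41L)
  for (case in expected) {
    expect_identical(encoderDim(case[[1]], 41L), case[[2]],
                     info = case[[1]]$name)
    expect_identical(ncol(encodeDataset(d, case[[1]])), case[[2]],
                     info = case[[1]]$name)
  }
})

test_that("k-mer family agrees with the brute-force substring oracle", {
  set.seed(11)
  for (i in 1:50) {
    s <- randomRnaSeq(sample(10:60, 1))
    for (k in 1:3) {
      for (dm in c("kmer_count", "seq_length")) {
        expect_equal(encodeKmer(s, k, dm), bruteKmerFreq(s, k, dm))
      }
    }
  }
  # fixed-k aliases are exactly Kmer at k = 1, 2, 3
  s <- randomRnaSeq(41)
  expect_identical(encodeNAC(s), encodeKmer(s, 1))
  expect_identical(encodeDNC(s), encodeKmer(s, 2))
  expect_identical(encodeTNC(s), encodeKmer(s, 3))
  expect_equal(sum(encodeTNC(s)), 1)
  expect_equal(encodeKmer("GAGACU", k = 1),
               c(A = 1/3, C = 1/6, G = 1/3, U = 1/6))
  expect_equal(encodeKmer("AAAA", k = 2)[["AA"]], 1)
})

test_that("canonical k-mers pool reverse complements correctly", {
  expect_identical(canonicalKmer("UU"), "AA")
  expect_identical(canonicalKmer("AU"), "AU")
  expect_identical(canonicalKmer("GA"), "GA")   # RC(GA) = UC > GA
  # idempotence and class counts over the full k-mer universe
  for (k in 2:3) {
    all_k <- names(encodeKmer(randomRnaSeq(10), k))
    canon <- vapply(all_k, canonicalKmer, "")
    expect_identical(canon, vapply(canon, canonicalKmer, ""))
    expect_identical(length(unique(canon)), c(10L, 32L)[k - 1L])
  }
  expect_equal(encodeRCKmer("UUUU", k = 2)[["AA"]], 1)
  # strand-collapse symmetry on random sequences
  set.seed(3)
  for (i in 1:20) {
    s <- randomRnaSeq(sample(10:40, 1))
    expect_equal(encodeRCKmer(s, 3), encodeRCKmer(reverseComplement(s), 3))
  }
})

test_that("positional encoders respect their block structure", {
  set.seed(5)
  for (i in 1:20) {
    s <- randomRnaSeq(sample(6:41, 1))
    b <- encodeBinary(s)
    blocks <- matrix(b, nrow = 4)
    expect_true(all(colSums(blocks) == 1))          # one-hot per position
    n <- encodeNCP(s)
    codes <- apply(matrix(n, nrow = 3), 2, paste, collapse = "")
    expect_true(all(codes %in% c("111", "010", "100", "001")))
    e <- encodeENAC(s, w = 5)
    expect_equal(unname(colSums(matrix(e, nrow = 4))),
                 rep(1, nchar(s) - 4))               # windows sum to 1
    a <- encodeANF(s)
    expect_equal(a[[1]], 1)
    expect_true(all(a > 0 & a <= 1))
  }
  expect_equal(unname(encodeENAC("GAGAC", w = 5)), c(0.4, 0.2, 0.4, 0))
})

test_that("encoders are pure and encodeDataset matches per-record encoding", {
  s <- randomRnaSeq(41)
  expect_identical(encodeNCP(s), encodeNCP(s))
  expect_identical(encodePseEIIP(s), encodePseEIIP(s))

  d <- toyDataset(5L, len = 41L)
  fm <- encodeDataset(d, encoderSpec("ENAC"))
  expect_s4_class(fm, "FeatureMatrix")
  expect_identical(rownames(featureValues(fm)), names(d))
  for (i in seq_len(5))
    expect_equal(featureValues(fm)[i, ],
                 encodeENAC(as.character(sequences(d))[[i]]))
  expect_identical(encoderOf(fm)$name, "ENAC")

  empty <- encodeDataset(d[0], encoderSpec("NCP"))
  expect_identical(dim(empty), c(0L, 123L))
  expect_identical(colnames(featureValues(empty)),
                   names(encodeNCP(randomRnaSeq(41))))
})

test_that("encoding errors carry position, parameter and record context", {
  expect_error(encodeNCP("ACGN"), "position 4")
  expect_error(encodeEIIP("ACGNA"), "position")
  expect_error(encodeENAC("ACGU", w = 5), "window")
  expect_error(encodeKmer("ACG", k = 4), "invalid")
  expect_error(encodePseEIIP("AC"), "length >= 3")
  expect_error(encoderSpec("SSC"), "NCP")   # error lists the valid schemes
  expect_error(encoderSpec("NCP", k = 2), "parameters")

  d <- DSiteDataset(c(ok = "ACGUACG", bad = "ACGNACG"),
                    species = "E.coli", labels = c(1L, 0L))
  expect_error(encodeDataset(d, "NCP"), "bad")
})
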