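test_that("alignPair handles identical and simple indel inputs", {
  a <- alignPair("ACGTACGT", "ACGTACGT")
  expect_equal(refAligned(a), "ACGTACGT")
  expect_equal(qryAligned(a), "ACGTACGT")

  a <- alignPair("AAAATTTT", "AAAATT", params = alignParams(k = 3))
  expect_equal(nchar(refAligned(a)), 8L)
  expect_equal(sum(strsplit(qryAligned(a), "")[[1]] == "-"), 2L)
  expect_equal(alignmentScore(a, alignParams(k = 3)),
               gotohScore("AAAATTTT", "AAAATT"))
})

test_that("alignPair attains the dynamic-programming optimum", {
  set.seed(23)
  bases <- c("A", "C", "G", "T")
  for (case in 1:6) {
    n <- sample(60:200, 1)
    ref <- paste(sample(bases, n, TRUE), collapse = "")
    # mutate lightly so anchors exist for some cases
    ch <- strsplit(ref, "")[[1]]
    nm <- sample(2:6, 1)
    idx <- sample(seq_along(ch), nm)
    ch[idx] <- sample(bases, nm, TRUE)
    if (case %% 2 == 0) ch <- ch[-sample(seq_along(ch), 3)]
    qry <- paste(ch, collapse = "")
    a <- alignPair(ref, qry)
    expect_equal(alignmentScore(a), gotohScore(ref, qry),
                 info = paste("case", case))
  }
})

test_that("alignPair refuses rearranged input it cannot anchor", {
  set.seed(41)
  ref <- paste(sample(c("A", "C", "G", "T"), 12000, TRUE), collapse = "")
  expect_error(alignPair(ref, revComp(ref)), "unalignable")
})

test_that("the reference row of alignPair reproduces the reference", {
  cfg <- smallConfig()
  rec <- generatePlastome(cfg, seed = 14)
  div <- applyDivergence(rec, rate = 0.01, config = cfg, seed = 15)
  ref <- stripIRa(rec)
  a <- alignPair(ref, stripIRa(div$record))
  expect_equal(gsub("-", "", refAligned(a)), ref)
})

test_that("adjustToReference trims overhangs and pads with N", {
  a <- adjustToReference(AlignedPair("--ACGT", "GGACGT"))
  expect_equal(refAligned(a), "ACGT")
  expect_equal(qryAligned(a), "ACGT")

  a <- adjustToReference(AlignedPair("ACGT", "--GT"))
  expect_equal(qryAligned(a), "NNGT")

  # afterwards: length = reference length + internal insertions
  a <- adjustToReference(AlignedPair("AC-GT--", "ACTGTAA"))
  expect_equal(nchar(refAligned(a)),
               nchar(gsub("-", "", refAligned(a))) +
                 sum(strsplit(refAligned(a), "")[[1]] == "-"))
  expect_equal(refAligned(a), "AC-GT")
})

test_that("classifyAlignment matches hand-traced example alignments", {
  p <- classifyAlignment(AlignedPair("ACGTAAAAATGC", "ACGTAAA--TGC"))
  expect_equal(p@substitutions, 0L)
  expect_equal(p@deletedBases, 2L)
  expect_equal(p@deletionEvents, 1L)
  expect_equal(p@insertedBases, 0L)
  expect_equal(p@nPositions, 0L)
  expect_equal(mismatchCount(p), 2L)

  p <- classifyAlignment(AlignedPair("AC-GT", "AGTGT"))
  expect_equal(p@substitutions, 1L)
  expect_equal(p@insertedBases, 1L)
  expect_equal(p@insertionEvents, 1L)
  expect_equal(mismatchCount(p), 2L)
})

test_that("double-gap columns are rejected", {
  expect_error(AlignedPair("A-C", "A-C"), "gap in both")
})

test_that("classifyAlignment equals the naive column-scan oracle", {
  set.seed(99)
  for (i in 1:200) {
    a <- randomAlignment(sample(20:120, 1))
    p <- classifyAlignment(a)
    o <- naiveClassify(refAligned(a), qryAligned(a))
    expect_equal(p@substitutions, o$substitutions)
    expect_equal(p@deletedBases, o$deletedBases)
    expect_equal(p@deletionEvents, o$deletionEvents)
    expect_equal(p@insertedBases, o$insertedBases)
    expect_equal(p@insertionEvents, o$insertionEvents)
    expect_equal(p@nPositions, o$nPositions)
    expect_equal(mismatchCount(p), o$mismatches)
  }
})

test_that("a 10 kb simulated pair recovers the planted taxonomy", {
  cfg <- SimulationConfig(regionLengths = c(lsc = 7000L, ir = 2000L,
                                            ssc = 1500L))
  rec <- generatePlastome(cfg, seed = 51)
  div <- applyDivergence(rec, rate = 0.01, config = cfg, seed = 52)
  aln <- adjustToReference(alignPair(stripIRa(rec), stripIRa(div$record)))
  p <- classifyAlignment(aln)
  tr <- div$truth
  expect_equal(p@substitutions, sum(tr$type == "sub"))
  expect_equal(p@deletedBases, sum(tr$length[tr$type == "del"]))
  expect_equal(p@insertedBases, sum(tr$length[tr$type == "ins"]))
  expect_equal(p@deletionEvents, sum(tr$type == "del"))
  expect_equal(p@insertionEvents, sum(tr$type == "ins"))
})

test_that("identityPercent reproduces the published convention", {
  expect_equal(identityPercent(MismatchProfile(1, 24, 0,
                                               refLength = 125633)), 99.98)
  expect_equal(identityPercent(MismatchProfile(67, 253, 42,
                                               refLength = 125633,
                                               nPositions = 152)), 99.59)
  expect_equal(identityPercent(MismatchProfile(0, 0, 0, refLength = 1000)),
               100.00)
})

test_that("identityPercent is monotone in each mismatch count", {
  base <- identityPercent(MismatchProfile(10, 10, 10, refLength = 5000),
                          digits = 6)
  for (bump in list(c(1, 0, 0), c(0, 1, 0))) {
    worse <- identityPercent(
      MismatchProfile(10 + bump[1], 10 + bump[2], 10,
                      alignmentLength = 5010L), digits = 6)
    expect_lt(worse, base)
  }
})

test_that("aligned FASTA round trips through read/write", {
  a <- AlignedPair("AC-GTA", "ACTG-A")
  path <- tempfile(fileext = ".afa")
  writeAlignedFasta(a, path)
  b <- readAlignedFasta(path)
  expect_equal(refAligned(b), refAligned(a))
  expect_equal(qryAligned(b), qryAligned(a))
})
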