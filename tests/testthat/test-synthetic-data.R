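test_that("every stochastic operation is a pure function of its seed", {
  cfg <- smallConfig(chimeraRate = 0.2)
  r1 <- generatePlastome(cfg, seed = 5)
  r2 <- generatePlastome(cfg, seed = 5)
  expect_identical(plastomeSequence(r1), plastomeSequence(r2))
  expect_false(identical(plastomeSequence(r1),
                         plastomeSequence(generatePlastome(cfg, seed = 6))))

  d1 <- applyDivergence(r1, config = cfg, seed = 7)
  d2 <- applyDivergence(r1, config = cfg, seed = 7)
  expect_identical(plastomeSequence(d1$record), plastomeSequence(d2$record))
  expect_identical(d1$truth, d2$truth)

  c1 <- corruptConsensus(stripIRa(r1), config = cfg, seed = 8)
  c2 <- corruptConsensus(stripIRa(r1), config = cfg, seed = 8)
  expect_identical(c1$sequence, c2$sequence)

  a1 <- simulateAmpliconPanel(r1, smallPanelConfig(), seed = 9)
  a2 <- simulateAmpliconPanel(r1, smallPanelConfig(), seed = 9)
  expect_identical(a1, a2)

  s1 <- simulateReads(a1, cfg, nReads = 20, seed = 10)
  s2 <- simulateReads(a1, cfg, nReads = 20, seed = 10)
  expect_identical(s1, s2)

  # seeding does not disturb the caller's RNG stream
  set.seed(123); x <- runif(1)
  set.seed(123); invisible(generatePlastome(cfg, seed = 5)); y <- runif(1)
  expect_identical(x, y)
})

test_that("generated genomes match the configured shape and composition", {
  cfg <- SimulationConfig(regionLengths = c(lsc = 40000L, ir = 8000L,
                                            ssc = 6000L), gcTarget = 0.5)
  rec <- generatePlastome(cfg, seed = 17)
  expect_equal(nchar(plastomeSequence(rec)), 40000 + 2 * 8000 + 6000)
  expect_lt(abs(gcFraction(plastomeSequence(rec)) - 0.5), 0.01)
  expect_true(validObject(rec))

  cfg2 <- smallConfig()   # default 37.45% target
  rec2 <- generatePlastome(cfg2, seed = 18)
  expect_lt(abs(gcFraction(plastomeSequence(rec2)) - 0.3745), 0.02)
})

test_that("applyDivergence preserves the IR invariant and writes truth", {
  cfg <- smallConfig()
  rec <- generatePlastome(cfg, seed = 19)
  div <- applyDivergence(rec, config = cfg, seed = 20)
  out <- div$record
  expect_true(validObject(out))
  expect_equal(regionSequence(out, "IRB"),
               revComp(regionSequence(out, "IRA")))
  expect_gt(nrow(div$truth), 0)
  # zero rate leaves the record untouched
  null <- applyDivergence(rec, rate = 0, config = cfg, seed = 21)
  expect_identical(plastomeSequence(null$record), plastomeSequence(rec))
  expect_equal(nrow(null$truth), 0L)
})

test_that("corruptConsensus with zero rates yields perfect identity", {
  cfg <- smallConfig(errorRate = 0)
  rec <- generatePlastome(cfg, seed = 22)
  ref <- stripIRa(rec)
  cor <- corruptConsensus(ref, config = cfg, seed = 23)
  expect_identical(cor$sequence, ref)
  aln <- adjustToReference(alignPair(ref, cor$sequence))
  expect_equal(identityPercent(classifyAlignment(aln)), 100.00)
})

test_that("hpBias = 1 reduces to the genomic null for deletion context", {
  cfg <- SimulationConfig(regionLengths = c(lsc = 20000L, ir = 5000L,
                                            ssc = 4000L), hpBias = 1,
                          errorRate = 0.008)
  rec <- generatePlastome(cfg, seed = 24)
  ref <- stripIRa(rec)
  cor <- corruptConsensus(ref, config = cfg, seed = 25)
  tr <- cor$truth
  runLens <- rle(strsplit(ref, "")[[1]])
  genomicHp <- sum(runLens$lengths[runLens$lengths >= 5]) / nchar(ref)
  expect_lt(abs(mean(tr$inHp[tr$type == "del"]) - genomicHp), 0.05)
})

test_that("the amplicon panel respects overlap, range and gap constraints", {
  cfg <- SimulationConfig()
  rec <- generatePlastome(cfg, seed = 26)
  amps <- simulateAmpliconPanel(rec, cfg, seed = 27)
  expect_equal(nrow(amps), 16L)
  expect_true(all(amps$length >= 6086 & amps$length <= 12499))
  ov <- amps$end[-16] + 1L - amps$start[-1]
  expect_true(all(ov[-14] >= 173))
  expect_equal(ov[14], -cfg@panelGapLength)
  # coverage: the union of amplicons is the genome minus the declared gap
  L <- nchar(plastomeSequence(rec))
  covered <- rep(FALSE, L)
  for (i in seq_len(16)) covered[amps$start[i]:amps$end[i]] <- TRUE
  expect_equal(sum(!covered), cfg@panelGapLength)
  expect_equal(amps$start[1], 1L)
  expect_equal(amps$end[16], L)
})

test_that("explicit amplicon intervals are honoured exactly", {
  rec <- generatePlastome(smallConfig(), seed = 28)
  iv <- data.frame(start = c(1L, 500L), end = c(600L, 1000L))
  amps <- simulateAmpliconPanel(rec, intervals = iv)
  expect_equal(amps$start, iv$start)
  expect_equal(amps$end, iv$end)
  expect_equal(nchar(amps$sequence), amps$length)
})

test_that("read simulation labels chimeras at the requested rate", {
  cfg <- smallConfig(chimeraRate = 0, readLengthRange = c(300L, 800L))
  rec <- generatePlastome(cfg, seed = 29)
  amps <- simulateAmpliconPanel(rec, smallPanelConfig(), seed = 30)
  rs <- simulateReads(amps, cfg, nReads = 100, seed = 31)
  expect_false(any(rs$truth$palindromic))

  cfg2 <- smallConfig(chimeraRate = 0.2, readLengthRange = c(300L, 800L))
  rs2 <- simulateReads(amps, cfg2, nReads = 1000, seed = 32)
  expect_lt(abs(mean(rs2$truth$palindromic) - 0.2), 0.03)
  # construction bound: read length never exceeds 2x the source amplicon
  maxSrc <- nchar(amps$sequence)[rs2$truth$amplicon]
  expect_true(all(nchar(rs2$reads$sequence) <= 2L * maxSrc))
})

test_that("FASTQ output round-trips sequences with constant quality", {
  cfg <- smallConfig(readLengthRange = c(300L, 500L))
  rec <- generatePlastome(cfg, seed = 33)
  amps <- simulateAmpliconPanel(rec, smallPanelConfig(), seed = 34)
  rs <- simulateReads(amps, cfg, nReads = 5, seed = 35)
  path <- tempfile(fileext = ".fastq")
  writeReadsFastq(rs$reads, path)
  back <- Biostrings::readDNAStringSet(path, format = "fastq")
  expect_equal(unname(as.character(back)), rs$reads$sequence)
  expect_equal(names(back), rs$reads$id)
})

test_that("perfect palindromes split at the exact pivot", {
  set.seed(36)
  arm <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  read <- paste0(arm, revComp(arm))
  out <- splitPalindromicRead(read)
  expect_length(out, 2L)
  expect_equal(out[1], arm)
  expect_equal(out[2], arm)  # second arm returned in genome orientation
})

test_that("non-palindromic reads are returned unchanged", {
  set.seed(37)
  for (i in 1:10) {
    read <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    expect_identical(splitPalindromicRead(read), read)
  }
})

test_that("short fragments are discarded after splitting", {
  set.seed(38)
  arm <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  read <- paste0(arm, revComp(arm))
  expect_length(splitPalindromicRead(read, minArm = 200), 2L)
  # arms shorter than minArm leave the read unsplit
  expect_length(splitPalindromicRead(read, minArm = 500), 1L)
})
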