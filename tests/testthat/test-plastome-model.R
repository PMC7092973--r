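test_that("assemblePlastome builds the quadripartite layout", {
  rec <- assemblePlastome("A", "C", "T")
  expect_equal(plastomeSequence(rec), "ACTG")
  expect_equal(unname(regionWidths(rec)), c(1L, 1L, 1L, 1L))
  r <- regionMap(rec)@ranges
  expect_equal(IRanges::start(r), 1:4)
  expect_equal(IRanges::end(r), 1:4)

  set.seed(5)
  lsc <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  ir <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  ssc <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  rec <- assemblePlastome(lsc, ir, ssc)
  expect_equal(nchar(plastomeSequence(rec)), 300 + 2 * 120 + 80)
  expect_equal(regionSequence(rec, "IRB"), revComp(regionSequence(rec, "IRA")))
  # inverse property: strip recovers the concatenated inputs
  expect_equal(stripIRa(rec), paste0(lsc, ir, ssc))
})

test_that("assemblePlastome rejects non-DNA input, naming the position", {
  expect_error(assemblePlastome("ACXGT", "C", "T"), "position 3")
  expect_error(assemblePlastome("ACGT", "", "T"), "non-empty")
})

test_that("detectInvertedRepeat recovers constructed region maps", {
  cfg <- SimulationConfig(regionLengths = c(lsc = 30000L, ir = 8000L,
                                            ssc = 6000L))
  rec <- generatePlastome(cfg, seed = 42)
  rm <- detectInvertedRepeat(plastomeSequence(rec), minIrLen = 5000)
  expect_equal(regionWidths(rm), regionWidths(rec))

  # round-trips across seeds (property)
  small <- smallConfig()
  for (seed in 1:5) {
    rec <- generatePlastome(small, seed = seed)
    rm <- detectInvertedRepeat(plastomeSequence(rec), minIrLen = 800)
    expect_equal(regionWidths(rm), regionWidths(rec))
  }
})

test_that("detectInvertedRepeat matches a brute-force repeat scan", {
  cfg <- SimulationConfig(regionLengths = c(lsc = 1100L, ir = 300L,
                                            ssc = 300L))
  rec <- generatePlastome(cfg, seed = 9)
  s <- plastomeSequence(rec)
  oracle <- bruteForceLongestIr(s, minLen = 150L)
  rm <- detectInvertedRepeat(s, minIrLen = 150L)
  w <- regionWidths(rm)
  expect_equal(unname(w["IRB"]), oracle$len)
  expect_equal(unname(w["LSC"]) + 1L, oracle$s1)
  expect_equal(oracle$e2, nchar(s))
})

test_that("detectInvertedRepeat errors cleanly on repeat-free input", {
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  expect_error(detectInvertedRepeat(s, minIrLen = 500), "no IR detected")
})

test_that("a palindromic IR does not crash detection", {
  set.seed(77)
  half <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  ir <- paste0(half, revComp(half))     # ir == revcomp(ir)
  lsc <- paste(sample(c("A", "C", "G", "T"), 180, TRUE), collapse = "")
  ssc <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  rec <- assemblePlastome(lsc, ir, ssc)
  res <- tryCatch(detectInvertedRepeat(plastomeSequence(rec), minIrLen = 60),
                  error = function(e) e)
  if (is(res, "RegionMap")) {
    # a flanking base may extend the maximal repeat by chance, so require
    # recovery of the construction up to a few bases
    w <- regionWidths(res)
    expect_gte(unname(w["IRB"]), 120L)
    expect_lte(abs(unname(w["IRB"]) - 120L), 3L)
  } else {
    expect_match(conditionMessage(res), "ambiguous|no IR|rotation")
  }
})

test_that("stripIRa requires a region map and subtracts the IRa length", {
  rec <- assemblePlastome("AAAT", "CG", "TTA")
  expect_equal(nchar(stripIRa(rec)), 4 + 2 + 3)
  bare <- PlastomeRecord("x", "ACGT")
  expect_error(stripIRa(bare), "region map")
})

test_that("normalizeSscOrientation flips only when closer, idempotently", {
  cfg <- smallConfig()
  ref <- generatePlastome(cfg, seed = 3)
  div <- applyDivergence(ref, rate = 0.02, config = cfg, seed = 4)$record
  # flip the diverged SSC in place
  r <- regionRange(div, "SSC")
  s <- plastomeSequence(div)
  flipped <- PlastomeRecord("flip",
                            paste0(substr(s, 1, IRanges::start(r) - 1),
                                   revComp(regionSequence(div, "SSC")),
                                   substr(s, IRanges::end(r) + 1, nchar(s))),
                            regions = regionMap(div))
  norm <- normalizeSscOrientation(flipped, ref)
  expect_equal(regionSequence(norm, "SSC"), regionSequence(div, "SSC"))
  # idempotent; already-matching record unchanged
  expect_equal(plastomeSequence(normalizeSscOrientation(norm, ref)),
               plastomeSequence(norm))
  expect_equal(plastomeSequence(normalizeSscOrientation(div, ref)),
               plastomeSequence(div))
})

test_that("gcFraction follows the N-exclusion rule", {
  expect_equal(gcFraction("GGCC"), 1.0)
  expect_equal(gcFraction("ACGT"), 0.5)
  expect_equal(gcFraction("ACGN"), 2 / 3)  # 2 of 3 called bases are G/C
  expect_equal(gcFraction("AT"), 0)
  expect_true(is.na(gcFraction("")))
  expect_true(is.na(gcFraction("NNN")))
})

test_that("reverse complement is an involution", {
  set.seed(11)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(1:200, 1), TRUE),
               collapse = "")
    expect_equal(revComp(revComp(s)), s)
  }
})

test_that("region maps serialize to BED and back", {
  rec <- assemblePlastome(strrep("A", 40), strrep("C", 10), strrep("T", 20))
  path <- tempfile(fileext = ".bed")
  writeRegionMapBed(rec, path)
  rm2 <- readRegionMapBed(path)
  expect_equal(regionWidths(rm2), regionWidths(rec))
})

test_that("FASTA round trip preserves id and sequence", {
  rec <- assemblePlastome("AAAT", "CG", "TTA", id = "toy")
  path <- tempfile(fileext = ".fasta")
  writePlastomeFasta(rec, path)
  back <- readPlastomeFasta(path)
  expect_length(back, 1L)
  expect_equal(seqId(back[[1]]), "toy")
  expect_equal(plastomeSequence(back[[1]]), plastomeSequence(rec))
})
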