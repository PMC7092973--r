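test_that("variantsFromAlignment emits one record per event", {
  expect_length(variantsFromAlignment(AlignedPair("ACGT", "ACGT")), 0L)
  # one 2-bp deletion -> a single variant at the first deleted base
  v <- variantsFromAlignment(AlignedPair("ACGTAAAAATGC", "ACGTAAA--TGC"))
  expect_equal(v, 8L)
  # substitution + insertion; N columns are silent
  v <- variantsFromAlignment(AlignedPair("AC-GTN", "ATTGTA"))
  expect_equal(v, c(2L, 2L))
})

test_that("alignment variants track planted positions within event length", {
  cfg <- smallConfig()
  rec <- generatePlastome(cfg, seed = 71)
  div <- applyDivergence(rec, rate = 0.01, config = cfg, seed = 72)
  aln <- adjustToReference(alignPair(stripIRa(rec), stripIRa(div$record)))
  v <- variantsFromAlignment(aln)
  tr <- div$truth
  expect_equal(length(v), nrow(tr))
  # every recovered position lies within the placement-ambiguity window of
  # its planted event
  d <- abs(sort(v) - sort(tr$pos))
  expect_true(all(d <= max(tr$length) + 1L))
})

test_that("VCF variant tables honour FILTER and contig checks", {
  vcf <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chl,length=2000>",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", sep = "\t"),
           "chl\t10\t.\tA\tT\t50\tPASS\t.",
           "chl\t20\t.\tC\tCA\t50\t.\t.",
           "chl\t30\t.\tG\tA,T\t50\tPASS\t.")
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_equal(loadVariantsFromVcf(path), c(10L, 20L, 30L))

  writeLines(c(vcf[1:3], "chl\t10\t.\tA\tT\t50\tlowqual\t."), path)
  expect_length(loadVariantsFromVcf(path), 0L)

  writeLines(c(vcf[1:4], "chl2\t11\t.\tA\tT\t50\tPASS\t."), path)
  expect_error(loadVariantsFromVcf(path), "multiple contigs")
})

test_that("truth VCFs round-trip through the VCF loader", {
  cfg <- smallConfig()
  rec <- generatePlastome(cfg, seed = 73)
  div <- applyDivergence(rec, rate = 0.015, config = cfg, seed = 74)
  path <- tempfile(fileext = ".vcf")
  writeTruthVcf(div$truth, stripIRa(rec), path)
  v <- loadVariantsFromVcf(path)
  expect_equal(length(v), nrow(div$truth))
})

test_that("windowCounts tiles without overlap and conserves counts", {
  wc <- windowCounts(c(1L, 1000L, 1001L), refLen = 2000)
  expect_equal(wc$count, c(2L, 1L))
  expect_equal(wc$start, c(1L, 1001L))
  expect_equal(wc$end, c(1000L, 2000L))

  wc <- windowCounts(integer(0), refLen = 3500)
  expect_equal(wc$count, rep(0L, 4))
  expect_equal(wc$end[4], 3500L)  # truncated final window kept

  set.seed(2)
  pos <- sort(sample.int(47000, 500))
  wc <- windowCounts(pos, refLen = 47000)
  expect_equal(sum(wc$count), 500L)
  expect_error(windowCounts(c(10L, 99L), refLen = 50), "outside")
})

test_that("flagging uses a strict threshold and is monotone", {
  d <- data.frame(start = c(1L, 1001L, 2001L), end = c(1000L, 2000L, 3000L),
                  count = c(8L, 9L, 3L))
  f <- flagHighVariabilityWindows(d, 8)
  expect_equal(f$start, 1001L)
  expect_equal(nrow(flagHighVariabilityWindows(d, 0)), 3L)
  for (th in 0:10)
    expect_lte(nrow(flagHighVariabilityWindows(d, th + 1L)),
               nrow(flagHighVariabilityWindows(d, th)))
  empty <- data.frame(start = 1L, end = 1000L, count = 0L)
  expect_equal(nrow(flagHighVariabilityWindows(empty)), 0L)
})

test_that("summarizeMarker computes variability and hotspots", {
  set.seed(3)
  pos <- sort(sample(1000:1868, 12))
  m <- summarizeMarker(pos, 1000, 1868, "toy")
  expect_equal(m$length, 869L)
  expect_equal(m$variants, 12L)
  expect_equal(m$variabilityPct, 1.38)

  m <- summarizeMarker(integer(0), 1, 500, "empty")
  expect_equal(m$variabilityPct, 0)

  m <- summarizeMarker(c(10L, 40L, 90L, 400L), 1, 500, "hs",
                       hotspotWindow = c(30, 100))
  expect_equal(c(m$hotspotStart, m$hotspotEnd), c(40L, 90L))
  expect_error(summarizeMarker(1L, 10, 5, "bad"), "empty")
})

test_that("planted dense windows are exactly the flagged ones", {
  cfg <- smallConfig()
  rec <- generatePlastome(cfg, seed = 75)
  refLen <- nchar(stripIRa(rec))
  set.seed(76)
  # background below threshold plus six planted dense windows
  dense <- sort(sample.int(refLen %/% 1000 - 1L, 6))
  pos <- sort(c(sample.int(refLen, 30),
                unlist(lapply(dense, function(w)
                  (w - 1L) * 1000L + sample.int(1000L, 12)))))
  pos <- unique(pos)
  wc <- windowCounts(pos, refLen)
  fl <- flagHighVariabilityWindows(wc, 8)
  expect_true(all((dense - 1L) * 1000L + 1L %in% fl$start))
  expect_lte(nrow(fl), length(dense) + 1L)  # background stays sparse
})
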