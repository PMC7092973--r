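#' @include utils.R
NULL

# ---------------------------------------------------------------- RegionMap

#' Quadripartite region map
#'
#' An S4 class holding the four plastome regions -- large single-copy (LSC),
#' first inverted repeat (IRb), small single-copy (SSC) and second inverted
#' repeat (IRa) -- as a named, contiguous [IRanges::IRanges] partition of the
#' genome (1-based, closed intervals).  Validity enforces the canonical order
#' LSC, IRB, SSC, IRA with no gaps or overlaps, a first interval starting at
#' position 1, and equal widths for the two repeat copies.
#'
#' @slot ranges An `IRanges` of length 4 named `LSC`, `IRB`, `SSC`, `IRA`.
#' @seealso [RegionMap()], [regionWidths()], [regionRange()]
#' @export
setClass("RegionMap", representation(ranges = "IRanges"))

setValidity("RegionMap", function(object) {
  r <- object@ranges
  if (length(r) != 4L)
    return("region map must contain exactly 4 intervals")
  if (!identical(names(r), c("LSC", "IRB", "SSC", "IRA")))
    return("intervals must be named LSC, IRB, SSC, IRA in that order")
  if (start(r)[1L] != 1L)
    return("LSC must start at position 1")
  if (any(width(r) < 1L))
    return("all regions must be non-empty")
  if (any(start(r)[-1L] != end(r)[-4L] + 1L))
    return("regions must be contiguous with no gaps or overlaps")
  if (width(r)[2L] != width(r)[4L])
    return("IRb and IRa must have equal length")
  TRUE
})

#' Construct a region map from region lengths or ranges
#'
#' @param lsc,ir,ssc Region lengths in bp (the IR length is shared by both
#'   copies), or alternatively pass a ready-made `IRanges` via `ranges`.
#' @param ranges Optional `IRanges` of length 4 (overrides the lengths).
#' @return A [RegionMap-class] object.
#' @examples
#' RegionMap(82675, 24558, 18400)
#' @export
RegionMap <- function(lsc, ir, ssc, ranges = NULL) {
  if (is.null(ranges)) {
    w <- as.integer(c(lsc, ir, ssc, ir))
    ranges <- IRanges(start = cumsum(c(1L, w[-4L])), width = w,
                      names = c("LSC", "IRB", "SSC", "IRA"))
  }
  new("RegionMap", ranges = ranges)
}

# ------------------------------------------------------------ PlastomeRecord

setClassUnion("RegionMapOrNULL", c("RegionMap", "NULL"))

#' A plastome sequence with optional quadripartite annotation
#'
#' Couples a DNA sequence (a [Biostrings::DNAString]) with an identifier and,
#' once constructed or detected, a [RegionMap-class].  Validity checks that
#' the region map tiles the sequence exactly and that the IRb subsequence is
#' the reverse complement of the IRa subsequence -- the defining property of
#' the plastome inverted repeat.
#'
#' @slot id Character identifier.
#' @slot sequence A `DNAString` over `A,C,G,T,N`.
#' @slot regions A [RegionMap-class] or `NULL` when not yet known.
#' @seealso [PlastomeRecord()], [assemblePlastome()], [detectInvertedRepeat()]
#' @export
setClass("PlastomeRecord",
         representation(id = "character", sequence = "DNAString",
                        regions = "RegionMapOrNULL"))

setValidity("PlastomeRecord", function(object) {
  if (length(object@id) != 1L || is.na(object@id))
    return("id must be a single non-NA string")
  s <- as.character(object@sequence)
  if (grepl("[^ACGTN]", s))
    return("sequence must contain only A, C, G, T, N")
  rm <- object@regions
  if (!is.null(rm)) {
    r <- rm@ranges
    if (sum(width(r)) != nchar(s))
      return("region widths must sum to the sequence length")
    irb <- substr(s, start(r)[2L], end(r)[2L])
    ira <- substr(s, start(r)[4L], end(r)[4L])
    if (!identical(irb, revComp(ira)))
      return("IRb subsequence must equal the reverse complement of IRa")
  }
  TRUE
})

#' Construct a plastome record
#'
#' @param id Sequence identifier.
#' @param sequence DNA sequence (character string or `DNAString`).
#' @param regions Optional [RegionMap-class].
#' @return A [PlastomeRecord-class].
#' @export
PlastomeRecord <- function(id, sequence, regions = NULL) {
  if (is.character(sequence)) {
    checkDna(sequence, "sequence")
    sequence <- DNAString(sequence)
  }
  new("PlastomeRecord", id = id, sequence = sequence, regions = regions)
}

# --------------------------------------------------------------- AlignedPair

#' A gapped pairwise alignment (reference on top)
#'
#' Two equal-length gapped rows over `{A,C,G,T,N,-}`; no column may carry a
#' gap in both rows.  Removing gaps from the reference row reproduces the
#' reference sequence, so reference coordinates are recoverable from column
#' indices.
#'
#' @slot refAligned Gapped reference row.
#' @slot qryAligned Gapped query row.
#' @seealso [AlignedPair()], [alignPair()], [classifyAlignment()]
#' @export
setClass("AlignedPair",
         representation(refAligned = "character", qryAligned = "character"))

setValidity("AlignedPair", function(object) {
  r <- object@refAligned
  q <- object@qryAligned
  if (length(r) != 1L || length(q) != 1L)
    return("aligned rows must be single strings")
  if (nchar(r) != nchar(q))
    return("aligned rows must have equal length")
  if (grepl("[^ACGTN-]", r) || grepl("[^ACGTN-]", q))
    return("aligned rows must contain only A, C, G, T, N, -")
  rb <- charToRaw(r)
  qb <- charToRaw(q)
  dash <- charToRaw("-")
  if (any(rb == dash & qb == dash))
    return("no column may have a gap in both rows")
  TRUE
})

#' Construct an aligned pair
#'
#' @param refAligned,qryAligned Equal-length gapped rows (reference, query).
#' @return An [AlignedPair-class].
#' @export
AlignedPair <- function(refAligned, qryAligned) {
  new("AlignedPair", refAligned = toupper(refAligned),
      qryAligned = toupper(qryAligned))
}

# ------------------------------------------------------------ MismatchProfile

#' Mismatch taxonomy of an adjusted pairwise alignment
#'
#' Per-comparison counts in the layout of an assembly-concordance table:
#' substitutions, deleted bases ("gaps") and deletion events, inserted bases
#' and insertion events, query-N positions, and the alignment length.  Total
#' mismatches are derived as substitutions + deleted + inserted bases; N
#' positions are tracked separately and excluded from mismatches.
#'
#' @slot alignmentLength Number of alignment columns.
#' @slot substitutions Substituted positions (query base differs, not N).
#' @slot deletedBases Reference bases absent from the query.
#' @slot deletionEvents Maximal runs of consecutive deletion columns.
#' @slot insertedBases Query bases absent from the reference.
#' @slot insertionEvents Maximal runs of consecutive insertion columns.
#' @slot nPositions Columns with a reference base under a query N.
#' @seealso [MismatchProfile()], [classifyAlignment()], [identityPercent()]
#' @export
setClass("MismatchProfile",
         representation(alignmentLength = "integer",
                        substitutions = "integer",
                        deletedBases = "integer",
                        deletionEvents = "integer",
                        insertedBases = "integer",
                        insertionEvents = "integer",
                        nPositions = "integer"))

setValidity("MismatchProfile", function(object) {
  v <- c(object@alignmentLength, object@substitutions, object@deletedBases,
         object@deletionEvents, object@insertedBases, object@insertionEvents,
         object@nPositions)
  if (length(v) != 7L || anyNA(v) || any(v < 0L))
    return("all counts must be single non-negative integers")
  if (object@deletionEvents > object@deletedBases)
    return("deletion events cannot exceed deleted bases")
  if (object@insertionEvents > object@insertedBases)
    return("insertion events cannot exceed inserted bases")
  TRUE
})

#' Construct a mismatch profile from raw counts
#'
#' Used for fixture-style input when only published counts (not alignments)
#' are available.  `alignmentLength` defaults to `refLength + insertedBases`,
#' the length convention of a reference-adjusted alignment.
#'
#' @param substitutions,deletedBases,insertedBases Mismatch base counts.
#' @param refLength Reference length in bp (without the second IR copy).
#' @param nPositions Query-N positions (default 0).
#' @param deletionEvents,insertionEvents Event counts; default to the base
#'   counts' minimal consistent values when unknown (one base per event is
#'   not assumed; unknown events are set to 0/clamped to the base count only
#'   for validity, they carry no meaning in fixture mode).
#' @param alignmentLength Override the default length convention.
#' @return A [MismatchProfile-class].
#' @examples
#' p <- MismatchProfile(substitutions = 67, deletedBases = 253,
#'                      insertedBases = 42, refLength = 125633,
#'                      nPositions = 152)
#' mismatchCount(p)
#' identityPercent(p)
#' @export
MismatchProfile <- function(substitutions, deletedBases, insertedBases,
                            refLength = NULL, nPositions = 0L,
                            deletionEvents = NULL, insertionEvents = NULL,
                            alignmentLength = NULL) {
  if (is.null(alignmentLength)) {
    if (is.null(refLength))
      stop("either refLength or alignmentLength must be given")
    alignmentLength <- refLength + insertedBases
  }
  if (is.null(deletionEvents))
    deletionEvents <- as.integer(min(deletedBases, deletedBases > 0))
  if (is.null(insertionEvents))
    insertionEvents <- as.integer(min(insertedBases, insertedBases > 0))
  new("MismatchProfile",
      alignmentLength = as.integer(alignmentLength),
      substitutions = as.integer(substitutions),
      deletedBases = as.integer(deletedBases),
      deletionEvents = as.integer(deletionEvents),
      insertedBases = as.integer(insertedBases),
      insertionEvents = as.integer(insertionEvents),
      nPositions = as.integer(nPositions))
}

# -------------------------------------------------------- ErrorContextSummary

#' Homopolymer attribution of indel events
#'
#' Counts of deletion/insertion events attributable to homopolymer context
#' (runs of at least `minHpLen` identical bases on the reference).
#'
#' @slot deletionEvents,insertionEvents Event totals from the alignment.
#' @slot deletionEventsInHp,insertionEventsInHp Events attributed to
#'   homopolymer runs.
#' @slot minHpLen Minimum run length defining a homopolymer (bp).
#' @seealso [attributeIndelEvents()], [deletionHpFraction()]
#' @export
setClass("ErrorContextSummary",
         representation(deletionEvents = "integer",
                        deletionEventsInHp = "integer",
                        insertionEvents = "integer",
                        insertionEventsInHp = "integer",
                        minHpLen = "integer"))

setValidity("ErrorContextSummary", function(object) {
  if (object@deletionEventsInHp > object@deletionEvents)
    return("in-homopolymer deletion events cannot exceed total")
  if (object@insertionEventsInHp > object@insertionEvents)
    return("in-homopolymer insertion events cannot exceed total")
  if (object@minHpLen < 2L)
    return("minHpLen must be at least 2")
  TRUE
})

# ----------------------------------------------------------- SimulationConfig

#' Configuration for the synthetic plastome generator
#'
#' Bundles every tunable of the simulator: genome shape, target base
#' composition, divergence process, consensus error model, amplicon panel
#' geometry and read/chimera model.  Defaults emulate a ~150 kb angiosperm
#' plastome at 37.45% G+C with 0.83% inter-species divergence and a
#' deletion-dominated, homopolymer-concentrated long-read consensus error
#' profile.
#'
#' @slot regionLengths Named integer vector `lsc`, `ir`, `ssc` (bp).
#' @slot gcTarget Target G+C fraction of the random genome.
#' @slot divergenceRate Expected mismatched bases per reference bp between
#'   the genome and a simulated relative.
#' @slot divergenceMix Fractions of mismatched bases that are substitutions,
#'   deleted bases, inserted bases (sums to 1).
#' @slot errorRate Expected mismatched bases per reference bp introduced by
#'   consensus corruption.
#' @slot errorMix Substitution/deletion/insertion base shares of the error
#'   process (sums to 1).
#' @slot hpBias Per-extra-homopolymer-base multiplier on the deletion weight;
#'   `NA` requests automatic calibration so that the expected fraction of
#'   deletion events inside homopolymer runs of `>= 5` bp equals
#'   `hpTargetFraction`.
#' @slot hpTargetFraction Target in-homopolymer deletion-event fraction used
#'   when `hpBias` is `NA`.
#' @slot indelMeanLen Mean of the truncated-geometric indel length law.
#' @slot maxIndelLen Truncation point of indel lengths (bp).
#' @slot ampliconCount Number of long-range-PCR fragments.
#' @slot ampliconLengthRange Allowed fragment lengths (bp).
#' @slot minOverlap Minimum overlap between consecutive fragments (bp).
#' @slot panelGapAfter Fragment index after which the panel has its one
#'   declared sequence gap.
#' @slot panelGapLength Length of that gap (bp).
#' @slot chimeraRate Fraction of simulated reads that are palindromic
#'   chimeras.
#' @slot readLengthRange Simulated read lengths (bp, before chimera
#'   doubling).
#' @slot readErrorRates Named per-base read error rates `sub`, `del`, `ins`.
#' @seealso [SimulationConfig()], [generatePlastome()]
#' @export
setClass("SimulationConfig",
         representation(regionLengths = "integer",
                        gcTarget = "numeric",
                        divergenceRate = "numeric",
                        divergenceMix = "numeric",
                        errorRate = "numeric",
                        errorMix = "numeric",
                        hpBias = "numeric",
                        hpTargetFraction = "numeric",
                        indelMeanLen = "numeric",
                        maxIndelLen = "integer",
                        ampliconCount = "integer",
                        ampliconLengthRange = "integer",
                        minOverlap = "integer",
                        panelGapAfter = "integer",
                        panelGapLength = "integer",
                        chimeraRate = "numeric",
                        readLengthRange = "integer",
                        readErrorRates = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (!identical(names(object@regionLengths), c("lsc", "ir", "ssc")) ||
      any(object@regionLengths < 1L))
    return("regionLengths must be positive and named lsc, ir, ssc")
  for (mx in list(object@divergenceMix, object@errorMix)) {
    if (length(mx) != 3L || any(mx < 0))
      return("mixes must be three non-negative fractions")
    if (abs(sum(mx) - 1) > 1e-9)
      return("mixes must sum to 1 (tolerance 1e-9)")
  }
  if (object@divergenceRate < 0 || object@errorRate < 0)
    return("rates must be non-negative")
  if (object@chimeraRate < 0 || object@chimeraRate > 1)
    return("chimeraRate must lie in [0, 1]")
  if (object@gcTarget < 0 || object@gcTarget > 1)
    return("gcTarget must lie in [0, 1]")
  if (object@indelMeanLen < 1 || object@maxIndelLen < 1L)
    return("indel length model must allow lengths >= 1")
  TRUE
})

#' Build a simulation configuration
#'
#' All parameters have study-condition defaults; see
#' [SimulationConfig-class] for their meaning.
#'
#' @param regionLengths,gcTarget,divergenceRate,divergenceMix,errorRate,errorMix
#'   Genome and mutation-process parameters.
#' @param hpBias,hpTargetFraction,indelMeanLen,maxIndelLen Error-context and
#'   indel-length parameters.
#' @param ampliconCount,ampliconLengthRange,minOverlap,panelGapAfter,panelGapLength
#'   Amplicon panel geometry.
#' @param chimeraRate,readLengthRange,readErrorRates Read model.
#' @return A validated [SimulationConfig-class].
#' @examples
#' cfg <- SimulationConfig()
#' cfg
#' @export
SimulationConfig <- function(regionLengths = c(lsc = 82675L, ir = 24558L,
                                               ssc = 18400L),
                             gcTarget = 0.3745,
                             divergenceRate = 0.0083,
                             divergenceMix = c(0.288, 0.377, 0.335),
                             errorRate = 0.00288,
                             errorMix = c(0.185, 0.699, 0.116),
                             hpBias = NA_real_,
                             hpTargetFraction = 0.80,
                             indelMeanLen = 1.3,
                             maxIndelLen = 5L,
                             ampliconCount = 16L,
                             ampliconLengthRange = c(6086L, 12499L),
                             minOverlap = 173L,
                             panelGapAfter = 14L,
                             panelGapLength = 100L,
                             chimeraRate = 0,
                             readLengthRange = c(500L, 3000L),
                             readErrorRates = c(sub = 0.025, del = 0.04,
                                                ins = 0.015)) {
  rl <- as.integer(regionLengths)
  names(rl) <- names(regionLengths)
  new("SimulationConfig",
      regionLengths = rl, gcTarget = gcTarget,
      divergenceRate = divergenceRate, divergenceMix = divergenceMix,
      errorRate = errorRate, errorMix = errorMix,
      hpBias = hpBias, hpTargetFraction = hpTargetFraction,
      indelMeanLen = indelMeanLen, maxIndelLen = as.integer(maxIndelLen),
      ampliconCount = as.integer(ampliconCount),
      ampliconLengthRange = as.integer(ampliconLengthRange),
      minOverlap = as.integer(minOverlap),
      panelGapAfter = as.integer(panelGapAfter),
      panelGapLength = as.integer(panelGapLength),
      chimeraRate = chimeraRate,
      readLengthRange = as.integer(readLengthRange),
      readErrorRates = readErrorRates)
}
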