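#' @include AllClasses.R accessors.R alignment.R
NULL

#' Classify alignment columns into the mismatch taxonomy
#'
#' Scans a reference-adjusted alignment column by column: a reference base
#' against a different query base (query not N) is a substitution; a
#' reference base over a query N is an N position (tracked separately, not a
#' mismatch); a reference base over a query gap is a deleted base; a
#' reference gap under a query base is an inserted base.  Deletion and
#' insertion *events* are maximal runs of consecutive deletion
#' (resp. insertion) columns; a run is broken by any column of another kind.
#' Total mismatches are substitutions + deleted bases + inserted bases.
#'
#' @param aln An [AlignedPair-class], already passed through
#'   [adjustToReference()].
#' @return A [MismatchProfile-class].
#' @examples
#' classifyAlignment(AlignedPair("ACGTAAAAATGC", "ACGTAAA--TGC"))
#' @export
classifyAlignment <- function(aln) {
  stopifnot(is(aln, "AlignedPair"))
  r <- s2c(aln@refAligned)
  q <- s2c(aln@qryAligned)
  refGap <- r == "-"
  qryGap <- q == "-"
  if (any(refGap & qryGap))
    stop("invalid alignment: column with gap in both rows", call. = FALSE)
  isDel <- !refGap & qryGap
  isIns <- refGap & !qryGap
  isN <- !refGap & !qryGap & q == "N"
  isSub <- !refGap & !qryGap & !isN & r != "N" & r != q
  delRle <- rle(isDel)
  insRle <- rle(isIns)
  new("MismatchProfile",
      alignmentLength = length(r),
      substitutions = sum(isSub),
      deletedBases = sum(isDel),
      deletionEvents = sum(delRle$values),
      insertedBases = sum(isIns),
      insertionEvents = sum(insRle$values),
      nPositions = sum(isN))
}

#' Alignment-referenced identity percentage
#'
#' `100 * (1 - (mismatches + nPositions) / alignmentLength)`, where the
#' alignment length of a reference-adjusted alignment equals the reference
#' length plus the inserted bases.  N positions count against identity even
#' though they are not mismatches -- they are reference positions the query
#' failed to cover.  Rounded half away from zero to two decimals.
#'
#' @param x A [MismatchProfile-class].
#' @param digits Decimals to round to (default 2, matching report tables).
#' @return A percentage in `[0, 100]`, or `NA` for an empty alignment.
#' @examples
#' identityPercent(MismatchProfile(67, 253, 42, refLength = 125633,
#'                                 nPositions = 152))
#' @export
setGeneric("identityPercent",
           function(x, digits = 2L) standardGeneric("identityPercent"))

#' @rdname identityPercent
#' @export
setMethod("identityPercent", "MismatchProfile", function(x, digits = 2L) {
  if (x@alignmentLength == 0L) return(NA_real_)
  roundHalfUp(100 * (1 - (mismatchCount(x) + x@nPositions) /
                       x@alignmentLength), digits)
})

#' Mismatch composition shares
#'
#' Percentages of total mismatches that are substitutions, deleted bases
#' ("gaps"), and inserted bases, plus the combined indel share, rounded half
#' away from zero to one decimal (report-table formatting).
#'
#' @param profile A [MismatchProfile-class].
#' @return Named numeric vector `substitutions`, `gaps`, `insertions`,
#'   `indels` (percent); all `NA` when there are no mismatches.
#' @examples
#' mismatchShares(MismatchProfile(67, 253, 42, refLength = 125633))
#' @export
mismatchShares <- function(profile) {
  stopifnot(is(profile, "MismatchProfile"))
  m <- mismatchCount(profile)
  if (m == 0L)
    return(c(substitutions = NA_real_, gaps = NA_real_,
             insertions = NA_real_, indels = NA_real_))
  c(substitutions = roundHalfUp(100 * profile@substitutions / m, 1L),
    gaps = roundHalfUp(100 * profile@deletedBases / m, 1L),
    insertions = roundHalfUp(100 * profile@insertedBases / m, 1L),
    indels = roundHalfUp(
      100 * (profile@deletedBases + profile@insertedBases) / m, 1L))
}

# One row of numbers from a profile, used by report assembly.
profileRow <- function(p) {
  data.frame(alignmentLength = p@alignmentLength,
             identityPct = identityPercent(p),
             nPositions = p@nPositions,
             nPositionsPct = roundHalfUp(
               100 * p@nPositions / p@alignmentLength, 2L),
             mismatches = mismatchCount(p),
             substitutions = p@substitutions,
             deletedBases = p@deletedBases,
             deletionEvents = p@deletionEvents,
             insertedBases = p@insertedBases,
             insertionEvents = p@insertionEvents)
}
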