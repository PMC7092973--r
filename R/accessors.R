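#' @include AllClasses.R
NULL

# ----------------------------------------------------------------- generics

#' Accessors for plastomeConcord classes
#'
#' @param x An object of the class named in the accessor's description.
#' @param region One of `"LSC"`, `"IRB"`, `"SSC"`, `"IRA"`.
#' @name accessors
NULL

#' @describeIn accessors Sequence identifier of a [PlastomeRecord-class].
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' @describeIn accessors Sequence of a [PlastomeRecord-class] as a character
#'   string.
#' @export
setGeneric("plastomeSequence",
           function(x) standardGeneric("plastomeSequence"))

#' @describeIn accessors Region map of a [PlastomeRecord-class] (or `NULL`).
#' @export
setGeneric("regionMap", function(x) standardGeneric("regionMap"))

#' @describeIn accessors Named widths of the four regions.
#' @export
setGeneric("regionWidths", function(x) standardGeneric("regionWidths"))

#' @describeIn accessors `IRanges` interval of one region.
#' @export
setGeneric("regionRange", function(x, region) standardGeneric("regionRange"))

#' @describeIn accessors Subsequence of one region of a
#'   [PlastomeRecord-class], as a character string.
#' @export
setGeneric("regionSequence",
           function(x, region) standardGeneric("regionSequence"))

#' @describeIn accessors Gapped reference row of an [AlignedPair-class].
#' @export
setGeneric("refAligned", function(x) standardGeneric("refAligned"))

#' @describeIn accessors Gapped query row of an [AlignedPair-class].
#' @export
setGeneric("qryAligned", function(x) standardGeneric("qryAligned"))

#' @describeIn accessors Total mismatches of a [MismatchProfile-class]
#'   (substitutions + deleted + inserted bases; N positions excluded).
#' @export
setGeneric("mismatchCount", function(x) standardGeneric("mismatchCount"))

#' @describeIn accessors Fraction of deletion events in homopolymer context
#'   from an [ErrorContextSummary-class] (`NaN` when no events).
#' @export
setGeneric("deletionHpFraction",
           function(x) standardGeneric("deletionHpFraction"))

#' @describeIn accessors Fraction of insertion events in homopolymer context
#'   (`NaN` when no events).
#' @export
setGeneric("insertionHpFraction",
           function(x) standardGeneric("insertionHpFraction"))

# ------------------------------------------------------------------ methods

#' @rdname accessors
#' @export
setMethod("seqId", "PlastomeRecord", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("plastomeSequence", "PlastomeRecord",
          function(x) as.character(x@sequence))

#' @rdname accessors
#' @export
setMethod("regionMap", "PlastomeRecord", function(x) x@regions)

#' @rdname accessors
#' @export
setMethod("regionWidths", "RegionMap",
          function(x) setNames(width(x@ranges), names(x@ranges)))

#' @rdname accessors
#' @export
setMethod("regionWidths", "PlastomeRecord", function(x) {
  if (is.null(x@regions)) stop("record has no region map")
  regionWidths(x@regions)
})

#' @rdname accessors
#' @export
setMethod("regionRange", "RegionMap", function(x, region) {
  region <- match.arg(region, c("LSC", "IRB", "SSC", "IRA"))
  x@ranges[region]
})

#' @rdname accessors
#' @export
setMethod("regionRange", "PlastomeRecord", function(x, region) {
  if (is.null(x@regions)) stop("record has no region map")
  regionRange(x@regions, region)
})

#' @rdname accessors
#' @export
setMethod("regionSequence", "PlastomeRecord", function(x, region) {
  r <- regionRange(x, region)
  substr(as.character(x@sequence), start(r), end(r))
})

#' @rdname accessors
#' @export
setMethod("refAligned", "AlignedPair", function(x) x@refAligned)

#' @rdname accessors
#' @export
setMethod("qryAligned", "AlignedPair", function(x) x@qryAligned)

#' @rdname accessors
#' @export
setMethod("mismatchCount", "MismatchProfile",
          function(x) x@substitutions + x@deletedBases + x@insertedBases)

#' @rdname accessors
#' @export
setMethod("deletionHpFraction", "ErrorContextSummary",
          function(x) x@deletionEventsInHp / x@deletionEvents)

#' @rdname accessors
#' @export
setMethod("insertionHpFraction", "ErrorContextSummary",
          function(x) x@insertionEventsInHp / x@insertionEvents)

# --------------------------------------------------------------------- show

setMethod("show", "RegionMap", function(object) {
  w <- regionWidths(object)
  cat("RegionMap:", paste(sprintf("%s=%d", names(w), w), collapse = " "),
      sprintf("(total %d bp)\n", sum(w)))
})

setMethod("show", "PlastomeRecord", function(object) {
  s <- as.character(object@sequence)
  cat(sprintf("PlastomeRecord '%s': %d bp", object@id, nchar(s)))
  gc <- gcFraction(s)
  if (!is.na(gc)) cat(sprintf(", G+C %.2f%%", 100 * gc))
  cat("\n")
  if (!is.null(object@regions)) show(object@regions)
  else cat("  (no region map)\n")
})

setMethod("show", "AlignedPair", function(object) {
  n <- nchar(object@refAligned)
  cat(sprintf("AlignedPair: %d columns\n", n))
  k <- min(n, 60L)
  cat("  ref: ", substr(object@refAligned, 1L, k),
      if (n > k) "..." else "", "\n", sep = "")
  cat("  qry: ", substr(object@qryAligned, 1L, k),
      if (n > k) "..." else "", "\n", sep = "")
})

setMethod("show", "MismatchProfile", function(object) {
  cat("MismatchProfile\n")
  cat(sprintf("  alignment length : %d\n", object@alignmentLength))
  cat(sprintf("  substitutions    : %d\n", object@substitutions))
  cat(sprintf("  deleted bases    : %d (%d events)\n",
              object@deletedBases, object@deletionEvents))
  cat(sprintf("  inserted bases   : %d (%d events)\n",
              object@insertedBases, object@insertionEvents))
  cat(sprintf("  N positions      : %d\n", object@nPositions))
  cat(sprintf("  total mismatches : %d\n", mismatchCount(object)))
  cat(sprintf("  identity         : %.2f%%\n", identityPercent(object)))
})

setMethod("show", "ErrorContextSummary", function(object) {
  cat(sprintf("ErrorContextSummary (homopolymer >= %d bp)\n",
              object@minHpLen))
  cat(sprintf("  deletion events : %d, in homopolymer %d (%.1f%%)\n",
              object@deletionEvents, object@deletionEventsInHp,
              100 * deletionHpFraction(object)))
  cat(sprintf("  insertion events: %d, in homopolymer %d (%.1f%%)\n",
              object@insertionEvents, object@insertionEventsInHp,
              100 * insertionHpFraction(object)))
})

setMethod("show", "SimulationConfig", function(object) {
  rl <- object@regionLengths
  cat("SimulationConfig\n")
  cat(sprintf("  genome: LSC %d + IR %d x2 + SSC %d = %d bp, G+C %.2f%%\n",
              rl["lsc"], rl["ir"], rl["ssc"], sum(rl) + rl["ir"],
              100 * object@gcTarget))
  cat(sprintf("  divergence: %.4f /bp, mix %.3f/%.3f/%.3f\n",
              object@divergenceRate, object@divergenceMix[1L],
              object@divergenceMix[2L], object@divergenceMix[3L]))
  cat(sprintf("  error model: %.5f /bp, mix %.3f/%.3f/%.3f, hpBias %s\n",
              object@errorRate, object@errorMix[1L], object@errorMix[2L],
              object@errorMix[3L],
              if (is.na(object@hpBias))
                sprintf("auto (target %.2f)", object@hpTargetFraction)
              else sprintf("%.2f", object@hpBias)))
  cat(sprintf("  panel: %d amplicons %d-%d bp, overlap >= %d, gap after %d\n",
              object@ampliconCount, object@ampliconLengthRange[1L],
              object@ampliconLengthRange[2L], object@minOverlap,
              object@panelGapAfter))
})
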