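#' @include AllClasses.R accessors.R classify.R
NULL

#' Locate homopolymer runs in a sequence
#'
#' All maximal runs of a single repeated base (A, C, G or T; N never forms a
#' run) of at least `minLen` bp, in coordinate order.
#'
#' @param sequence DNA character string.
#' @param minLen Minimum run length in bp (default 5, `>= 2`).
#' @return A data frame with columns `start`, `end` (1-based, closed),
#'   `base`, `length`; zero rows when no run qualifies.
#' @examples
#' findHomopolymerRuns("AAAAACCCCCG")
#' @export
findHomopolymerRuns <- function(sequence, minLen = 5L) {
  checkDna(sequence, "sequence", allowEmpty = TRUE)
  if (minLen < 2L) stop("minLen must be >= 2", call. = FALSE)
  empty <- data.frame(start = integer(), end = integer(),
                      base = character(), length = integer())
  if (nchar(sequence) == 0L) return(empty)
  rl <- rle(s2c(sequence))
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$lengths >= minLen & rl$values != "N"
  if (!any(keep)) return(empty)
  data.frame(start = starts[keep], end = ends[keep],
             base = rl$values[keep], length = rl$lengths[keep])
}

#' Attribute indel events to homopolymer context
#'
#' For a reference-adjusted alignment, decides for every deletion and
#' insertion event whether it lies in homopolymer context.  A deletion event
#' is "in homopolymer" iff its deleted reference interval overlaps a
#' reference homopolymer run of at least `minLen` bp, *or* all deleted bases
#' equal the base of a run immediately adjacent to the deletion site (an
#' aligner may place a one-base deletion from a run at either run edge, so a
#' pure-overlap rule would under-count edge placements).  An insertion event
#' is "in homopolymer" iff all inserted bases are identical *and* equal the
#' base of a reference run overlapping or immediately adjacent to the
#' insertion point; mixed-base insertions are never attributed.
#'
#' @param aln An [AlignedPair-class] adjusted to the reference (no terminal
#'   reference gaps).
#' @param minLen Minimum homopolymer run length in bp (default 5).
#' @return An [ErrorContextSummary-class]; its event totals equal those of
#'   [classifyAlignment()] on the same alignment.
#' @examples
#' attributeIndelEvents(AlignedPair("AAAAAATG", "AAAA--TG"))
#' @export
attributeIndelEvents <- function(aln, minLen = 5L) {
  stopifnot(is(aln, "AlignedPair"))
  r <- s2c(aln@refAligned)
  q <- s2c(aln@qryAligned)
  n <- length(r)
  if (n > 0L && (r[1L] == "-" || r[n] == "-"))
    stop("alignment is not reference-adjusted (terminal reference gap); ",
         "run adjustToReference() first", call. = FALSE)
  refGap <- r == "-"
  refPos <- cumsum(!refGap)          # reference coordinate of each column
  refSeq <- paste(r[!refGap], collapse = "")
  runs <- findHomopolymerRuns(refSeq, minLen)

  eventRuns <- function(flag) {
    rl <- rle(flag)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    cbind(start = starts[rl$values], end = ends[rl$values])
  }
  overlapsRun <- function(lo, hi) {
    nrow(runs) > 0L && any(runs$start <= hi & runs$end >= lo)
  }
  adjacentSameBase <- function(lo, hi, base) {
    nrow(runs) > 0L &&
      any(runs$base == base & (runs$end == lo - 1L | runs$start == hi + 1L))
  }

  delRuns <- eventRuns(!refGap & q == "-")
  delIn <- 0L
  for (e in seq_len(nrow(delRuns))) {
    cols <- delRuns[e, "start"]:delRuns[e, "end"]
    lo <- refPos[cols[1L]]
    hi <- refPos[cols[length(cols)]]
    bases <- unique(r[cols])
    hit <- overlapsRun(lo, hi) ||
      (length(bases) == 1L && adjacentSameBase(lo, hi, bases))
    if (hit) delIn <- delIn + 1L
  }

  insRuns <- eventRuns(refGap & q != "-")
  insIn <- 0L
  for (e in seq_len(nrow(insRuns))) {
    cols <- insRuns[e, "start"]:insRuns[e, "end"]
    bases <- unique(q[cols])
    if (length(bases) != 1L || bases == "N") next
    p <- refPos[cols[1L]]            # reference base left of the insertion
    # a run touches the insertion junction if it covers p or starts at p+1
    hit <- nrow(runs) > 0L &&
      any(runs$base == bases & runs$start <= p + 1L & runs$end >= p)
    if (hit) insIn <- insIn + 1L
  }

  new("ErrorContextSummary",
      deletionEvents = nrow(delRuns), deletionEventsInHp = delIn,
      insertionEvents = nrow(insRuns), insertionEventsInHp = insIn,
      minHpLen = as.integer(minLen))
}

#' Write homopolymer runs as BED
#'
#' @param runs Data frame from [findHomopolymerRuns()].
#' @param path Output path.
#' @param chrom Sequence name for the BED records.
#' @return `path`, invisibly.
#' @export
writeHomopolymerBed <- function(runs, path, chrom = "reference") {
  gr <- GRanges(seqnames = chrom,
                ranges = IRanges(start = runs$start, end = runs$end))
  names(gr) <- paste0(runs$base, runs$length)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
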