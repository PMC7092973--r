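#' @include AllClasses.R accessors.R classify.R
NULL

#' Derive a variant table from a pairwise alignment
#'
#' Produces one variant per substitution column, one per deletion event
#' (positioned at the first deleted reference base) and one per insertion
#' event (positioned at the reference base left of the insertion; position 1
#' for an insertion at the very start).  N columns produce no variant.  This
#' mirrors how a variant caller emits one record per event, so window
#' densities from alignments and from VCFs are comparable.
#'
#' @param aln A reference-adjusted [AlignedPair-class].
#' @return A sorted integer vector of 1-based reference positions (one entry
#'   per variant record; a multi-base indel is a single variant).
#' @examples
#' variantsFromAlignment(AlignedPair("ACGTAAAAATGC", "ACGTAAA--TGC"))
#' @export
variantsFromAlignment <- function(aln) {
  stopifnot(is(aln, "AlignedPair"))
  r <- s2c(aln@refAligned)
  q <- s2c(aln@qryAligned)
  refGap <- r == "-"
  refPos <- cumsum(!refGap)
  isSub <- !refGap & q != "-" & q != "N" & r != "N" & r != q
  firstOfRun <- function(flag) {
    rl <- rle(flag)
    ends <- cumsum(rl$lengths)
    (ends - rl$lengths + 1L)[rl$values]
  }
  delCols <- firstOfRun(!refGap & q == "-")
  insCols <- firstOfRun(refGap & q != "-")
  pos <- c(refPos[isSub], refPos[delCols], pmax(refPos[insCols], 1L))
  sort(as.integer(pos))
}

#' Load a variant table from a VCF file
#'
#' Reads a VCF 4.x file (plain or bgzipped) and keeps one position per
#' non-filtered record (`FILTER` of `PASS` or `.`); multiallelic records
#' count once.  All records must lie on a single reference contig.
#'
#' @param path Path to the VCF file.
#' @return A sorted integer vector of 1-based positions.
#' @export
loadVariantsFromVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  if (nrow(fx) == 0L) return(integer(0))
  contigs <- unique(fx[, "CHROM"])
  if (length(contigs) > 1L)
    stop("VCF contains records on multiple contigs: ",
         paste(contigs, collapse = ", "), call. = FALSE)
  filt <- fx[, "FILTER"]
  keep <- is.na(filt) | filt %in% c("PASS", ".")
  sort(as.integer(fx[keep, "POS"]))
}

#' Count variants in fixed windows
#'
#' Tiles `[1, refLen]` with non-overlapping windows of `window` bp anchored
#' at position 1 (the final, possibly partial window is kept) and counts the
#' variants in each.
#'
#' @param variants Sorted integer vector of 1-based positions.
#' @param refLen Reference length in bp.
#' @param window Window size in bp (default 1000).
#' @return A data frame with columns `start`, `end`, `count`; counts sum to
#'   `length(variants)`.
#' @examples
#' windowCounts(c(1L, 1000L, 1001L), refLen = 2000)
#' @export
windowCounts <- function(variants, refLen, window = 1000L) {
  stopifnot(window >= 1L, refLen >= 1L)
  variants <- as.integer(variants)
  if (any(variants < 1L | variants > refLen))
    stop("variant position outside [1, refLen]", call. = FALSE)
  starts <- seq.int(1L, refLen, by = window)
  nw <- length(starts)
  counts <- tabulate((variants - 1L) %/% window + 1L, nbins = nw)
  data.frame(start = starts,
             end = pmin(starts + window - 1L, as.integer(refLen)),
             count = counts)
}

#' Flag high-variability windows
#'
#' Windows with *strictly more* than `threshold` variants, in coordinate
#' order.
#'
#' @param density Data frame from [windowCounts()].
#' @param threshold Count threshold (default 8: "more than eight variants").
#' @return The flagged subset of `density`.
#' @export
flagHighVariabilityWindows <- function(density, threshold = 8L) {
  stopifnot(all(c("start", "end", "count") %in% names(density)))
  out <- density[density$count > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a candidate marker region
#'
#' Computes the variant count and variability of a named interval, and
#' optionally the hotspot bounded by the first and last variant inside a
#' caller-supplied sub-window.
#'
#' @param variants Sorted integer vector of 1-based positions.
#' @param start,end 1-based inclusive interval on the reference.
#' @param name Marker name.
#' @param hotspotWindow Optional length-2 vector `c(start, end)`; when
#'   given, the hotspot is `[first variant, last variant]` within it.
#' @return A one-row data frame: `name`, `start`, `end`, `length`,
#'   `variants`, `variabilityPct` (= `round(100 * variants / length, 2)`),
#'   `hotspotStart`, `hotspotEnd` (NA when absent).
#' @examples
#' summarizeMarker(c(10L, 200L, 860L), 1, 869, "trnE-rpoB")
#' @export
summarizeMarker <- function(variants, start, end, name,
                            hotspotWindow = NULL) {
  if (end < start) stop("empty marker interval", call. = FALSE)
  variants <- as.integer(variants)
  len <- end - start + 1L
  inside <- variants[variants >= start & variants <= end]
  hs <- c(NA_integer_, NA_integer_)
  if (!is.null(hotspotWindow)) {
    inWin <- inside[inside >= hotspotWindow[1L] & inside <= hotspotWindow[2L]]
    if (length(inWin) > 0L) hs <- range(inWin)
  }
  data.frame(name = name, start = as.integer(start), end = as.integer(end),
             length = len, variants = length(inside),
             variabilityPct = roundHalfUp(100 * length(inside) / len, 2L),
             hotspotStart = hs[1L], hotspotEnd = hs[2L])
}

#' Read marker intervals from a BED file
#'
#' @param path BED file of annotation intervals (name column used as marker
#'   name).
#' @return A data frame with columns `name`, `start`, `end` (1-based
#'   inclusive).
#' @export
readMarkerBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- if (is.null(gr$name)) paste0("region", seq_along(gr)) else gr$name
  data.frame(name = nm, start = start(gr), end = end(gr))
}
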