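#' @include AllClasses.R accessors.R classify.R error-context.R marker-scan.R
NULL

# Coerce a reference/query input (record, FASTA path, or raw sequence) to a
# PlastomeRecord; plain sequences get no region map.
asRecord <- function(x, id = "seq") {
  if (is(x, "PlastomeRecord")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (file.exists(x) && grepl("\\.(fa|fasta|fna)(\\.gz)?$", x,
                                ignore.case = TRUE))
      return(readPlastomeFasta(x)[[1L]])
    return(PlastomeRecord(id, x))
  }
  stop("cannot interpret input as a plastome record", call. = FALSE)
}

#' Compare query assemblies against a reference assembly
#'
#' Runs the full concordance pipeline for each query: optional SSC
#' orientation normalization, IR_A stripping of both sequences (when region
#' maps are available), anchored global alignment, adjustment to the
#' reference frame, mismatch classification, identity computation, and
#' homopolymer attribution of the indel events.  The first output row
#' describes the reference itself (mismatch fields `NA`, mirroring the
#' "n.a." convention of published comparison tables).
#'
#' @param reference Reference assembly ([PlastomeRecord-class], FASTA path,
#'   or sequence string).
#' @param queries List of query assemblies (same forms), or a single one.
#' @param labels Optional row labels (default: record ids).
#' @param aligned Optional list of pre-computed [AlignedPair-class] objects
#'   (or aligned-FASTA paths), one per query, bypassing the internal
#'   aligner.
#' @param normalizeSsc Normalize query SSC orientation first (needs region
#'   maps on both sides).
#' @param minHpLen Homopolymer run length for indel attribution.
#' @param params Alignment parameters from [alignParams()].
#' @return A data frame with one row per assembly: `label`,
#'   `assemblyLength` (IR_A-stripped bp), `gcPct`, `identityPct`,
#'   `nPositionsPct`, mismatch taxonomy counts, and in-homopolymer indel
#'   fractions.
#' @examples
#' rec <- assemblePlastome(strrep("ACGGT", 60), strrep("GATTC", 20),
#'                         strrep("TTACG", 20))
#' runCompare(rec, rec, labels = c("reference", "self"))
#' @export
runCompare <- function(reference, queries, labels = NULL, aligned = NULL,
                       normalizeSsc = TRUE, minHpLen = 5L,
                       params = alignParams()) {
  reference <- asRecord(reference, "reference")
  if (!is.list(queries)) queries <- list(queries)
  queries <- lapply(seq_along(queries), function(i)
    asRecord(queries[[i]], paste0("query", i)))
  if (is.null(labels))
    labels <- vapply(queries, seqId, character(1))
  refSeq <- if (!is.null(regionMap(reference))) stripIRa(reference)
            else plastomeSequence(reference)
  refRow <- data.frame(label = seqId(reference),
                       assemblyLength = nchar(refSeq),
                       gcPct = roundHalfUp(100 * gcFraction(refSeq), 2L),
                       profileRow(MismatchProfile(0L, 0L, 0L,
                                                  refLength = nchar(refSeq))),
                       deletionHpFraction = NA_real_,
                       insertionHpFraction = NA_real_,
                       status = "reference")
  refRow[, c("identityPct", "nPositionsPct", "mismatches", "substitutions",
             "deletedBases", "deletionEvents", "insertedBases",
             "insertionEvents", "nPositions", "alignmentLength")] <- NA
  rows <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    rows[[i]] <- tryCatch({
      qry <- queries[[i]]
      if (normalizeSsc && !is.null(regionMap(qry)) &&
          !is.null(regionMap(reference)))
        qry <- normalizeSscOrientation(qry, reference)
      qrySeq <- if (!is.null(regionMap(qry))) stripIRa(qry)
                else plastomeSequence(qry)
      aln <- if (!is.null(aligned) && !is.null(aligned[[i]])) {
        a <- aligned[[i]]
        if (is.character(a)) a <- readAlignedFasta(a)
        a
      } else {
        alignPair(refSeq, qrySeq, params = params)
      }
      aln <- adjustToReference(aln)
      prof <- classifyAlignment(aln)
      ctx <- attributeIndelEvents(aln, minLen = minHpLen)
      data.frame(label = labels[i],
                 assemblyLength = nchar(qrySeq),
                 gcPct = roundHalfUp(100 * gcFraction(qrySeq), 2L),
                 profileRow(prof),
                 deletionHpFraction = deletionHpFraction(ctx),
                 insertionHpFraction = insertionHpFraction(ctx),
                 status = "ok")
    }, error = function(e) {
      bad <- refRow[1, , drop = FALSE]
      bad$label <- labels[i]
      bad$assemblyLength <- NA_integer_
      bad$gcPct <- NA_real_
      bad$status <- conditionMessage(e)
      bad
    })
  }
  out <- rbind(refRow, do.call(rbind, rows))
  rownames(out) <- NULL
  if (all(out$status[-1L] != "ok") && length(queries) > 0L)
    stop("all comparisons failed; first error: ", out$status[2L],
         call. = FALSE)
  out
}

#' Assemble a comparison report from published counts
#'
#' Fixture-input mode of [runCompare()]: builds the identity and share
#' columns directly from [MismatchProfile-class] objects (e.g. transcribed
#' from a published table) without any alignment.
#'
#' @param profiles List of [MismatchProfile-class] objects.
#' @param labels Row labels.
#' @return A data frame with one row per profile: `label`, `identityPct`
#'   and the taxonomy counts/shares.
#' @export
comparisonFromProfiles <- function(profiles, labels) {
  stopifnot(length(profiles) == length(labels))
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    sh <- mismatchShares(p)
    data.frame(label = labels[i], profileRow(p),
               subPct = sh[["substitutions"]], gapPct = sh[["gaps"]],
               insPct = sh[["insertions"]], indelPct = sh[["indels"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Windowed variant density and marker summarization
#'
#' Computes the per-window variant density of a reference, flags windows
#' exceeding the variant-count threshold, and summarizes caller-supplied
#' marker intervals (variant counts, variability percentages, optional
#' hotspots).
#'
#' @param variants Sorted 1-based positions, or a VCF path (loaded with
#'   [loadVariantsFromVcf()]).
#' @param refLen Reference length in bp.
#' @param window Window size in bp (default 1000).
#' @param threshold Flagging threshold: windows with strictly more variants
#'   are reported (default 8).
#' @param markers Optional marker intervals: a data frame with `name`,
#'   `start`, `end` and optionally `hotspotStart`, `hotspotEnd` (a
#'   sub-window within which the hotspot is bounded by the first and last
#'   variant), or a BED path.
#' @return A list with `density` (from [windowCounts()]), `flagged` (from
#'   [flagHighVariabilityWindows()]) and `markers` (one
#'   [summarizeMarker()] row per interval, or `NULL`).
#' @export
runMarkers <- function(variants, refLen, window = 1000L, threshold = 8L,
                       markers = NULL) {
  if (is.character(variants) && length(variants) == 1L)
    variants <- loadVariantsFromVcf(variants)
  density <- windowCounts(variants, refLen, window)
  flagged <- flagHighVariabilityWindows(density, threshold)
  markerTable <- NULL
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- readMarkerBed(markers)
    rows <- lapply(seq_len(nrow(markers)), function(i) {
      hw <- if (all(c("hotspotStart", "hotspotEnd") %in% names(markers)) &&
                !is.na(markers$hotspotStart[i]))
        c(markers$hotspotStart[i], markers$hotspotEnd[i])
      else NULL
      summarizeMarker(variants, markers$start[i], markers$end[i],
                      markers$name[i], hotspotWindow = hw)
    })
    markerTable <- do.call(rbind, rows)
    rownames(markerTable) <- NULL
  }
  list(density = density, flagged = flagged, markers = markerTable)
}

#' Write and read tab-separated reports
#'
#' Plain TSV serialization used for all report tables; `readReportTsv()`
#' round-trips what `writeReportTsv()` wrote.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `path` (writer, invisibly) or a data frame (reader).
#' @export
writeReportTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname writeReportTsv
#' @export
readReportTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write alignment difference events as BED
#'
#' One BED feature per substitution, deletion event and insertion event, in
#' reference coordinates, named by type.
#'
#' @param aln A reference-adjusted [AlignedPair-class].
#' @param path Output path.
#' @param chrom Reference name for the BED records.
#' @return `path`, invisibly.
#' @export
writeEventBed <- function(aln, path, chrom = "reference") {
  r <- s2c(aln@refAligned)
  q <- s2c(aln@qryAligned)
  refGap <- r == "-"
  refPos <- cumsum(!refGap)
  isSub <- !refGap & q != "-" & q != "N" & r != "N" & r != q
  runsOf <- function(flag) {
    rl <- rle(flag)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    cbind(starts[rl$values], ends[rl$values])
  }
  del <- runsOf(!refGap & q == "-")
  ins <- runsOf(refGap & q != "-")
  starts <- c(refPos[isSub], refPos[del[, 1L]],
              pmax(refPos[ins[, 1L]], 1L))
  ends <- c(refPos[isSub], refPos[del[, 2L]], pmax(refPos[ins[, 1L]], 1L))
  types <- c(rep("substitution", sum(isSub)),
             rep("deletion", nrow(del)), rep("insertion", nrow(ins)))
  ord <- order(starts)
  gr <- GRanges(seqnames = chrom,
                ranges = IRanges(start = starts[ord], end = ends[ord]))
  names(gr) <- types[ord]
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
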