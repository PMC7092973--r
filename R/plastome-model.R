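#' @include AllClasses.R accessors.R
NULL

#' Assemble a quadripartite plastome from its three unique segments
#'
#' Builds the canonical circular-plastome linearization
#' `LSC + IRb + SSC + IRa`, where IRa is the reverse complement of the
#' supplied IR segment -- the same construction used to restore the second
#' repeat copy after assembly.
#'
#' @param lsc,ir,ssc DNA character strings (non-empty, over `A,C,G,T,N`).
#' @param id Identifier for the resulting record.
#' @return A [PlastomeRecord-class] with its [RegionMap-class] set; total
#'   length is `nchar(lsc) + 2 * nchar(ir) + nchar(ssc)`.
#' @examples
#' rec <- assemblePlastome("AAAT", "CG", "TTA")
#' plastomeSequence(rec)
#' regionWidths(rec)
#' @export
assemblePlastome <- function(lsc, ir, ssc, id = "plastome") {
  checkDna(lsc, "lsc")
  checkDna(ir, "ir")
  checkDna(ssc, "ssc")
  seq <- paste0(lsc, ir, ssc, revComp(ir))
  PlastomeRecord(id, seq,
                 regions = RegionMap(nchar(lsc), nchar(ir), nchar(ssc)))
}

#' Detect the inverted repeat and derive a region map
#'
#' Finds the longest maximal pair of exact reverse-complement repeats of at
#' least `minIrLen` bp whose copies do not overlap, and returns the implied
#' quadripartite [RegionMap-class].  Copies are located by matching k-mers of
#' the sequence against its reverse complement and merging co-diagonal hits
#' into maximal runs, so only *exact* repeat copies are found; assemblies
#' whose polished IR copies have desynchronized raise "no IR detected" rather
#' than guessing.
#'
#' The single-copy segment preceding the first repeat copy is labelled LSC
#' when it is at least as long as the segment between the copies (the
#' longer-segment rule, with the position-0 segment winning ties).  The
#' sequence must be in the canonical rotation with the second repeat copy
#' ending at the final position.
#'
#' @param sequence DNA character string.
#' @param minIrLen Minimum repeat length in bp (default 10000).
#' @return A [RegionMap-class].
#' @examples
#' rec <- assemblePlastome(strrep("ACGGT", 40), strrep("GATTC", 20),
#'                         strrep("TTACG", 12))
#' detectInvertedRepeat(plastomeSequence(rec), minIrLen = 50)
#' @export
detectInvertedRepeat <- function(sequence, minIrLen = 10000L) {
  checkDna(sequence, "sequence")
  n <- nchar(sequence)
  cand <- invertedRepeatCandidates(sequence, minIrLen)
  if (nrow(cand) == 0L)
    stop("no IR detected (no exact reverse-complement repeat >= ",
         minIrLen, " bp with non-overlapping copies)", call. = FALSE)
  best <- cand[cand$length == max(cand$length), , drop = FALSE]
  if (nrow(best) > 1L)
    stop("ambiguous IR: ", nrow(best), " non-nested candidates of length ",
         best$length[1L], " bp at [",
         paste(sprintf("%d-%d/%d-%d", best$s1, best$e1, best$s2, best$e2),
               collapse = ", "), "]", call. = FALSE)
  s1 <- best$s1; e1 <- best$e1; s2 <- best$s2; e2 <- best$e2
  if (e2 != n)
    stop("IR detected but genome is not in canonical LSC-IRb-SSC-IRa ",
         "rotation (trailing single-copy segment after the second repeat ",
         "copy); rotate the sequence first", call. = FALSE)
  lenA <- s1 - 1L          # segment before the first copy
  lenB <- s2 - e1 - 1L     # segment between the copies
  if (lenA < 1L || lenB < 1L)
    stop("no IR detected (degenerate single-copy segments)", call. = FALSE)
  if (lenB > lenA)
    stop("IR detected but the longer single-copy segment is not first; ",
         "genome appears rotated (SSC leading); rotate the sequence first",
         call. = FALSE)
  RegionMap(lenA, e1 - s1 + 1L, lenB)
}

# All maximal exact reverse-complement repeat pairs of length >= minLen with
# non-overlapping copies, found via k-mer matches between the sequence and
# its reverse complement grouped by diagonal.
invertedRepeatCandidates <- function(sequence, minLen) {
  n <- nchar(sequence)
  k <- min(31L, as.integer(minLen))
  empty <- data.frame(s1 = integer(), e1 = integer(),
                      s2 = integer(), e2 = integer(), length = integer())
  if (n < 2L * k) return(empty)
  rc <- revComp(sequence)
  iS <- seq_len(n - k + 1L)
  kS <- substring(sequence, iS, iS + k - 1L)
  kT <- substring(rc, iS, iS + k - 1L)
  # drop hyper-repetitive k-mers to bound the match list
  tS <- table(kS)
  keep <- kS %in% names(tS)[tS <= 10L]
  grpT <- split(iS, kT)
  hits <- grpT[kS[keep]]
  iHit <- rep(iS[keep], lengths(hits))
  jHit <- unlist(hits, use.names = FALSE)
  if (length(iHit) == 0L) return(empty)
  d <- iHit - jHit
  runs <- do.call(rbind, lapply(split(iHit, d), function(ii) {
    ii <- sort(ii)
    brk <- c(0L, which(diff(ii) != 1L), length(ii))
    cbind(i0 = ii[brk[-length(brk)] + 1L], i1 = ii[brk[-1L]])
  }))
  dRun <- rep(as.integer(names(split(iHit, d))), {
    tmp <- vapply(split(iHit, d), function(ii) {
      sum(diff(sort(ii)) != 1L) + 1L
    }, integer(1))
    tmp
  })
  # copy1 = [i0, i1+k-1] on S; matching j range gives copy2 on S
  s1 <- runs[, "i0"]
  e1 <- runs[, "i1"] + k - 1L
  jMax <- runs[, "i1"] - dRun
  jMin <- runs[, "i0"] - dRun
  s2 <- n - (jMax + k - 1L) + 1L
  e2 <- n - jMin + 1L
  len <- e1 - s1 + 1L
  cand <- data.frame(s1 = s1, e1 = e1, s2 = s2, e2 = e2, length = len)
  # orient so copy1 precedes copy2; drop overlapping/self pairs
  flip <- cand$s2 < cand$s1
  cand[flip, c("s1", "e1", "s2", "e2")] <-
    cand[flip, c("s2", "e2", "s1", "e1")]
  cand <- cand[cand$length >= minLen & cand$e1 < cand$s2, , drop = FALSE]
  unique(cand)
}

#' Drop the second inverted repeat copy
#'
#' Returns `LSC + IRb + SSC`, the representation used for all pairwise
#' comparisons (the IR_A carries no independent information, being the exact
#' reverse complement of IR_B).
#'
#' @param record A [PlastomeRecord-class] with a region map.
#' @return A character string of length `total - width(IRA)`.
#' @examples
#' rec <- assemblePlastome("AAAT", "CG", "TTA")
#' stripIRa(rec)
#' @export
stripIRa <- function(record) {
  stopifnot(is(record, "PlastomeRecord"))
  if (is.null(record@regions))
    stop("record has no region map; run detectInvertedRepeat() first",
         call. = FALSE)
  sscEnd <- end(regionRange(record, "SSC"))
  substr(as.character(record@sequence), 1L, sscEnd)
}

#' Normalize the SSC orientation against a reference
#'
#' Both orientations of the small single-copy region coexist in plastid
#' populations, so two assemblies of close relatives may come out with
#' opposite SSC strands.  If the edit distance between the record's SSC and
#' the reference SSC exceeds that of its reverse complement, the SSC is
#' flipped in place (region boundaries unchanged).  The operation is
#' idempotent; ties leave the record unchanged.
#'
#' @param record,reference [PlastomeRecord-class] objects with region maps.
#' @return The (possibly SSC-flipped) record.
#' @export
normalizeSscOrientation <- function(record, reference) {
  stopifnot(is(record, "PlastomeRecord"), is(reference, "PlastomeRecord"))
  if (is.null(record@regions) || is.null(reference@regions))
    stop("both records need region maps", call. = FALSE)
  ssc <- regionSequence(record, "SSC")
  refSsc <- regionSequence(reference, "SSC")
  dFwd <- adist(ssc, refSsc)[1L, 1L]
  dRev <- adist(revComp(ssc), refSsc)[1L, 1L]
  if (dRev >= dFwd) return(record)
  r <- regionRange(record, "SSC")
  s <- as.character(record@sequence)
  newSeq <- paste0(substr(s, 1L, start(r) - 1L), revComp(ssc),
                   substr(s, end(r) + 1L, nchar(s)))
  PlastomeRecord(record@id, newSeq, regions = record@regions)
}

#' G+C fraction of called bases
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; N is excluded from both numerator and
#' denominator, so the value reflects the composition of called bases only.
#'
#' @param sequence DNA character string (may be empty).
#' @return A fraction in `[0, 1]`, or `NA` for empty/all-N input.
#' @examples
#' gcFraction("ACGN")  # 1/3
#' @export
gcFraction <- function(sequence) {
  if (is(sequence, "PlastomeRecord"))
    sequence <- plastomeSequence(sequence)
  checkDna(sequence, "sequence", allowEmpty = TRUE)
  if (nchar(sequence) == 0L) return(NA_real_)
  f <- alphabetFrequency(DNAString(sequence))
  called <- sum(f[c("A", "C", "G", "T")])
  if (called == 0L) return(NA_real_)
  sum(f[c("G", "C")]) / called
}

#' Serialize a region map as BED
#'
#' Writes four BED features named LSC, IRB, SSC, IRA (BED's 0-based
#' half-open convention handled by [rtracklayer::export]).
#'
#' @param map A [RegionMap-class] (or a [PlastomeRecord-class] with one).
#' @param path Output file path.
#' @param chrom Chromosome/sequence name for the BED records.
#' @return `path`, invisibly.
#' @export
writeRegionMapBed <- function(map, path, chrom = "plastome") {
  if (is(map, "PlastomeRecord")) {
    chrom <- seqId(map)
    map <- regionMap(map)
  }
  stopifnot(is(map, "RegionMap"))
  gr <- GRanges(seqnames = chrom, ranges = map@ranges)
  names(gr) <- names(map@ranges)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a region map from BED
#'
#' @param path A BED file with exactly four features named LSC, IRB, SSC,
#'   IRA (any order; reordered by coordinate).
#' @return A [RegionMap-class].
#' @export
readRegionMapBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) != 4L || is.null(gr$name) ||
      !setequal(gr$name, c("LSC", "IRB", "SSC", "IRA")))
    stop("BED file must contain exactly the features LSC, IRB, SSC, IRA",
         call. = FALSE)
  gr <- gr[order(start(gr))]
  r <- IRanges(start = start(gr), end = end(gr), names = gr$name)
  new("RegionMap", ranges = r)
}

#' Read plastome records from a FASTA file
#'
#' @param path Multi-record FASTA file.
#' @return A list of [PlastomeRecord-class] objects (regions unset).
#' @export
readPlastomeFasta <- function(path) {
  ss <- readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  lapply(seq_along(ss), function(i)
    PlastomeRecord(ids[i], toupper(as.character(ss[[i]]))))
}

#' Write plastome records to FASTA
#'
#' Sequences are wrapped at 70 columns.
#'
#' @param records A [PlastomeRecord-class] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePlastomeFasta <- function(records, path) {
  if (is(records, "PlastomeRecord")) records <- list(records)
  ss <- DNAStringSet(vapply(records, plastomeSequence, character(1)))
  names(ss) <- vapply(records, seqId, character(1))
  writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
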