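#' @include AllClasses.R accessors.R
NULL

# Scoring scheme container with the package defaults: match 1, mismatch -2,
# affine gaps costing gapOpen + len * gapExt.  N scores 0 against anything.
alignParams <- function(match = 1, mismatch = -2, gapOpen = 4, gapExt = 1,
                        k = 21L) {
  list(match = match, mismatch = mismatch,
       gapOpen = gapOpen, gapExt = gapExt, k = as.integer(k))
}

substMatrix <- function(params) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- params$match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

# Longest strictly increasing subsequence of j; returns indices into j.
# Patience algorithm with preallocated buffers; the common almost-sorted
# case (collinear anchors) takes the O(1) append fast path.
lisIndices <- function(j) {
  n <- length(j)
  if (n == 0L) return(integer(0))
  tails <- numeric(n)      # smallest tail value of an LIS of each length
  tailAt <- integer(n)     # index of that tail in j
  prev <- integer(n)
  top <- 0L
  for (t in seq_len(n)) {
    x <- j[t]
    if (top > 0L && x > tails[top]) {
      pos <- top + 1L
    } else {
      lo <- 1L
      hi <- top
      while (lo <= hi) {
        mid <- (lo + hi) %/% 2L
        if (tails[mid] < x) lo <- mid + 1L else hi <- mid - 1L
      }
      pos <- lo
    }
    tails[pos] <- x
    tailAt[pos] <- t
    prev[t] <- if (pos > 1L) tailAt[pos - 1L] else 0L
    top <- max(top, pos)
  }
  out <- integer(top)
  t <- tailAt[top]
  for (p in rev(seq_len(top))) {
    out[p] <- t
    t <- prev[t]
  }
  out
}

# Collinear chain of unique shared k-mer anchors, merged into maximal exact
# blocks (refStart, refEnd, qryStart, qryEnd), trimmed to be non-overlapping.
anchorBlocks <- function(ref, qry, k) {
  nr <- nchar(ref)
  nq <- nchar(qry)
  if (nr < k || nq < k) return(NULL)
  iR <- seq_len(nr - k + 1L)
  iQ <- seq_len(nq - k + 1L)
  kR <- substring(ref, iR, iR + k - 1L)
  kQ <- substring(qry, iQ, iQ + k - 1L)
  uR <- !(duplicated(kR) | duplicated(kR, fromLast = TRUE))
  uQ <- !(duplicated(kQ) | duplicated(kQ, fromLast = TRUE))
  m <- match(kR, kQ)
  ok <- uR & !is.na(m) & uQ[ifelse(is.na(m), 1L, m)]
  if (!any(ok)) return(NULL)
  ai <- iR[ok]
  aj <- iQ[m[ok]]
  keep <- lisIndices(aj)           # ai already ascending
  ai <- ai[keep]
  aj <- aj[keep]
  diag <- ai - aj
  newBlock <- c(TRUE, diff(diag) != 0L | diff(ai) > k)
  grp <- cumsum(newBlock)
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  b <- data.frame(refStart = ai[first], refEnd = ai[last] + k - 1L,
                  qryStart = aj[first], qryEnd = aj[last] + k - 1L)
  # trim any residual overlap between consecutive blocks (different
  # diagonals can still overlap in one coordinate)
  for (r in seq_len(nrow(b))[-1L]) {
    t <- max(b$refEnd[r - 1L] - b$refStart[r] + 1L,
             b$qryEnd[r - 1L] - b$qryStart[r] + 1L, 0L)
    b$refStart[r] <- b$refStart[r] + t
    b$qryStart[r] <- b$qryStart[r] + t
  }
  b <- b[b$refStart <= b$refEnd & b$qryStart <= b$qryEnd, , drop = FALSE]
  if (nrow(b) == 0L) NULL else b
}

# Globally align two (short) segments, returning c(refRow, qryRow).
# The common one-event cases (identical segments, few substitutions, a
# single clean indel) are resolved directly; everything else goes through
# affine-gap dynamic programming.
fillSegment <- function(refSeg, qrySeg, params, maxCells = 6.4e7) {
  nr <- nchar(refSeg)
  nq <- nchar(qrySeg)
  if (nr == 0L && nq == 0L) return(c("", ""))
  if (nr == 0L) return(c(strrep("-", nq), qrySeg))
  if (nq == 0L) return(c(refSeg, strrep("-", nr)))
  if (refSeg == qrySeg) return(c(refSeg, qrySeg))
  rb <- charToRaw(refSeg)
  qb <- charToRaw(qrySeg)
  noN <- !any(rb == charToRaw("N")) && !any(qb == charToRaw("N"))
  if (noN && nr == nq) {
    # ungapped is provably optimal while the total substitution penalty is
    # below the cheapest gapped layout (one gap run in each row)
    h <- sum(rb != qb)
    if (h * (params$match - params$mismatch) <
        2 * (params$gapOpen + params$gapExt))
      return(c(refSeg, qrySeg))
  }
  if (noN && nr != nq) {
    # single clean indel: shorter segment = prefix + suffix of the longer
    mn <- min(nr, nq)
    d <- abs(nr - nq)
    pref <- match(TRUE, rb[seq_len(mn)] != qb[seq_len(mn)],
                  nomatch = mn + 1L) - 1L
    suf <- match(TRUE, rev(rb)[seq_len(mn)] != rev(qb)[seq_len(mn)],
                 nomatch = mn + 1L) - 1L
    if (pref + min(suf, mn - pref) >= mn) {
      suf <- mn - pref
      gap <- strrep("-", d)
      if (nr > nq)   # deletion in the query
        return(c(refSeg,
                 paste0(substr(qrySeg, 1L, pref), gap,
                        substr(qrySeg, pref + 1L, nq))))
      return(c(paste0(substr(refSeg, 1L, pref), gap,
                      substr(refSeg, pref + 1L, nr)),
               qrySeg))
    }
  }
  if (as.double(nr) * nq > maxCells)
    stop("unalignable without rearrangement: unanchored segment of ",
         nr, " x ", nq, " bp; if the query's SSC is inverted, run ",
         "normalizeSscOrientation() first", call. = FALSE)
  pa <- pairwiseAlignment(DNAString(refSeg), DNAString(qrySeg),
                          type = "global",
                          substitutionMatrix = substMatrix(params),
                          gapOpening = params$gapOpen,
                          gapExtension = params$gapExt)
  c(as.character(alignedPattern(pa)), as.character(alignedSubject(pa)))
}

#' Globally align a query consensus to a reference
#'
#' Anchor-and-fill global alignment: unique k-mers shared by both sequences
#' (default `k = 21`) are chained collinearly (longest increasing
#' subsequence) and merged into maximal exact blocks; the gaps between
#' consecutive blocks and at both ends are closed by affine-gap global
#' dynamic programming (match 1, mismatch -2, gap open 4, gap extend 1 by
#' default).  Deterministic for fixed inputs and parameters.  Inputs with no
#' collinear anchor chain (e.g. a reversed SSC) raise an error advising SSC
#' normalization, unless they are small enough for direct dynamic
#' programming.
#'
#' @param ref,qry DNA character strings (or [PlastomeRecord-class]s, whose
#'   full sequences are used).
#' @param params Scoring parameters from [alignParams()].
#' @return An [AlignedPair-class] (reference row first).
#' @examples
#' alignPair("AAAATTTT", "AAAATT", params = alignParams(k = 3))
#' @export
alignPair <- function(ref, qry, params = alignParams()) {
  if (is(ref, "PlastomeRecord")) ref <- plastomeSequence(ref)
  if (is(qry, "PlastomeRecord")) qry <- plastomeSequence(qry)
  checkDna(ref, "ref")
  checkDna(qry, "qry")
  blocks <- anchorBlocks(ref, qry, params$k)
  if (is.null(blocks)) {
    rows <- fillSegment(ref, qry, params)   # errors when too large
    return(AlignedPair(rows[1L], rows[2L]))
  }
  refRows <- character(0)
  qryRows <- character(0)
  pr <- 1L
  pq <- 1L
  for (r in seq_len(nrow(blocks))) {
    seg <- fillSegment(substr(ref, pr, blocks$refStart[r] - 1L),
                       substr(qry, pq, blocks$qryStart[r] - 1L), params)
    blk <- substr(ref, blocks$refStart[r], blocks$refEnd[r])
    refRows <- c(refRows, seg[1L], blk)
    qryRows <- c(qryRows, seg[2L], blk)
    pr <- blocks$refEnd[r] + 1L
    pq <- blocks$qryEnd[r] + 1L
  }
  seg <- fillSegment(substr(ref, pr, nchar(ref)),
                     substr(qry, pq, nchar(qry)), params)
  AlignedPair(paste(c(refRows, seg[1L]), collapse = ""),
              paste(c(qryRows, seg[2L]), collapse = ""))
}

#' Score a gapped alignment under the package scoring scheme
#'
#' Sums match/mismatch scores over base-base columns (columns involving N
#' score 0) and charges each maximal gap run, in either row,
#' `gapOpen + length * gapExt`.
#'
#' @param aln An [AlignedPair-class].
#' @param params Scoring parameters from [alignParams()].
#' @return A single numeric score.
#' @export
alignmentScore <- function(aln, params = alignParams()) {
  stopifnot(is(aln, "AlignedPair"))
  r <- s2c(aln@refAligned)
  q <- s2c(aln@qryAligned)
  refGap <- r == "-"
  qryGap <- q == "-"
  base <- !refGap & !qryGap
  hasN <- r == "N" | q == "N"
  sc <- sum(base & !hasN & r == q) * params$match +
    sum(base & !hasN & r != q) * params$mismatch
  for (g in list(refGap, qryGap)) {
    rl <- rle(g)
    runs <- rl$lengths[rl$values]
    sc <- sc - sum(params$gapOpen + runs * params$gapExt)
  }
  sc
}

#' Adjust an alignment to the reference frame
#'
#' Trims query overhangs and pads query end-gaps so that the alignment spans
#' exactly the reference: terminal columns where the reference is gapped
#' (query bases beyond the reference ends) are deleted, and terminal columns
#' where the query is gapped (reference positions with no query base) have
#' the query gap replaced by `N`.  Afterwards the alignment length equals
#' the reference length plus the internal insertion columns.
#'
#' @param aln An [AlignedPair-class].
#' @return The adjusted [AlignedPair-class].
#' @examples
#' adjustToReference(AlignedPair("--ACGT", "GGACGT"))  # overhang trimmed
#' adjustToReference(AlignedPair("ACGT", "--GT"))      # N padding
#' @export
adjustToReference <- function(aln) {
  stopifnot(is(aln, "AlignedPair"))
  r <- s2c(aln@refAligned)
  q <- s2c(aln@qryAligned)
  n <- length(r)
  drop <- logical(n)
  i <- 1L
  while (i <= n && (r[i] == "-" || q[i] == "-")) {
    if (r[i] == "-") drop[i] <- TRUE else q[i] <- "N"
    i <- i + 1L
  }
  j <- n
  while (j >= i && (r[j] == "-" || q[j] == "-")) {
    if (r[j] == "-") drop[j] <- TRUE else q[j] <- "N"
    j <- j - 1L
  }
  keep <- !drop
  AlignedPair(paste(r[keep], collapse = ""), paste(q[keep], collapse = ""))
}

#' Read a pre-computed pairwise alignment from aligned FASTA
#'
#' Accepts externally produced alignments (e.g. from a multiple-alignment
#' web service) as an aligned FASTA with exactly two records, the reference
#' first.
#'
#' @param path Aligned FASTA file with two equal-length gapped records.
#' @return An [AlignedPair-class].
#' @export
readAlignedFasta <- function(path) {
  ss <- readBStringSetUpper(path)
  if (length(ss) != 2L)
    stop("aligned FASTA must contain exactly 2 records (reference first); ",
         "found ", length(ss), call. = FALSE)
  AlignedPair(ss[[1L]], ss[[2L]])
}

# Gapped FASTA reader tolerant of '-' (DNAStringSet accepts it, but keep the
# rows as plain character strings).
readBStringSetUpper <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  lapply(seq_along(ss), function(i) toupper(as.character(ss[[i]])))
}

#' Write an aligned pair as aligned FASTA
#'
#' @param aln An [AlignedPair-class].
#' @param path Output path.
#' @param ids Record names (reference first).
#' @return `path`, invisibly.
#' @export
writeAlignedFasta <- function(aln, path, ids = c("reference", "query")) {
  stopifnot(is(aln, "AlignedPair"))
  ss <- Biostrings::BStringSet(c(aln@refAligned, aln@qryAligned))
  names(ss) <- ids
  writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
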