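#' @include AllClasses.R accessors.R plastome-model.R error-context.R
NULL

# ---------------------------------------------------------- length model

# Truncated geometric length distribution with a given mean on 1..maxLen.
truncGeomProbs <- function(meanLen, maxLen) {
  ls <- seq_len(maxLen)
  if (maxLen == 1L) return(1)
  meanOf <- function(p) {
    w <- (1 - p)^(ls - 1)
    sum(ls * w) / sum(w)
  }
  if (meanLen <= 1) return(c(1, rep(0, maxLen - 1L)))
  if (meanLen >= (maxLen + 1) / 2 - 1e-12) {
    p <- 1e-9
  } else {
    p <- uniroot(function(p) meanOf(p) - meanLen, c(1e-9, 1 - 1e-9),
                 tol = 1e-12)$root
  }
  w <- (1 - p)^(ls - 1)
  w / sum(w)
}

sampleIndelLengths <- function(n, probs) {
  if (n == 0L) return(integer(0))
  sample.int(length(probs), n, replace = TRUE, prob = probs)
}

# Substitute each base by one of the alternatives, uniformly (an N is
# replaced by a uniformly random called base).
substituteBases <- function(bases) {
  vapply(bases, function(b) {
    alt <- setdiff(c("A", "C", "G", "T"), b)
    alt[sample.int(length(alt), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

# ----------------------------------------------------------- genome

#' Generate a random quadripartite plastome
#'
#' Draws three random segments with independent bases at the configured G+C
#' target and assembles them via [assemblePlastome()], so the resulting
#' record satisfies the inverted-repeat invariant by construction.
#' Reproducible: identical seeds give identical sequences.
#'
#' @param config A [SimulationConfig-class].
#' @param seed Integer seed (mandatory).
#' @param id Record identifier.
#' @return A [PlastomeRecord-class].
#' @examples
#' cfg <- SimulationConfig(regionLengths = c(lsc = 400L, ir = 100L,
#'                                           ssc = 150L))
#' generatePlastome(cfg, seed = 1)
#' @export
generatePlastome <- function(config = SimulationConfig(), seed,
                             id = sprintf("sim_plastome_s%d", seed)) {
  stopifnot(is(config, "SimulationConfig"))
  rl <- config@regionLengths
  withSeed(seed, {
    lsc <- randomDna(rl["lsc"], config@gcTarget)
    ir <- randomDna(rl["ir"], config@gcTarget)
    ssc <- randomDna(rl["ssc"], config@gcTarget)
    assemblePlastome(lsc, ir, ssc, id = id)
  })
}

# ------------------------------------------------------------- divergence

# Sample n event anchor positions in [lo, hi] at least `spacing` apart from
# each other and from `avoid`, optionally weighted.  Candidates come from a
# generous weighted draw without replacement (exponential-key reservoir) and
# are accepted greedily in draw order, preserving the weighting.
sampleEventPositions <- function(n, lo, hi, spacing, weights = NULL,
                                 avoid = integer(0)) {
  if (n == 0L) return(integer(0))
  avail <- hi - lo + 1L
  if (avail < (n + length(avoid)) * spacing)
    stop("too many events for the sequence length", call. = FALSE)
  poolSize <- min(avail, max(8L * n, n + 100L))
  idx <- if (is.null(weights)) {
    sample.int(avail, poolSize)
  } else {
    order(stats::rexp(avail) / weights)[seq_len(poolSize)]
  }
  picked <- integer(0)
  blocked <- avoid - lo + 1L
  for (p in idx) {
    if (length(picked) == n) break
    if (all(abs(p - picked) >= spacing) &&
        (length(blocked) == 0L || all(abs(p - blocked) >= spacing)))
      picked <- c(picked, p)
  }
  if (length(picked) < n)
    stop("could not place ", n, " events with spacing ", spacing,
         call. = FALSE)
  sort(picked) + lo - 1L
}

# Apply a list of events (data.frame pos/type/length/alt) to a character
# vector; events must be non-overlapping.  Returns the mutated vector.
applyEvents <- function(ch, events) {
  if (nrow(events) == 0L) return(ch)
  events <- events[order(events$pos, decreasing = TRUE), , drop = FALSE]
  for (e in seq_len(nrow(events))) {
    p <- events$pos[e]
    switch(events$type[e],
           sub = { ch[p] <- events$alt[e] },
           del = { ch <- ch[-(p:(p + events$length[e] - 1L))] },
           ins = { ch <- append(ch, s2c(events$alt[e]), after = p) })
  }
  ch
}

#' Plant divergence between a genome and a simulated relative
#'
#' Introduces substitutions and short (1--`maxIndelLen` bp) indels so that
#' the expected mismatched-base count per reference bp equals `rate` and the
#' expected composition (substituted / deleted / inserted bases) equals
#' `mix`.  When the record carries a region map, mutations are applied to
#' LSC, IRb and SSC only and the IRb changes are mirrored into IRa by
#' reconstruction, preserving the exact IR identity (plastome IRs evolve in
#' concert through biased gene conversion).  Event anchors keep a minimum
#' spacing so planted events never merge.
#'
#' @param record A [PlastomeRecord-class].
#' @param rate Expected mismatched bases per bp of the IR_A-stripped
#'   reference (defaults from `config`).
#' @param mix Length-3 fractions (substitution, deletion, insertion bases).
#' @param config A [SimulationConfig-class] supplying defaults.
#' @param seed Integer seed.
#' @return A list with `record` (the diverged [PlastomeRecord-class]),
#'   `truth` (data frame `pos`, `type`, `length`, `ref`, `alt`, 1-based
#'   positions on the original IR_A-stripped reference), and `refLen`.
#' @seealso [writeTruthVcf()] to serialize `truth` as VCF.
#' @export
applyDivergence <- function(record, rate = NULL, mix = NULL,
                            config = SimulationConfig(), seed) {
  stopifnot(is(record, "PlastomeRecord"))
  if (is.null(rate)) rate <- config@divergenceRate
  if (is.null(mix)) mix <- config@divergenceMix
  if (abs(sum(mix) - 1) > 1e-9)
    stop("divergence mix must sum to 1", call. = FALSE)
  probs <- truncGeomProbs(config@indelMeanLen, config@maxIndelLen)
  EL <- sum(seq_along(probs) * probs)
  hasRegions <- !is.null(record@regions)
  s <- plastomeSequence(record)
  L <- if (hasRegions) end(regionRange(record, "SSC")) else nchar(s)
  M <- rate * L
  nSub <- round(M * mix[1L])
  nDel <- round(M * mix[2L] / EL)
  nIns <- round(M * mix[3L] / EL)
  nTot <- nSub + nDel + nIns
  if (nTot == 0L) {
    return(list(record = record,
                truth = data.frame(pos = integer(), type = character(),
                                   length = integer(), ref = character(),
                                   alt = character()),
                refLen = L))
  }
  withSeed(seed, {
    spacing <- 2L * config@maxIndelLen + 2L
    pos <- sampleEventPositions(nTot, 2L, L - config@maxIndelLen - 1L,
                                spacing)
    # keep events clear of region boundaries so IR mirroring stays exact
    if (hasRegions) {
      bnd <- c(end(regionRange(record, "LSC")),
               end(regionRange(record, "IRB")))
      clear <- vapply(pos, function(p)
        all(abs(p - bnd) > config@maxIndelLen + 1L), logical(1))
      pos <- pos[clear]
    }
    type <- sample(rep(c("sub", "del", "ins"),
                       times = c(nSub, nDel, nIns))[seq_len(nTot)])
    type <- type[seq_along(pos)]
    len <- ifelse(type == "sub", 1L, sampleIndelLengths(length(pos), probs))
    ch <- s2c(substr(s, 1L, L))
    refBase <- vapply(seq_along(pos), function(i)
      paste(ch[pos[i]:(pos[i] + ifelse(type[i] == "del", len[i] - 1L, 0L))],
            collapse = ""), character(1))
    alt <- character(length(pos))
    alt[type == "sub"] <- substituteBases(refBase[type == "sub"])
    alt[type == "ins"] <- vapply(len[type == "ins"], randomDna, character(1))
    alt[type == "del"] <- ""
    truth <- data.frame(pos = pos, type = type, length = as.integer(len),
                        ref = refBase, alt = alt)
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
    mutated <- applyEvents(ch, truth)
    if (hasRegions) {
      w <- regionWidths(record)
      delta <- function(region, lim) {
        inR <- truth$pos >= lim[1L] & truth$pos <= lim[2L]
        sum(ifelse(truth$type[inR] == "ins", truth$length[inR],
                   ifelse(truth$type[inR] == "del", -truth$length[inR], 0L)))
      }
      rr <- regionMap(record)@ranges
      wNew <- w[1:3] + c(
        delta("LSC", c(start(rr)[1L], end(rr)[1L])),
        delta("IRB", c(start(rr)[2L], end(rr)[2L])),
        delta("SSC", c(start(rr)[3L], end(rr)[3L])))
      irbNew <- paste(mutated[(wNew[1L] + 1L):(wNew[1L] + wNew[2L])],
                      collapse = "")
      newSeq <- paste0(paste(mutated, collapse = ""), revComp(irbNew))
      rec <- PlastomeRecord(paste0(record@id, "_div"), newSeq,
                            regions = RegionMap(wNew[1L], wNew[2L],
                                                wNew[3L]))
    } else {
      rec <- PlastomeRecord(paste0(record@id, "_div"),
                            paste(mutated, collapse = ""))
    }
    list(record = rec, truth = truth, refLen = L)
  })
}

#' Write a planted-truth variant table as VCF
#'
#' Serializes the `truth` component of [applyDivergence()] (or any data
#' frame with the same columns) as a minimal VCF 4.2 file against the
#' original reference, using the conventional left-anchored representation
#' for indels.
#'
#' @param truth Data frame with columns `pos`, `type`, `length`, `ref`,
#'   `alt`.
#' @param refSeq The original (IR_A-stripped) reference as a character
#'   string.
#' @param path Output path.
#' @param chrom Contig name.
#' @return `path`, invisibly.
#' @export
writeTruthVcf <- function(truth, refSeq, path, chrom = "plastome") {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", chrom, nchar(refSeq)),
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"))
  if (nrow(truth) > 0L) {
    recs <- vapply(seq_len(nrow(truth)), function(i) {
      p <- truth$pos[i]
      switch(truth$type[i],
             sub = sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", chrom, p,
                           truth$ref[i], truth$alt[i]),
             del = {
               anchor <- substr(refSeq, p - 1L, p - 1L)
               sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", chrom, p - 1L,
                       paste0(anchor, truth$ref[i]), anchor)
             },
             ins = {
               anchor <- substr(refSeq, p, p)
               sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", chrom, p,
                       anchor, paste0(anchor, truth$alt[i]))
             })
    }, character(1))
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

# ------------------------------------------------------------- corruption

#' Calibrate the homopolymer deletion bias
#'
#' Under the corruption model, a deletion event anchors at position `i` with
#' weight `hpBias^(runLength(i) - 1)`.  This solves for the bias that makes
#' the expected fraction of deletion anchors falling inside homopolymer runs
#' of at least `minHpLen` bp equal `targetFraction`, given the actual
#' run-length spectrum of `sequence`.
#'
#' @param sequence DNA character string.
#' @param targetFraction Target in-homopolymer anchor fraction.
#' @param minHpLen Minimum run length defining a homopolymer (default 5).
#' @return The calibrated bias (a multiplier per extra run base).
#' @export
calibrateHpBias <- function(sequence, targetFraction = 0.80, minHpLen = 5L) {
  runLen <- positionRunLengths(sequence)
  inHp <- runLen >= minHpLen
  if (!any(inHp))
    stop("sequence has no homopolymer runs >= ", minHpLen,
         " bp; cannot calibrate", call. = FALSE)
  frac <- function(b) {
    w <- b^(pmin(runLen, 12L) - 1L)
    sum(w[inHp]) / sum(w)
  }
  if (frac(1) >= targetFraction) return(1)
  uniroot(function(b) frac(b) - targetFraction, c(1, 1e6), tol = 1e-9)$root
}

# Length of the maximal single-base run containing each position (N runs
# get length 1 so they never attract homopolymer bias).
positionRunLengths <- function(sequence) {
  rl <- rle(s2c(sequence))
  len <- rep.int(rl$lengths, rl$lengths)
  isN <- rep.int(rl$values == "N", rl$lengths)
  len[isN] <- 1L
  len
}

#' Corrupt a consensus with a Nanopore-style error process
#'
#' Plants substitution, deletion and insertion errors whose expected
#' per-base rate and composition match the configured error model.  Deletion
#' events anchor preferentially inside homopolymer runs: the anchor weight
#' of a position is `hpBias^(runLength - 1)`, with `hpBias` calibrated
#' automatically (see [calibrateHpBias()]) when the config leaves it `NA`.
#' Substitutions are uniform over the three alternative bases (no A/T
#' enrichment); inserted bases are drawn uniformly.  The returned truth
#' records every event with its homopolymer flag.
#'
#' @param x A [PlastomeRecord-class] or DNA character string.
#' @param config A [SimulationConfig-class]; `errorRate`, `errorMix`,
#'   `hpBias`, `hpTargetFraction` and the indel length model are taken from
#'   it unless overridden.
#' @param rate,mix Optional overrides of `errorRate` / `errorMix`.
#' @param minHpLen Run length defining homopolymer context (default 5).
#' @param seed Integer seed.
#' @return A list with `sequence` (corrupted), `truth` (data frame `pos`,
#'   `type`, `length`, `ref`, `alt`, `inHp`), `hpBias` (the bias used) and
#'   `refLen`.
#' @export
corruptConsensus <- function(x, config = SimulationConfig(), rate = NULL,
                             mix = NULL, minHpLen = 5L, seed) {
  if (is(x, "PlastomeRecord")) x <- plastomeSequence(x)
  checkDna(x, "sequence")
  if (is.null(rate)) rate <- config@errorRate
  if (is.null(mix)) mix <- config@errorMix
  probs <- truncGeomProbs(config@indelMeanLen, config@maxIndelLen)
  EL <- sum(seq_along(probs) * probs)
  L <- nchar(x)
  runLen <- positionRunLengths(x)
  hpBias <- config@hpBias
  if (is.na(hpBias))
    hpBias <- calibrateHpBias(x, config@hpTargetFraction, minHpLen)
  w <- hpBias^(pmin(runLen, 12L) - 1L)
  runs <- findHomopolymerRuns(x, minHpLen)
  withSeed(seed, {
    nSub <- round(L * rate * mix[1L])
    nDel <- round(L * rate * mix[2L] / EL)
    nIns <- round(L * rate * mix[3L] / EL)
    spacing <- 2L * config@maxIndelLen + 2L
    lo <- 2L
    hi <- L - config@maxIndelLen - 1L
    # expected share of deletion anchors inside runs >= minHpLen under the
    # per-base weight field; anchors are planted to meet it (one run can
    # host at most one anchor once spacing is enforced, so naive weighted
    # sampling would systematically under-fill the runs)
    inHp <- runLen >= minHpLen
    fracExp <- sum(w[inHp]) / sum(w)
    nHpDel <- round(nDel * fracExp)
    posHp <- integer(0)
    if (nHpDel > 0L) {
      if (nrow(runs) < nHpDel)
        stop("only ", nrow(runs), " homopolymer runs >= ", minHpLen,
             " bp for ", nHpDel, " in-run deletion events; sequence too ",
             "short for this error rate", call. = FALSE)
      runW <- runs$length * hpBias^(pmin(runs$length, 12L) - 1L)
      nDraw <- min(nrow(runs), nHpDel + 25L)
      pick <- sample.int(nrow(runs), nDraw, prob = runW)
      cand <- runs$start[pick] +
        floor(runif(nDraw) * runs$length[pick])
      cand <- pmin(pmax(cand, lo), hi)
      for (p in cand) {
        if (length(posHp) == nHpDel) break
        if (all(abs(p - posHp) >= spacing)) posHp <- c(posHp, p)
      }
      if (length(posHp) < nHpDel)
        stop("could not place ", nHpDel, " in-run deletion events",
             call. = FALSE)
    }
    wOut <- w[lo:hi]
    wOut[inHp[lo:hi]] <- 0
    posDel <- sort(c(posHp,
                     sampleEventPositions(nDel - nHpDel, lo, hi, spacing,
                                          weights = wOut, avoid = posHp)))
    others <- sampleEventPositions(nSub + nIns, lo, hi, spacing,
                                   avoid = posDel)
    isSub <- seq_along(others) %in% sample.int(length(others),
                                               min(nSub, length(others)))
    posSub <- others[isSub]
    posIns <- others[!isSub]
    ch <- s2c(x)
    mk <- function(pos, type) {
      if (length(pos) == 0L)
        return(data.frame(pos = integer(), type = character(),
                          length = integer(), ref = character(),
                          alt = character(), inHp = logical()))
      len <- if (type == "sub") rep(1L, length(pos))
             else sampleIndelLengths(length(pos), probs)
      refB <- vapply(seq_along(pos), function(i)
        paste(ch[pos[i]:(pos[i] + ifelse(type == "del", len[i] - 1L, 0L))],
              collapse = ""), character(1))
      alt <- switch(type,
                    sub = substituteBases(refB),
                    del = rep("", length(pos)),
                    ins = vapply(len, randomDna, character(1)))
      inHp <- if (type == "del") {
        vapply(seq_along(pos), function(i) {
          lo2 <- pos[i]
          hi2 <- pos[i] + len[i] - 1L
          b <- unique(s2c(refB[i]))
          (nrow(runs) > 0L &&
             any(runs$start <= hi2 & runs$end >= lo2)) ||
            (length(b) == 1L && nrow(runs) > 0L &&
               any(runs$base == b &
                     (runs$end == lo2 - 1L | runs$start == hi2 + 1L)))
        }, logical(1))
      } else if (type == "ins") {
        vapply(seq_along(pos), function(i) {
          b <- unique(s2c(alt[i]))
          length(b) == 1L && nrow(runs) > 0L &&
            any(runs$base == b & runs$start <= pos[i] + 1L &
                  runs$end >= pos[i])
        }, logical(1))
      } else rep(FALSE, length(pos))
      data.frame(pos = pos, type = type, length = as.integer(len),
                 ref = refB, alt = alt, inHp = inHp)
    }
    truth <- rbind(mk(posSub, "sub"), mk(posDel, "del"), mk(posIns, "ins"))
    truth <- truth[order(truth$pos), , drop = FALSE]
    rownames(truth) <- NULL
    mutated <- applyEvents(ch, truth)
    list(sequence = paste(mutated, collapse = ""), truth = truth,
         hpBias = hpBias, refLen = L)
  })
}

# ---------------------------------------------------------- amplicon panel

#' Simulate a long-range-PCR amplicon panel
#'
#' Tiles the genome with `ampliconCount` overlapping fragments whose lengths
#' fall in `ampliconLengthRange` and whose consecutive overlaps are at least
#' `minOverlap` bp, except for one declared sequence gap after fragment
#' `panelGapAfter` (mirroring a panel whose one primer was reused between
#' neighbouring fragments).  Alternatively pass explicit `intervals`.
#'
#' @param record A [PlastomeRecord-class].
#' @param config A [SimulationConfig-class] with the panel geometry.
#' @param intervals Optional data frame `start`, `end` of explicit amplicon
#'   intervals (overrides the automatic tiling).
#' @param seed Integer seed (required for automatic tiling).
#' @return A data frame with columns `index`, `start`, `end`, `length`,
#'   `sequence`.
#' @export
simulateAmpliconPanel <- function(record, config = SimulationConfig(),
                                  intervals = NULL, seed = NULL) {
  stopifnot(is(record, "PlastomeRecord"))
  s <- plastomeSequence(record)
  L <- nchar(s)
  if (!is.null(intervals)) {
    stopifnot(all(intervals$start >= 1L), all(intervals$end <= L))
    out <- data.frame(index = seq_len(nrow(intervals)),
                      start = as.integer(intervals$start),
                      end = as.integer(intervals$end))
  } else {
    if (is.null(seed)) stop("seed is required for automatic tiling")
    n <- config@ampliconCount
    rng <- config@ampliconLengthRange
    out <- withSeed(seed, {
      ov <- round(runif(n - 1L, config@minOverlap, config@minOverlap + 327))
      if (config@panelGapAfter >= 1L && config@panelGapAfter < n)
        ov[config@panelGapAfter] <- -config@panelGapLength
      total <- L + sum(ov)
      if (total < n * rng[1L] || total > n * rng[2L])
        stop("amplicon panel cannot tile the genome: need total fragment ",
             "length ", total, " from ", n, " fragments in [", rng[1L],
             ", ", rng[2L], "]", call. = FALSE)
      raw <- runif(n, rng[1L], rng[2L])
      len <- round(raw * total / sum(raw))
      len <- pmin(pmax(len, rng[1L]), rng[2L])
      resid <- total - sum(len)
      i <- 1L
      while (resid != 0L) {
        step <- sign(resid)
        if ((step > 0 && len[i] < rng[2L]) || (step < 0 && len[i] > rng[1L])) {
          len[i] <- len[i] + step
          resid <- resid - step
        }
        i <- if (i == n) 1L else i + 1L
      }
      starts <- cumsum(c(1L, len[-n] - ov))
      data.frame(index = seq_len(n), start = as.integer(starts),
                 end = as.integer(starts + len - 1L))
    })
  }
  out$length <- out$end - out$start + 1L
  out$sequence <- substring(s, out$start, out$end)
  out
}

# --------------------------------------------------------------- read sets

# Per-base corruption of one read.
corruptRead <- function(s, rates) {
  ch <- s2c(s)
  L <- length(ch)
  if (L == 0L) return("")
  sub <- runif(L) < rates[["sub"]]
  if (any(sub)) ch[sub] <- substituteBases(ch[sub])
  del <- runif(L) < rates[["del"]]
  ins <- runif(L) < rates[["ins"]]
  add <- character(L)
  if (any(ins))
    add[ins] <- sample(c("A", "C", "G", "T"), sum(ins), replace = TRUE)
  ch[del] <- ""
  paste(paste0(ch, add), collapse = "")
}

#' Simulate a read set with palindromic chimeras
#'
#' Draws reads as error-bearing sub-fragments of the amplicons; a fraction
#' `chimeraRate` are palindromic chimeras of the form
#' `prefix + revcomp(prefix)` (each arm carries independent errors).  Every
#' read is truth-labelled.
#'
#' @param amplicons Data frame from [simulateAmpliconPanel()].
#' @param config A [SimulationConfig-class] (read length range, per-base
#'   error rates, chimera rate).
#' @param nReads Number of reads to simulate.
#' @param chimeraRate Override of the configured chimera fraction.
#' @param seed Integer seed.
#' @return A list with `reads` (data frame `id`, `sequence`) and `truth`
#'   (data frame `id`, `amplicon`, `start`, `armLength`, `palindromic`,
#'   `pivot`; `pivot` is the final-read position where the first arm ends,
#'   `NA` for normal reads).
#' @seealso [splitPalindromicRead()], [writeReadsFastq()]
#' @export
simulateReads <- function(amplicons, config = SimulationConfig(),
                          nReads = 1000L, chimeraRate = NULL, seed) {
  if (is.null(chimeraRate)) chimeraRate <- config@chimeraRate
  stopifnot(chimeraRate >= 0, chimeraRate <= 1)
  rng <- config@readLengthRange
  rates <- config@readErrorRates
  withSeed(seed, {
    ampIdx <- sample.int(nrow(amplicons), nReads, replace = TRUE)
    isPal <- runif(nReads) < chimeraRate
    seqs <- character(nReads)
    starts <- integer(nReads)
    armLen <- integer(nReads)
    pivot <- rep(NA_integer_, nReads)
    for (i in seq_len(nReads)) {
      amp <- amplicons$sequence[ampIdx[i]]
      ampLen <- nchar(amp)
      len <- min(round(runif(1, rng[1L], rng[2L])), ampLen)
      st <- sample.int(ampLen - len + 1L, 1L)
      frag <- substr(amp, st, st + len - 1L)
      starts[i] <- st
      armLen[i] <- len
      if (isPal[i]) {
        a1 <- corruptRead(frag, rates)
        a2 <- corruptRead(revComp(frag), rates)
        seqs[i] <- paste0(a1, a2)
        pivot[i] <- nchar(a1)
      } else {
        seqs[i] <- corruptRead(frag, rates)
      }
    }
    ids <- sprintf("read_%05d", seq_len(nReads))
    list(reads = data.frame(id = ids, sequence = seqs),
         truth = data.frame(id = ids, amplicon = ampIdx, start = starts,
                            armLength = armLen, palindromic = isPal,
                            pivot = pivot))
  })
}

#' Write simulated reads as FASTQ
#'
#' Qualities are a constant Phred score per base (default Q12, the modal
#' quality of the emulated long-read run).
#'
#' @param reads Data frame `id`, `sequence` (from [simulateReads()]).
#' @param path Output path.
#' @param quality Constant Phred quality.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path, quality = 12L) {
  qchar <- rawToChar(as.raw(33L + quality))
  dna <- DNAStringSet(reads$sequence)
  names(dna) <- reads$id
  q <- Biostrings::PhredQuality(
    vapply(nchar(reads$sequence), function(w) strrep(qchar, w),
           character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(dna, q)
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

# ---------------------------------------------------------- chimera split

#' Split a palindromic chimeric read
#'
#' Detects the pivot of a `prefix + revcomp(prefix)` chimera by voting:
#' every k-mer of the read matching a k-mer of its own reverse complement
#' implies a candidate pivot, and a genuine palindrome concentrates its
#' votes on one pivot.  The modal pivot is accepted when both arms reach
#' `minArm` bp and their normalized edit distance (arm 1 vs the reverse
#' complement of arm 2) is at most `maxArmDivergence`; the read is then
#' split into the two arms, the second reverse-complemented back to genome
#' orientation, and fragments shorter than 50 bp are discarded.  Otherwise
#' the read is returned unchanged.
#'
#' @param read DNA character string.
#' @param minArm Minimum arm length to accept a split (bp).
#' @param maxArmDivergence Maximum normalized arm edit distance.
#' @param k K-mer size for pivot voting.
#' @param minVotes Minimum concordant votes to consider a pivot.
#' @return A character vector of 1 or 2 fragments.
#' @examples
#' arm <- strrep("ACGGTTCAAG", 30)
#' splitPalindromicRead(paste0(arm, revComp(arm)))
#' @export
splitPalindromicRead <- function(read, minArm = 200L,
                                 maxArmDivergence = 0.25, k = 15L,
                                 minVotes = 3L) {
  checkDna(read, "read")
  n <- nchar(read)
  if (n < 2L * max(minArm, 50L)) return(read)
  p <- palindromePivot(read, k, minVotes)
  if (is.na(p)) return(read)
  a1 <- substr(read, 1L, p)
  a2 <- revComp(substr(read, p + 1L, n))
  if (nchar(a1) < minArm || nchar(a2) < minArm) return(read)
  d <- adist(a1, a2)[1L, 1L]
  if (d / max(nchar(a1), nchar(a2)) > maxArmDivergence) return(read)
  out <- c(a1, a2)
  out[nchar(out) >= 50L]
}

# Modal self-reverse-complement pivot of a read, or NA.
palindromePivot <- function(read, k, minVotes) {
  n <- nchar(read)
  if (n < 2L * k) return(NA_integer_)
  rc <- revComp(read)
  i <- seq_len(n - k + 1L)
  kF <- substring(read, i, i + k - 1L)
  kR <- substring(rc, i, i + k - 1L)
  uF <- !(duplicated(kF) | duplicated(kF, fromLast = TRUE))
  uR <- !(duplicated(kR) | duplicated(kR, fromLast = TRUE))
  m <- match(kF, kR)
  ok <- uF & !is.na(m) & uR[ifelse(is.na(m), 1L, m)]
  if (sum(ok) < minVotes) return(NA_integer_)
  # read[i..] == revcomp(read)[j..] implies a mirror centre near (i+n-j)/2
  piv <- round((i[ok] + n - i[m[ok]]) / 2)
  tab <- table(piv)
  best <- as.integer(names(tab)[which.max(tab)])
  votes <- sum(abs(piv - best) <= 2L)   # allow indel jitter around the mode
  if (votes < minVotes) return(NA_integer_)
  if (best < 1L || best >= n) return(NA_integer_)
  best
}

#' Split palindromic chimeras across a read set
#'
#' @param reads Data frame `id`, `sequence` (e.g. from [simulateReads()]).
#' @param ... Passed to [splitPalindromicRead()].
#' @return A list with `reads` (data frame `id`, `sequence` of the split
#'   output; split fragments carry `/1`, `/2` suffixes) and `info` (data
#'   frame `id`, `split`, `nFragments`).
#' @export
splitReads <- function(reads, ...) {
  pieces <- lapply(reads$sequence, splitPalindromicRead, ...)
  nf <- lengths(pieces)
  ids <- unlist(lapply(seq_along(pieces), function(i)
    if (nf[i] == 1L) reads$id[i]
    else paste0(reads$id[i], "/", seq_len(nf[i]))))
  list(reads = data.frame(id = ids,
                          sequence = unlist(pieces, use.names = FALSE)),
       info = data.frame(id = reads$id, split = nf > 1L, nFragments = nf))
}
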