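# Independent oracles used to cross-check the implementation.  These are
# deliberately written in the most literal way possible (single-pass loops,
# full dynamic-programming matrices) and share no code with the package
# internals they verify.

# Single-pass column-scan mismatch classifier.
naiveClassify <- function(refRow, qryRow) {
  r <- strsplit(refRow, "")[[1]]
  q <- strsplit(qryRow, "")[[1]]
  subs <- delB <- delE <- insB <- insE <- nPos <- 0L
  state <- "none"
  for (i in seq_along(r)) {
    if (r[i] != "-" && q[i] == "-") {
      delB <- delB + 1L
      if (state != "del") delE <- delE + 1L
      state <- "del"
    } else if (r[i] == "-" && q[i] != "-") {
      insB <- insB + 1L
      if (state != "ins") insE <- insE + 1L
      state <- "ins"
    } else {
      if (q[i] == "N") {
        nPos <- nPos + 1L
      } else if (r[i] != "N" && r[i] != q[i]) {
        subs <- subs + 1L
      }
      state <- "none"
    }
  }
  list(substitutions = subs, deletedBases = delB, deletionEvents = delE,
       insertedBases = insB, insertionEvents = insE, nPositions = nPos,
       mismatches = subs + delB + insB)
}

# Full-matrix affine-gap global alignment score (Gotoh), end gaps charged.
# Gap of length L costs gapOpen + L * gapExt.
gotohScore <- function(ref, qry, match = 1, mismatch = -2, gapOpen = 4,
                       gapExt = 1) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(qry, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in query (deletion)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in reference (insertion)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gapOpen + i * gapExt)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gapOpen + j * gapExt)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - gapOpen - gapExt,
                             X[i, j + 1] - gapExt,
                             Y[i, j + 1] - gapOpen - gapExt)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gapOpen - gapExt,
                             X[i + 1, j] - gapOpen - gapExt,
                             Y[i + 1, j] - gapExt)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Random gapped alignment (no double-gap columns) for property tests.
randomAlignment <- function(nCols = 80) {
  types <- sample(c("match", "sub", "del", "ins", "n"), nCols,
                  replace = TRUE, prob = c(0.6, 0.1, 0.12, 0.12, 0.06))
  bases <- c("A", "C", "G", "T")
  r <- q <- character(nCols)
  for (i in seq_len(nCols)) {
    b <- sample(bases, 1)
    if (types[i] == "match") {
      r[i] <- b; q[i] <- b
    } else if (types[i] == "sub") {
      r[i] <- b; q[i] <- sample(setdiff(bases, b), 1)
    } else if (types[i] == "del") {
      r[i] <- b; q[i] <- "-"
    } else if (types[i] == "ins") {
      r[i] <- "-"; q[i] <- b
    } else {
      r[i] <- b; q[i] <- "N"
    }
  }
  # keep the alignment reference-adjusted: base-base columns at both ends
  b1 <- sample(bases, 1); b2 <- sample(bases, 1)
  AlignedPair(paste(c(b1, r, b2), collapse = ""),
              paste(c(b1, q, b2), collapse = ""))
}

# Brute-force longest exact reverse-complement repeat pair with
# non-overlapping copies: for every first-copy start, grow the copy while
# its reverse complement still occurs downstream (plain string search).
rcOracle <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

bruteForceLongestIr <- function(seq, minLen) {
  n <- nchar(seq)
  best <- NULL
  for (s1 in seq_len(n - 2L * minLen + 1L)) {
    l <- minLen
    repeat {
      e1 <- s1 + l - 1L
      if (e1 + l > n) break
      pat <- rcOracle(substr(seq, s1, e1))
      hits <- gregexpr(pat, seq, fixed = TRUE)[[1]]
      hits <- hits[hits > e1]
      if (length(hits) == 0L) break
      if (is.null(best) || l > best$len)
        best <- list(s1 = s1, e1 = e1, s2 = hits[1L],
                     e2 = hits[1L] + l - 1L, len = l)
      l <- l + 1L
    }
  }
  best
}

# Small quadripartite config so structural tests stay fast.
smallConfig <- function(...) {
  SimulationConfig(regionLengths = c(lsc = 6000L, ir = 1500L, ssc = 1200L),
                   ...)
}

# Matching amplicon panel geometry for the small genome (10,200 bp).
smallPanelConfig <- function(...) {
  smallConfig(ampliconCount = 4L, ampliconLengthRange = c(2500L, 4000L),
              minOverlap = 100L, panelGapAfter = 2L, panelGapLength = 50L,
              ...)
}
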