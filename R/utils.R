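# Small shared helpers.  All sequence strings handled here are plain upper-case
# character scalars over {A,C,G,T,N}; gapped alignment rows additionally use '-'.

#' Reverse complement of a DNA string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param x A DNA sequence as a single character string over `A,C,G,T,N`.
#' @return The reverse complement, as a character string.
#' @examples
#' revComp("ACGTN")
#' @export
revComp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Validate a DNA string; errors name the first offending position.
checkDna <- function(x, what = "sequence", allowEmpty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string", call. = FALSE)
  if (!allowEmpty && nchar(x) == 0L)
    stop(what, " must be non-empty", call. = FALSE)
  bad <- regexpr("[^ACGTN]", x)
  if (bad != -1L)
    stop(what, " contains non-DNA character '", substr(x, bad, bad),
         "' at position ", as.integer(bad), call. = FALSE)
  invisible(x)
}

# Round half away from zero (printed tables use commercial rounding, while
# base round() rounds halves to even).
roundHalfUp <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards, so simulations are pure functions of (inputs, seed).
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Random DNA string of length n with independent bases at a target G+C
# fraction (G and C equiprobable, likewise A and T).
randomDna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Split a scalar string into a character vector of single characters.
s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
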