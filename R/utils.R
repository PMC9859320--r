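#' @importFrom methods new validObject is slot
#' @importFrom stats weighted.mean rbinom runif
#' @importFrom utils read.delim write.table head
NULL

## Sequence string helpers. Monomers and reads are handled as plain upper-case
## character strings internally; Biostrings containers at the interfaces.

.BASES <- c("A", "C", "G", "T")

#' Validate and normalize a DNA sequence string
#'
#' Upcases the input and checks its alphabet. Consensus monomers must be pure
#' A/C/G/T; reads may additionally contain N.
#'
#' @param x character(1) or an object coercible via `as.character()`.
#' @param allowN logical(1), permit ambiguous N characters.
#' @param what label used in error messages.
#' @return The validated upper-case string.
#' @keywords internal
.checkSeq <- function(x, allowN = FALSE, what = "sequence") {
  x <- toupper(as.character(x))
  if (length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop("invalid ", what, ": empty sequence", call. = FALSE)
  alphabet <- if (allowN) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), x))
    stop("invalid ", what, ": characters outside {", paste(strsplit(alphabet, "")[[1]], collapse = ","),
         "}", call. = FALSE)
  x
}

## reverse complement on plain strings (vectorized)
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## all rotations of a single string
.rotations <- function(x) {
  n <- nchar(x)
  if (n == 1L) return(x)
  vapply(seq_len(n), function(i) paste0(substr(x, i, n), substr(x, 1L, i - 1L)), character(1))
}

#' Canonical form of a circular monomer
#'
#' The lexicographically smallest rotation of the strand whose smallest
#' rotation is smaller, so that any rotation of either strand of the same
#' monomer maps to one representative. Used for stable naming and for
#' collapsing mirror-image discoveries.
#'
#' @param x character vector of monomer sequences.
#' @return character vector of canonical monomers.
#' @export
canonicalMonomer <- function(x) {
  vapply(x, function(s) {
    s <- .checkSeq(s, allowN = FALSE, what = "monomer")
    fwd <- min(.rotations(s))
    rev <- min(.rotations(.revcomp(s)))
    if (fwd <= rev) fwd else rev
  }, character(1), USE.NAMES = FALSE)
}

## deterministic sub-seed derived from a master seed and a stream index;
## kept below 2^31 - 1
.subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483647)
}

## run code under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

## random DNA string(s): n sequences of length len at given GC content
.randomSeq <- function(n, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(.BASES, len, replace = TRUE, prob = p), collapse = ""), character(1))
}

## hamming identity (percent) between equal-length strings
.hammingIdentity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  100 * sum(av == bv) / length(av)
}
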