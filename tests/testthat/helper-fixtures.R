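## shared helpers: random sequences, catalogs, and independent oracles

randSeq <- function(n, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
          collapse = ""), character(1))
}

rcStr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

rotStr <- function(x, k) {
  n <- nchar(x)
  k <- ((k - 1) %% n) + 1
  if (k == n) x else paste0(substr(x, k + 1, n), substr(x, 1, k))
}

substituteBases <- function(x, positions) {
  v <- strsplit(x, "")[[1]]
  for (p in positions) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

randomCatalog <- function(nFam, abbrev = "Tst", rulRange = c(6L, 40L)) {
  lens <- sample(rulRange[1]:rulRange[2], nFam, replace = TRUE)
  seqs <- vapply(lens, function(L) randSeq(1, L), character(1))
  while (anyDuplicated(seqs)) {
    dup <- which(duplicated(seqs))
    seqs[dup] <- vapply(lens[dup], function(L) randSeq(1, L), character(1))
  }
  assignNames(seqs, round(stats::runif(nFam, 1e-5, 1e-2), 8), abbrev,
              divergence = round(stats::runif(nFam, 0, 30), 4))
}

## independent oracle for rotation/strand-invariant similarity: plain global
## alignment against every explicit rotation of either strand, identity =
## matches / all alignment columns (terminal gaps included); same scoring
## constants as the package's homology convention
bruteRotSim <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  rots <- vapply(seq_len(nchar(b)), function(i) rotStr(b, i), character(1))
  cands <- c(rots, rcStr(rots))
  max(vapply(cands, function(x) {
    aln <- Biostrings::pairwiseAlignment(
      a, x, type = "global", substitutionMatrix = mat,
      gapOpening = 5, gapExtension = 3)
    100 * Biostrings::nmatch(aln) /
      nchar(as.character(Biostrings::alignedPattern(aln)))
  }, numeric(1)))
}

## read sample of error-free tandem-array reads from one monomer
arrayReads <- function(monomer, copies, coverage = 5, readLength = 101,
                       errorRate = 0, seed = 1) {
  arr <- strrep(monomer, copies)
  simulateReads(arr, coverage = coverage, readLength = readLength,
                errorRate = errorRate, seed = seed)
}
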