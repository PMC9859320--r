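## Alignment core shared by read filtering, read mapping and monomer
## homology. Scoring constants: match +1, mismatch -1, gap open -2,
## gap extend -1; identity = matches / alignment columns including internal
## gaps (Biostrings PID1).

.SEED_LEN <- 12L

.subMat <- local({
  mat <- NULL
  function() {
    if (is.null(mat))
      mat <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE)
    mat
  }
})

#' Concatenate copies of a monomer
#'
#' Tandem repeats are circular: a read or monomer may start anywhere in the
#' repeat unit, so alignments are computed against a head-to-tail
#' concatenation of the monomer ("dimerization"). At least `copies` copies
#' are used, and more if needed to reach `minLength`, so that short monomers
#' still present an alignable target.
#'
#' @param seq monomer sequence (character).
#' @param copies minimum number of copies (default 2).
#' @param minLength minimum total length of the multimer (default 0).
#' @return character(1) concatenated multimer.
#' @export
dimerize <- function(seq, copies = 2L, minLength = 0L) {
  seq <- .checkSeq(seq, what = "monomer")
  n <- max(copies, ceiling(minLength / nchar(seq)))
  paste(rep(seq, n), collapse = "")
}

## all k-mers of each string in x; returns data.table(idx, kmer)
.kmerTable <- function(x, k = .SEED_LEN) {
  n <- nchar(x)
  maxn <- max(n)
  if (maxn < k) return(data.table::data.table(idx = integer(0),
                                              kmer = character(0)))
  pieces <- vector("list", maxn - k + 1L)
  for (i in seq_len(maxn - k + 1L)) {
    ok <- n >= i + k - 1L
    pieces[[i]] <- data.table::data.table(
      idx = which(ok), kmer = substr(x[ok], i, i + k - 1L))
  }
  data.table::rbindlist(pieces)
}

## indices of reads sharing at least one exact k-mer (either strand) with
## the subject sequence
.seedCandidates <- function(readsChr, subjectChr, k = .SEED_LEN) {
  if (nchar(subjectChr) < k) return(seq_along(readsChr))
  subjKmers <- unique(c(.kmerTable(subjectChr, k)$kmer,
                        .kmerTable(.revcomp(subjectChr), k)$kmer))
  rk <- .kmerTable(readsChr, k)
  unique(rk$idx[rk$kmer %chin% subjKmers])
}

## align a set of reads (both strands) against one subject; returns a
## data.frame with one row per read: best-strand score, identity (PID1),
## readBases (read bases consumed) and mismatches
.alignToSubject <- function(readSet, subjectChr, type = "local") {
  subject <- Biostrings::DNAString(subjectChr)
  stats <- function(p) {
    aln <- Biostrings::pairwiseAlignment(
      p, subject, type = type, substitutionMatrix = .subMat(),
      gapOpening = 2, gapExtension = 1)
    pat <- Biostrings::pattern(aln)
    data.frame(score = Biostrings::score(aln),
               identity = Biostrings::pid(aln, type = "PID1"),
               readBases = BiocGenerics::end(pat) -
                 BiocGenerics::start(pat) + 1L,
               mismatches = Biostrings::nmismatch(aln))
  }
  fwd <- stats(readSet)
  rev <- stats(Biostrings::reverseComplement(readSet))
  take <- rev$score > fwd$score
  fwd[take, ] <- rev[take, ]
  fwd$strand <- ifelse(take, "-", "+")
  fwd
}

## Polish a candidate monomer by majority vote: reads sharing a seed with
## the dimerized candidate are aligned to it (both strands, best kept) and
## each monomer position takes the majority base over the aligned columns.
## Iterates until fixed point or maxRounds. Substitution errors introduced
## by graph traversal are corrected; the monomer length is left unchanged.
.polishConsensus <- function(mono, sample, maxRounds = 2L, maxReads = 300L) {
  readsChr <- as.character(reads(sample))
  names(readsChr) <- NULL
  rl <- if (!is.na(sample@readLength)) sample@readLength else
    max(nchar(readsChr))
  for (round in seq_len(maxRounds)) {
    m <- nchar(mono)
    subj <- dimerize(mono, copies = 2L, minLength = rl + m)
    cand <- .seedCandidates(readsChr, subj)
    cand <- cand[!grepl("N", readsChr[cand], fixed = TRUE)]
    if (!length(cand)) return(mono)
    if (length(cand) > maxReads) cand <- cand[seq_len(maxReads)]
    readSet <- Biostrings::DNAStringSet(readsChr[cand])
    alnOf <- function(p) Biostrings::pairwiseAlignment(
      p, Biostrings::DNAString(subj), type = "local",
      substitutionMatrix = .subMat(), gapOpening = 2, gapExtension = 1)
    alnF <- alnOf(readSet)
    alnR <- alnOf(Biostrings::reverseComplement(readSet))
    votes <- matrix(0L, nrow = 4L, ncol = m, dimnames = list(.BASES, NULL))
    for (i in seq_along(cand)) {
      aln <- if (Biostrings::score(alnR)[i] > Biostrings::score(alnF)[i])
        alnR[i] else alnF[i]
      p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      pos <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
      for (j in seq_along(s)) {
        if (s[j] == "-") next
        pos <- pos + 1L
        if (p[j] %in% .BASES)
          votes[p[j], ((pos - 1L) %% m) + 1L] <-
            votes[p[j], ((pos - 1L) %% m) + 1L] + 1L
      }
    }
    cur <- strsplit(mono, "")[[1]]
    new <- vapply(seq_len(m), function(i) {
      w <- votes[, i]
      if (max(w) == 0L) return(cur[i])
      top <- .BASES[w == max(w)]
      if (cur[i] %in% top) cur[i] else top[1]  # ties keep the current base
    }, character(1))
    newMono <- paste(new, collapse = "")
    if (newMono == mono) return(mono)
    mono <- newMono
  }
  mono
}

## Align reads against every family of a catalog; subjects are monomers
## multimerized to >= readLength + rul so that any read position in an array
## is fully alignable. With prefilter = TRUE only reads sharing an exact
## 12-mer seed with a family's multimer (either strand) are aligned to it --
## reads below ~80% identity essentially never carry such a seed by chance.
## Returns data.table(read, family, score, identity, readBases, mismatches).
.alignReadsToFamilies <- function(sample, familySeqs, prefilter = TRUE,
                                  chunkSize = 50000L) {
  readSet <- reads(sample)
  readsChr <- as.character(readSet)
  names(readsChr) <- NULL
  rl <- if (!is.na(sample@readLength)) sample@readLength else
    max(Biostrings::width(readSet))
  hasN <- grepl("N", readsChr, fixed = TRUE)
  subjects <- vapply(familySeqs, function(mono)
    dimerize(mono, copies = 2L, minLength = rl + nchar(mono)), character(1))
  nfam <- length(familySeqs)
  if (prefilter) {
    ## the read k-mer table is built once per chunk and probed by every
    ## family, keeping memory flat for large mapping samples
    famK <- lapply(subjects, function(s)
      unique(c(.kmerTable(s, .SEED_LEN)$kmer,
               .kmerTable(.revcomp(s), .SEED_LEN)$kmer)))
    candList <- rep(list(integer(0)), nfam)
    starts <- seq(1L, length(readsChr), by = chunkSize)
    for (b in starts) {
      block <- b:min(b + chunkSize - 1L, length(readsChr))
      rk <- .kmerTable(readsChr[block], .SEED_LEN)
      for (j in seq_len(nfam)) {
        idx <- unique(rk$idx[rk$kmer %chin% famK[[j]]])
        candList[[j]] <- c(candList[[j]], block[idx])
      }
    }
  } else {
    candList <- rep(list(seq_along(readsChr)), nfam)
  }
  out <- vector("list", nfam)
  for (j in seq_len(nfam)) {
    cand <- setdiff(candList[[j]], which(hasN))
    if (!length(cand)) { out[[j]] <- NULL; next }
    st <- .alignToSubject(readSet[cand], subjects[[j]], type = "local")
    out[[j]] <- data.table::data.table(
      read = cand, family = names(familySeqs)[j], score = st$score,
      identity = st$identity, readBases = st$readBases,
      mismatches = st$mismatches)
  }
  res <- data.table::rbindlist(out)
  if (!nrow(res))
    res <- data.table::data.table(read = integer(0), family = character(0),
                                  score = numeric(0), identity = numeric(0),
                                  readBases = integer(0),
                                  mismatches = integer(0))
  res
}
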