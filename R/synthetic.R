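#' Specification of one planted satDNA family
#'
#' Describes a tandem-repeat family to plant in a synthetic genome: monomer
#' length, the genome fraction its arrays should occupy, the expected
#' per-copy substitution divergence of array copies from the species-level
#' consensus, a per-base single-base indel rate for copies, and the number
#' of separate array loci.
#'
#' Defaults emulate the ranges observed in published fish satellitomes:
#' monomer lengths from 6 bp up to a few kb and genome fractions between
#' roughly 1e-4 and 1e-2.
#'
#' @param monomerLength integer(1) >= 6, monomer length in bp.
#' @param targetGenomeFraction numeric(1) in (0, 1).
#' @param intraArrayDivergence numeric(1), expected percent substitution
#'   distance of each copy from the species consensus (default 5).
#' @param indelRate numeric(1), per-base probability of a single-base indel
#'   in each copy (default 0).
#' @param nArrays integer(1), number of separate loci (default 1).
#' @return A list of class `"PlantedFamilySpec"`.
#' @export
plantedFamilySpec <- function(monomerLength, targetGenomeFraction,
                              intraArrayDivergence = 5, indelRate = 0,
                              nArrays = 1L) {
  stopifnot(monomerLength >= 6, targetGenomeFraction > 0,
            targetGenomeFraction < 1, intraArrayDivergence >= 0,
            indelRate >= 0, nArrays >= 1)
  structure(list(monomerLength = as.integer(monomerLength),
                 targetGenomeFraction = targetGenomeFraction,
                 intraArrayDivergence = intraArrayDivergence,
                 indelRate = indelRate, nArrays = as.integer(nArrays)),
            class = "PlantedFamilySpec")
}

#' Specification of a diverged species pair sharing a satDNA library
#'
#' Encodes the library-hypothesis setup used for validation: an ancestral
#' set of satDNA families is inherited by two descendant species; each
#' species' consensus then diverges independently from the ancestor by
#' `crossSpeciesDivergence` percent substitutions, and each species may in
#' addition carry private families absent from the other.
#'
#' @param genomeLength integer(1), haploid genome length in bp.
#' @param sharedLibrary list of [plantedFamilySpec()] shared by both species.
#' @param crossSpeciesDivergence numeric(1) >= 0, percent substitution
#'   applied independently to each descendant consensus. With per-base rate
#'   d the expected pairwise consensus identity is about
#'   100 * ((1-d)^2 + d^2/3 + 2*d*(1-d)*0), i.e. ~ 100 - 2*d*100*(1 - 2d/3)
#'   for small d.
#' @param privateA,privateB per-species lists of [plantedFamilySpec()].
#' @param gcBackground numeric(1) in (0, 1), GC content of the i.i.d.
#'   background sequence (default 0.5).
#' @param seed integer(1) RNG seed; output is deterministic given the seed.
#' @return A list of class `"SpeciesPairSpec"`.
#' @export
speciesPairSpec <- function(genomeLength, sharedLibrary = list(),
                            crossSpeciesDivergence = 5,
                            privateA = list(), privateB = list(),
                            gcBackground = 0.5, seed = 1L) {
  stopifnot(genomeLength > 0, crossSpeciesDivergence >= 0,
            gcBackground > 0, gcBackground < 1)
  allFracs <- vapply(c(sharedLibrary, privateA, privateB),
                     function(s) s$targetGenomeFraction, numeric(1))
  if (length(allFracs) && sum(allFracs) >= 1)
    stop("planted genome fractions must sum to < 1")
  structure(list(genomeLength = as.integer(genomeLength),
                 sharedLibrary = sharedLibrary,
                 crossSpeciesDivergence = crossSpeciesDivergence,
                 privateA = privateA, privateB = privateB,
                 gcBackground = gcBackground, seed = as.integer(seed)),
            class = "SpeciesPairSpec")
}

## substitute each base independently with probability rate (to one of the
## three alternatives); optional single-base indels at indelRate
.mutateSeq <- function(seq, subRate, indelRate = 0) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  hit <- which(runif(n) < subRate)
  if (length(hit)) {
    repl <- vapply(v[hit], function(b) sample(setdiff(.BASES, b), 1L),
                   character(1), USE.NAMES = FALSE)
    v[hit] <- repl
  }
  if (indelRate > 0) {
    ind <- which(runif(n) < indelRate)
    if (length(ind)) {
      del <- runif(length(ind)) < 0.5
      keep <- rep(TRUE, n)
      keep[ind[del]] <- FALSE
      ins <- ind[!del]
      out <- character(0)
      last <- 0L
      for (i in seq_len(n)) {
        if (keep[i]) out <- c(out, v[i])
        if (i %in% ins) out <- c(out, sample(.BASES, 1L))
      }
      v <- out
    }
  }
  paste(v, collapse = "")
}

## build the tandem arrays for one family from a species consensus
.buildArrays <- function(consensus, fam, genomeLength) {
  totalCopies <- max(1L, round(fam$targetGenomeFraction * genomeLength /
                                 fam$monomerLength))
  per <- diff(round(seq(0, totalCopies, length.out = fam$nArrays + 1L)))
  per <- per[per > 0]
  lapply(per, function(nc) {
    copies <- vapply(seq_len(nc), function(i)
      .mutateSeq(consensus, fam$intraArrayDivergence / 100, fam$indelRate),
      character(1))
    paste(copies, collapse = "")
  })
}

.assembleGenome <- function(arrays, genomeLength, gc) {
  arrLen <- sum(nchar(unlist(arrays)))
  if (arrLen >= genomeLength)
    stop("planted arrays (", arrLen, " bp) do not fit in a ",
         genomeLength, " bp genome")
  bgLen <- genomeLength - arrLen
  nArr <- length(unlist(arrays))
  flat <- unlist(arrays)
  famOf <- rep(names(arrays), lengths(arrays))
  ## split the background into nArr + 1 chunks and interleave
  cuts <- sort(sample.int(bgLen + 1L, nArr, replace = TRUE) - 1L)
  bounds <- c(0L, cuts, bgLen)
  bg <- .randomSeq(1L, bgLen, gc)
  pieces <- character(0)
  coords <- data.frame(family = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  pos <- 0L
  ord <- sample.int(nArr)  # random array order along the genome
  for (i in seq_len(nArr)) {
    chunk <- substr(bg, bounds[i] + 1L, bounds[i + 1L])
    pieces <- c(pieces, chunk)
    pos <- pos + nchar(chunk)
    a <- flat[ord[i]]
    pieces <- c(pieces, a)
    coords <- rbind(coords, data.frame(
      family = famOf[ord[i]], start = pos + 1L, end = pos + nchar(a),
      stringsAsFactors = FALSE))
    pos <- pos + nchar(a)
  }
  pieces <- c(pieces, substr(bg, bounds[nArr + 1L] + 1L, bgLen))
  list(genome = paste(pieces, collapse = ""), coords = coords)
}

.speciesGenome <- function(consensuses, fams, genomeLength, gc) {
  arrays <- lapply(seq_along(fams), function(i)
    .buildArrays(consensuses[[i]], fams[[i]], genomeLength))
  names(arrays) <- names(fams)
  asm <- .assembleGenome(arrays, genomeLength, gc)
  truthFrac <- vapply(names(fams), function(f) {
    rows <- asm$coords$family == f
    sum(asm$coords$end[rows] - asm$coords$start[rows] + 1L) / genomeLength
  }, numeric(1))
  list(genome = asm$genome, coords = asm$coords, fraction = truthFrac)
}

#' Generate a ground-truthed diverged species pair
#'
#' Builds two synthetic genomes that share an ancestral satellite library
#' (each species' consensus diverged independently from the ancestor) plus
#' optional species-private families, embedded as tandem arrays of mutated
#' copies in i.i.d. background sequence. Returns the genomes together with a
#' truth manifest recording, per species, every planted family's consensus,
#' exact genome fraction and array coordinates, and, across species, the
#' pairwise consensus similarity of each shared family.
#'
#' @param spec a [speciesPairSpec()].
#' @return A list with elements `genomeA`, `genomeB`
#'   ([Biostrings::DNAStringSet] of length 1 each) and `truth`, a list with
#'   `speciesA`, `speciesB` (each a data.frame `family`, `consensus`,
#'   `fraction` plus a `coords` data.frame) and `shared` (data.frame
#'   `family`, `similarity`).
#' @export
generateSpeciesPair <- function(spec) {
  stopifnot(inherits(spec, "SpeciesPairSpec"))
  .withSeed(spec$seed, {
    ns <- length(spec$sharedLibrary)
    sharedIds <- if (ns) sprintf("shared%02d", seq_len(ns)) else character(0)
    ancestors <- lapply(spec$sharedLibrary, function(f)
      .randomSeq(1L, f$monomerLength, 0.5))
    d <- spec$crossSpeciesDivergence / 100
    consA <- lapply(ancestors, .mutateSeq, subRate = d)
    consB <- lapply(ancestors, .mutateSeq, subRate = d)
    privCons <- function(fams, tag) {
      out <- lapply(fams, function(f) .randomSeq(1L, f$monomerLength, 0.5))
      names(out) <- if (length(fams))
        sprintf("%s%02d", tag, seq_along(fams)) else character(0)
      out
    }
    pA <- privCons(spec$privateA, "privateA")
    pB <- privCons(spec$privateB, "privateB")
    famsA <- c(spec$sharedLibrary, spec$privateA)
    names(famsA) <- c(sharedIds, names(pA))
    famsB <- c(spec$sharedLibrary, spec$privateB)
    names(famsB) <- c(sharedIds, names(pB))
    consAall <- c(stats::setNames(consA, sharedIds), pA)
    consBall <- c(stats::setNames(consB, sharedIds), pB)
    gA <- .speciesGenome(consAall, famsA, spec$genomeLength,
                         spec$gcBackground)
    gB <- .speciesGenome(consBall, famsB, spec$genomeLength,
                         spec$gcBackground)
    shared <- data.frame(
      family = sharedIds,
      similarity = vapply(seq_len(ns), function(i)
        .hammingIdentity(consA[[i]], consB[[i]]), numeric(1)),
      stringsAsFactors = FALSE)
    truthSide <- function(g, cons) {
      list(families = data.frame(family = names(cons),
                                 consensus = unlist(cons),
                                 fraction = g$fraction[names(cons)],
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
           coords = g$coords)
    }
    list(genomeA = Biostrings::DNAStringSet(c(genomeA = gA$genome)),
         genomeB = Biostrings::DNAStringSet(c(genomeB = gB$genome)),
         truth = list(speciesA = truthSide(gA, consAall),
                      speciesB = truthSide(gB, consBall),
                      shared = shared))
  })
}

#' Simulate fixed-length error-prone reads from a genome
#'
#' Draws `floor(coverage * G / readLength)` reads at uniform positions, each
#' from either strand with probability 0.5, with i.i.d. substitution errors
#' at `errorRate` per base. The read count is deterministic (not Poisson).
#'
#' @param genome [Biostrings::DNAStringSet] (first sequence used) or a
#'   character string.
#' @param coverage numeric(1) > 0, fold coverage.
#' @param readLength integer(1), read length in bp (default 101).
#' @param errorRate numeric(1), per-base substitution error rate
#'   (default 0.01).
#' @param seed integer(1) RNG seed.
#' @return A [ReadSample-class].
#' @export
simulateReads <- function(genome, coverage, readLength = 101L,
                          errorRate = 0.01, seed = 1L) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome[[1]])
  genome <- toupper(as.character(genome))
  G <- nchar(genome)
  if (readLength > G) stop("readLength exceeds genome length")
  stopifnot(coverage > 0)
  .withSeed(seed, {
    n <- floor(coverage * G / readLength)
    starts <- sample.int(G - readLength + 1L, n, replace = TRUE)
    rd <- substring(genome, starts, starts + readLength - 1L)
    ## strand
    flip <- runif(n) < 0.5
    if (any(flip)) rd[flip] <- .revcomp(rd[flip])
    ## substitution errors
    if (errorRate > 0) {
      nerr <- rbinom(n, readLength, errorRate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(readLength, nerr[i])
        v <- strsplit(rd[i], "")[[1]]
        v[pos] <- vapply(v[pos], function(b) sample(setdiff(.BASES, b), 1L),
                         character(1), USE.NAMES = FALSE)
        rd[i] <- paste(v, collapse = "")
      }
    }
    ReadSample(rd, readLength = readLength, errorRate = errorRate,
               coverage = coverage, seed = seed)
  })
}

#' Crop reads to a fixed length
#'
#' Reads shorter than `targetLength` are discarded; longer reads are
#' truncated at the 3' end, standardizing mixed-length libraries before
#' analysis.
#'
#' @param sample a [ReadSample-class].
#' @param targetLength integer(1) > 0.
#' @return A [ReadSample-class] whose reads all have length `targetLength`.
#' @export
cropReads <- function(sample, targetLength) {
  stopifnot(targetLength > 0)
  rd <- reads(sample)
  rd <- rd[Biostrings::width(rd) >= targetLength]
  rd <- Biostrings::subseq(rd, 1L, targetLength)
  ReadSample(as.character(rd), readLength = targetLength,
             errorRate = sample@errorRate, coverage = sample@coverage,
             seed = sample@seed)
}

#' Write reads as FASTQ
#'
#' Base qualities are a constant placeholder ('I', Phred 40), as simulated
#' reads carry no quality model.
#'
#' @param sample a [ReadSample-class].
#' @param path output FASTQ path.
#' @return Invisibly, `path`.
#' @export
writeReadsFastq <- function(sample, path) {
  rd <- reads(sample)
  if (is.null(names(rd)) || any(!nzchar(names(rd))))
    names(rd) <- sprintf("read%06d", seq_along(rd))
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(rd)))
  Biostrings::writeXStringSet(rd, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a ReadSample
#'
#' @param path FASTQ path.
#' @return A [ReadSample-class]; metadata fields are NA.
#' @export
readReadsFastq <- function(path) {
  rd <- Biostrings::readDNAStringSet(path, format = "fastq")
  ReadSample(as.character(rd))
}
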