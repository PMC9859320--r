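#' Map reads against a satellite catalog
#'
#' Locally aligns every read (both strands) against each family's dimerized
#' consensus -- the monomer multimerized past the read length so that any
#' position in an array, including monomer junctions, is fully alignable --
#' and keeps, per read, the single best-scoring hit with identity at or
#' above `minIdentity` percent over at least `minCoverage` of the read
#' length. Score ties are broken in favour of the lower (more abundant)
#' family rank, deterministically. Alignment scoring: match +1, mismatch -1,
#' gap open -2, gap extend -1; identity = matches / alignment columns
#' including internal gaps.
#'
#' @param sample a [ReadSample-class] of uniform-length reads.
#' @param catalog a non-empty [SatelliteCatalog-class] with consensus
#'   sequences.
#' @param minIdentity minimum identity percent of a reportable hit
#'   (default 80, matching the cross-species conservation threshold).
#' @param minCoverage minimum aligned fraction of the read (default 0.5);
#'   required because an unconstrained local alignment always finds short
#'   spurious perfect matches on random reads.
#' @param prefilter use the exact 12-mer seed prefilter (default TRUE).
#' @return [S4Vectors::DataFrame] of read hits with columns `read` (index
#'   into the sample), `family`, `aligned_length`, `identity`, `mismatches`.
#' @export
mapReads <- function(sample, catalog, minIdentity = 80, minCoverage = 0.5,
                     prefilter = TRUE) {
  stopifnot(is(catalog, "SatelliteCatalog"), nFamilies(catalog) > 0L)
  if (length(consensusSeqs(catalog)) == 0L)
    stop("catalog has no consensus sequences")
  fam <- .familySeqsOf(catalog)
  hits <- .alignReadsToFamilies(sample, fam, prefilter = prefilter)
  rl <- if (!is.na(sample@readLength)) sample@readLength else
    max(Biostrings::width(reads(sample)))
  hits <- hits[hits$identity >= minIdentity &
                 hits$readBases >= minCoverage * rl, ]
  if (!nrow(hits))
    return(S4Vectors::DataFrame(read = integer(0), family = character(0),
                                aligned_length = integer(0),
                                identity = numeric(0),
                                mismatches = integer(0)))
  hits$famRank <- match(hits$family, familyNames(catalog))
  data.table::setorderv(hits, c("read", "score", "famRank"),
                        order = c(1L, -1L, 1L))
  best <- hits[!duplicated(hits$read), ]
  S4Vectors::DataFrame(read = best$read, family = best$family,
                       aligned_length = as.integer(best$readBases),
                       identity = best$identity,
                       mismatches = as.integer(best$mismatches))
}

#' Estimate genome-proportion abundance and divergence
#'
#' Abundance per family is the summed aligned read nucleotides divided by
#' the total analyzed nucleotides of the sample (reads x read length), i.e.
#' the genome proportion the family occupies; divergence is the
#' aligned-length-weighted mean of (100 - identity). Families without hits
#' report zero abundance.
#'
#' @param hits read-hit table from [mapReads()].
#' @param catalog the [SatelliteCatalog-class] that was mapped against.
#' @param sample the [ReadSample-class] that was mapped (supplies the
#'   analyzed-nucleotide denominator).
#' @return [S4Vectors::DataFrame] with one row per family: `family`,
#'   `abundance`, `divergence`, `n_reads`; sample metadata
#'   (`n_reads_sampled`, `read_length`, `total_nucleotides`, plus the
#'   unmapped fraction) is attached as attribute `"sampleMeta"`.
#' @export
estimateAbundance <- function(hits, catalog, sample) {
  stopifnot(is(catalog, "SatelliteCatalog"))
  rl <- sample@readLength
  totalNt <- sum(Biostrings::width(reads(sample)))
  if (totalNt == 0) stop("sample contains zero nucleotides")
  unknown <- setdiff(unique(hits$family), familyNames(catalog))
  if (length(unknown))
    stop("hits reference unknown families: ", paste(unknown, collapse = ", "))
  per <- lapply(familyNames(catalog), function(f) {
    h <- hits[hits$family == f, , drop = FALSE]
    data.frame(
      family = f,
      abundance = sum(h$aligned_length) / totalNt,
      divergence = if (nrow(h))
        weighted.mean(100 - h$identity, h$aligned_length) else NA_real_,
      n_reads = nrow(h), stringsAsFactors = FALSE)
  })
  res <- S4Vectors::DataFrame(do.call(rbind, per))
  attr(res, "sampleMeta") <- list(
    n_reads_sampled = length(reads(sample)), read_length = rl,
    total_nucleotides = totalNt,
    unmapped_fraction = 1 - sum(res$abundance))
  res
}

#' Repeat landscape: abundance mass by divergence bin
#'
#' Splits each family's abundance into divergence bins \[0,b), \[b,2b), ...
#' where the divergence of a hit is 100 - identity; row sums equal the
#' family abundances of [estimateAbundance()]. The landscape is the standard
#' companion view of a satellitome mapping: recently homogenized families
#' pile up near zero divergence, degenerate ones spread right.
#'
#' @param hits read-hit table from [mapReads()].
#' @param catalog the mapped [SatelliteCatalog-class].
#' @param sample the mapped [ReadSample-class].
#' @param binWidth divergence bin width in percent (default 1).
#' @return numeric matrix, families x bins, of abundance mass.
#' @export
repeatLandscape <- function(hits, catalog, sample, binWidth = 1) {
  stopifnot(binWidth > 0)
  totalNt <- sum(Biostrings::width(reads(sample)))
  nb <- max(1L, ceiling(100 / binWidth))
  m <- matrix(0, nrow = nFamilies(catalog), ncol = nb,
              dimnames = list(familyNames(catalog),
                              sprintf("[%g,%g)", binWidth * (seq_len(nb) - 1),
                                      binWidth * seq_len(nb))))
  if (nrow(hits)) {
    div <- pmin(100 - hits$identity, 100 - 1e-9)
    bin <- pmin(floor(div / binWidth) + 1L, nb)
    for (i in seq_len(nrow(hits)))
      m[hits$family[i], bin[i]] <- m[hits$family[i], bin[i]] +
        hits$aligned_length[i] / totalNt
  }
  m
}

#' Name a discovered candidate set into a catalog
#'
#' Convenience wrapper tying discovery to quantification: maps the sample
#' against the candidate consensuses, estimates abundances, and applies the
#' naming convention in decreasing abundance order.
#'
#' @param candidates candidate table from [runDiscoveryLoop()].
#' @param sample the [ReadSample-class] used for quantification.
#' @param speciesAbbrev species abbreviation for naming.
#' @param minIdentity passed to [mapReads()].
#' @return A named [SatelliteCatalog-class] with abundance and divergence
#'   columns estimated from the sample.
#' @export
candidatesToCatalog <- function(candidates, sample, speciesAbbrev,
                                minIdentity = 80) {
  if (nrow(candidates) == 0L)
    return(assignNames(character(0), numeric(0), speciesAbbrev))
  tmp <- assignNames(candidates$consensus,
                     rep(0, nrow(candidates)), speciesAbbrev)
  ## provisional (alphabetical-by-name) catalog just to map against
  hits <- mapReads(sample, tmp, minIdentity = minIdentity)
  ab <- estimateAbundance(hits, tmp, sample)
  ord <- match(ab$family, familyNames(tmp))
  assignNames(as.character(consensusSeqs(tmp))[ord], ab$abundance,
              speciesAbbrev, divergence = ab$divergence)
}
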