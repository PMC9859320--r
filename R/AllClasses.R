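#' @import methods
NULL

setClassUnion("integerOrNull", c("integer", "NULL"))

#' SatelliteCatalog: an ordered collection of satDNA families
#'
#' The central container of the package: one species' satellitome. Families
#' are ordered by strictly non-increasing genome-proportion abundance, and
#' each carries the standard catalog columns (repeat unit length, A+T
#' content, abundance as a genome fraction, mean divergence). Family names
#' follow the convention `<Abbrev>Sat<NN>-<RUL>` where `<NN>` is the
#' abundance rank (zero-padded to two digits) and `<RUL>` the monomer length
#' in bp.
#'
#' The `consensus` slot holds the consensus monomers as a
#' [Biostrings::DNAStringSet]. It may be empty for metadata-only catalogs
#' (e.g. published catalog tables for which the deposited sequences are not
#' bundled); sequence-dependent operations require it to be populated.
#'
#' @slot speciesAbbrev character(1), the species abbreviation used in names
#'   (conventionally three letters, e.g. "Pme").
#' @slot consensus [Biostrings::DNAStringSet] of consensus monomers, named by
#'   family, or empty.
#' @slot familyData [S4Vectors::DataFrame] with columns `name`, `rank`,
#'   `rul`, `at_content`, `abundance`, `divergence`.
#'
#' @seealso [SatelliteCatalog()], [assignNames()], [summarizeCatalog()],
#'   [readCatalog()], [writeCatalog()]
#' @export
setClass("SatelliteCatalog",
  slots = c(
    speciesAbbrev = "character",
    consensus = "DNAStringSet",
    familyData = "DataFrame"
  )
)

.validSatelliteCatalog <- function(object) {
  msgs <- character(0)
  fd <- object@familyData
  needed <- c("name", "rank", "rul", "at_content", "abundance", "divergence")
  if (!all(needed %in% colnames(fd)))
    return(paste("familyData lacks columns:",
                 paste(setdiff(needed, colnames(fd)), collapse = ", ")))
  if (length(object@speciesAbbrev) != 1L || is.na(object@speciesAbbrev))
    msgs <- c(msgs, "speciesAbbrev must be a single string")
  if (nrow(fd) > 0L) {
    if (anyDuplicated(fd$name))
      msgs <- c(msgs, "family names must be unique within a catalog")
    if (any(diff(fd$abundance) > 1e-12))
      msgs <- c(msgs, "families must be sorted by non-increasing abundance")
    if (!identical(as.integer(fd$rank), seq_len(nrow(fd))))
      msgs <- c(msgs, "rank must equal the row position")
    if (any(fd$abundance < 0 | fd$abundance > 1, na.rm = TRUE))
      msgs <- c(msgs, "abundance must lie in [0, 1]")
    if (any(fd$at_content < 0 | fd$at_content > 100, na.rm = TRUE))
      msgs <- c(msgs, "at_content must lie in [0, 100]")
    if (any(fd$divergence < 0 | fd$divergence > 100, na.rm = TRUE))
      msgs <- c(msgs, "divergence must lie in [0, 100]")
    if (any(fd$rul < 1, na.rm = TRUE))
      msgs <- c(msgs, "rul must be a positive integer")
  }
  if (length(object@consensus) > 0L) {
    if (length(object@consensus) != nrow(fd))
      msgs <- c(msgs, "consensus and familyData sizes differ")
    else {
      if (!identical(names(object@consensus), fd$name))
        msgs <- c(msgs, "consensus names must match familyData$name")
      bad <- which(Biostrings::width(object@consensus) != fd$rul)
      if (length(bad))
        msgs <- c(msgs, paste0("rul does not equal consensus length for: ",
                               paste(fd$name[bad], collapse = ", ")))
      freq <- Biostrings::alphabetFrequency(object@consensus, baseOnly = TRUE)
      if (any(freq[, "other"] > 0))
        msgs <- c(msgs, "consensus monomers must contain only A/C/G/T")
      suffix <- suppressWarnings(as.integer(sub("^.*-", "", fd$name)))
      if (any(is.na(suffix)) || any(suffix != fd$rul))
        msgs <- c(msgs, "numeric name suffix must equal rul")
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("SatelliteCatalog", .validSatelliteCatalog)

#' Construct a SatelliteCatalog
#'
#' @param speciesAbbrev character(1) species abbreviation (e.g. "Pme").
#' @param familyData data.frame or DataFrame with columns `name`, `rul`,
#'   `at_content`, `abundance`, `divergence` (a `rank` column is derived from
#'   row order if absent).
#' @param consensus optional [Biostrings::DNAStringSet] (or named character
#'   vector) of consensus monomers, in the same order as `familyData`.
#' @return A validated [SatelliteCatalog-class] object.
#' @examples
#' fd <- data.frame(name = "XyzSat01-4", rul = 4, at_content = 50,
#'                  abundance = 0.001, divergence = NA_real_)
#' SatelliteCatalog("Xyz", fd, consensus = c("XyzSat01-4" = "ACGT"))
#' @export
SatelliteCatalog <- function(speciesAbbrev, familyData, consensus = NULL) {
  fd <- S4Vectors::DataFrame(familyData)
  if (!"rank" %in% colnames(fd)) fd$rank <- seq_len(nrow(fd))
  fd$rank <- as.integer(fd$rank)
  fd$rul <- as.integer(fd$rul)
  fd <- fd[, c("name", "rank", "rul", "at_content", "abundance", "divergence")]
  if (is.null(consensus)) {
    consensus <- Biostrings::DNAStringSet()
  } else {
    consensus <- Biostrings::DNAStringSet(toupper(as.character(consensus)))
    if (is.null(names(consensus)) || any(!nzchar(names(consensus))))
      names(consensus) <- fd$name
  }
  new("SatelliteCatalog", speciesAbbrev = as.character(speciesAbbrev),
      consensus = consensus, familyData = fd)
}

#' ReadSample: a fixed-length short-read collection
#'
#' Wraps a [Biostrings::DNAStringSet] of reads together with the sampling
#' metadata (nominal read length, per-base error rate, fold coverage, seed)
#' needed for abundance accounting and reproducibility.
#'
#' @slot reads [Biostrings::DNAStringSet] of reads.
#' @slot readLength numeric(1) nominal read length in bp (NA if mixed).
#' @slot errorRate numeric(1) per-base substitution error rate used in
#'   simulation (NA for real data).
#' @slot coverage numeric(1) fold coverage of the source genome (NA if
#'   unknown).
#' @slot seed integer(1) RNG seed used to draw the sample, or NULL.
#' @export
setClass("ReadSample",
  slots = c(
    reads = "DNAStringSet",
    readLength = "numeric",
    errorRate = "numeric",
    coverage = "numeric",
    seed = "integerOrNull"
  ),
  prototype = list(readLength = NA_real_, errorRate = NA_real_,
                   coverage = NA_real_, seed = NULL)
)

setValidity("ReadSample", function(object) {
  w <- Biostrings::width(object@reads)
  if (length(w) && !is.na(object@readLength) &&
      any(w != object@readLength))
    return("all reads must have length readLength")
  TRUE
})

#' Construct a ReadSample
#'
#' @param reads character vector or [Biostrings::DNAStringSet] of reads.
#' @param readLength nominal read length; defaults to the common width if
#'   all reads agree, NA otherwise.
#' @param errorRate,coverage,seed sampling metadata (see
#'   [ReadSample-class]).
#' @return A [ReadSample-class] object.
#' @export
ReadSample <- function(reads, readLength = NULL, errorRate = NA_real_,
                       coverage = NA_real_, seed = NULL) {
  reads <- Biostrings::DNAStringSet(toupper(as.character(reads)))
  w <- Biostrings::width(reads)
  if (is.null(readLength))
    readLength <- if (length(w) && length(unique(w)) == 1L) w[1] else NA_real_
  new("ReadSample", reads = reads, readLength = as.numeric(readLength),
      errorRate = as.numeric(errorRate), coverage = as.numeric(coverage),
      seed = if (is.null(seed)) NULL else as.integer(seed))
}
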