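#' A+T content of a DNA sequence
#'
#' Percentage of A and T bases, reported to one decimal (round-half-even),
#' matching the A+T column of published satellitome tables. Invariant under
#' reverse complement.
#'
#' @param seq character(1), [Biostrings::DNAString] or single-sequence input;
#'   alphabet restricted to A/C/G/T.
#' @return numeric(1) percent in \[0, 100\].
#' @examples
#' atContent("ACGTAT")  # 66.7
#' @export
atContent <- function(seq) {
  s <- .checkSeq(seq, allowN = FALSE, what = "sequence")
  v <- strsplit(s, "")[[1]]
  round(100 * sum(v %in% c("A", "T")) / length(v), 1)
}

.makeName <- function(abbrev, rank, rul) {
  sprintf("%sSat%02d-%d", abbrev, rank, rul)
}

#' Build a named catalog from consensus monomers and abundances
#'
#' Orders families by decreasing genome-proportion abundance and applies the
#' standard naming convention `<Abbrev>Sat<NN>-<RUL>` (rank zero-padded to
#' two digits, monomer length as suffix). Abundance ties are broken by larger
#' repeat unit length, then by lexicographic consensus, so catalogs are
#' deterministic across runs. Renaming an already named catalog is a no-op.
#'
#' @param consensus [Biostrings::DNAStringSet] or character vector of
#'   consensus monomers.
#' @param abundance numeric vector of genome fractions in \[0, 1\], parallel
#'   to `consensus`.
#' @param speciesAbbrev character(1) species abbreviation (e.g. "Pme").
#' @param divergence optional numeric vector of mean divergences (percent).
#' @return A [SatelliteCatalog-class] with names, ranks, RUL and A+T filled.
#' @examples
#' cat <- assignNames(c("ACGTACGTAT", "ACGT"), c(0.01, 0.02), "Xyz")
#' familyNames(cat)  # "XyzSat01-4" "XyzSat02-10"
#' @export
assignNames <- function(consensus, abundance, speciesAbbrev,
                        divergence = NULL) {
  consensus <- vapply(as.character(consensus), .checkSeq,
                      character(1), what = "consensus", USE.NAMES = FALSE)
  if (length(consensus) != length(abundance))
    stop("consensus and abundance lengths differ")
  if (any(abundance < 0))
    stop("abundances must be non-negative")
  if (anyDuplicated(consensus))
    stop("duplicate identical consensus sequences; merge before naming")
  if (is.null(divergence)) divergence <- rep(NA_real_, length(consensus))
  if (length(consensus) == 0L)
    return(SatelliteCatalog(speciesAbbrev, S4Vectors::DataFrame(
      name = character(0), rank = integer(0), rul = integer(0),
      at_content = numeric(0), abundance = numeric(0),
      divergence = numeric(0))))
  rul <- nchar(consensus)
  ord <- order(-abundance, -rul, consensus)
  consensus <- consensus[ord]; abundance <- abundance[ord]
  rul <- rul[ord]; divergence <- divergence[ord]
  nm <- .makeName(speciesAbbrev, seq_along(consensus), rul)
  fd <- S4Vectors::DataFrame(
    name = nm, rank = seq_along(nm), rul = as.integer(rul),
    at_content = vapply(consensus, atContent, numeric(1), USE.NAMES = FALSE),
    abundance = as.numeric(abundance), divergence = as.numeric(divergence))
  SatelliteCatalog(speciesAbbrev, fd,
                   consensus = stats::setNames(consensus, nm))
}

#' Summarize a satellite catalog
#'
#' Computes the usual satellitome summary: number of families, min/max/mean
#' (and median) of repeat unit length and A+T content, and counts of long
#' (RUL > 100 bp) and short (RUL < 100 bp) families. Families with RUL
#' exactly 100 bp are counted in neither class. Means and medians are
#' reported to one decimal (round-half-even).
#'
#' Published catalog tables occasionally carry a RUL column that disagrees
#' with the length encoded in the family name; `useNameRul = TRUE` summarizes
#' the name-implied lengths instead of the column.
#'
#' @param catalog a non-empty [SatelliteCatalog-class].
#' @param useNameRul logical(1), summarize name-implied monomer lengths
#'   rather than the `rul` column.
#' @return A named list of class `"CatalogSummary"` with elements
#'   `n_families`, `rul_min`, `rul_max`, `rul_mean`, `rul_median`, `at_min`,
#'   `at_max`, `at_mean`, `at_median`, `n_long`, `n_short`.
#' @export
summarizeCatalog <- function(catalog, useNameRul = FALSE) {
  stopifnot(is(catalog, "SatelliteCatalog"))
  fd <- familyInfo(catalog)
  if (nrow(fd) == 0L) stop("cannot summarize an empty catalog")
  rul <- if (useNameRul) as.integer(sub("^.*-", "", fd$name)) else fd$rul
  at <- fd$at_content
  out <- list(
    n_families = nrow(fd),
    rul_min = min(rul), rul_max = max(rul),
    rul_mean = round(mean(rul), 1), rul_median = round(stats::median(rul), 1),
    at_min = min(at), at_max = max(at),
    at_mean = round(mean(at), 1), at_median = round(stats::median(at), 1),
    n_long = sum(rul > 100L), n_short = sum(rul < 100L))
  class(out) <- "CatalogSummary"
  out
}

#' @export
print.CatalogSummary <- function(x, ...) {
  cat(sprintf("%d satDNA families\n", x$n_families))
  cat(sprintf("  RUL: %d-%d bp (mean %.1f, median %.1f)\n",
              x$rul_min, x$rul_max, x$rul_mean, x$rul_median))
  cat(sprintf("  A+T: %.1f-%.1f%% (mean %.1f, median %.1f)\n",
              x$at_min, x$at_max, x$at_mean, x$at_median))
  cat(sprintf("  long (>100 bp): %d; short (<100 bp): %d\n",
              x$n_long, x$n_short))
  invisible(x)
}

#' Write a catalog to FASTA + TSV
#'
#' FASTA holds the consensus monomers (headers are family names, wrapped at
#' 70 columns); the TSV mirrors the standard satellitome table with columns
#' `name`, `rul`, `at_content`, `abundance`, `divergence` (tab-separated,
#' header line, '.' decimal separator). Numeric fields are written with full
#' precision so that `readCatalog(writeCatalog(x))` is the identity.
#'
#' @param catalog a [SatelliteCatalog-class] with consensus sequences.
#' @param fastaPath,tsvPath output file paths.
#' @param header optional character vector of comment lines (each prefixed
#'   with `# `) recorded at the top of the TSV, e.g. seed and config hash.
#' @return Invisibly, `c(fastaPath, tsvPath)`.
#' @export
writeCatalog <- function(catalog, fastaPath, tsvPath, header = NULL) {
  stopifnot(is(catalog, "SatelliteCatalog"))
  if (length(consensusSeqs(catalog)) != nFamilies(catalog))
    stop("catalog has no consensus sequences; cannot write FASTA")
  Biostrings::writeXStringSet(consensusSeqs(catalog), fastaPath, width = 70L)
  fd <- as.data.frame(familyInfo(catalog))
  tab <- data.frame(
    name = fd$name, rul = fd$rul,
    at_content = sprintf("%.1f", fd$at_content),
    abundance = sprintf("%.17g", fd$abundance),
    divergence = ifelse(is.na(fd$divergence), "NA",
                        sprintf("%.17g", fd$divergence)),
    stringsAsFactors = FALSE)
  con <- file(tsvPath, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fastaPath, tsvPath))
}

.readCatalogTsv <- function(tsvPath) {
  tab <- read.delim(tsvPath, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c("name", "rul", "at_content", "abundance", "divergence")
  miss <- setdiff(needed, colnames(tab))
  if (length(miss))
    stop("catalog table is missing column(s): ", paste(miss, collapse = ", "))
  tab
}

#' Read a catalog from FASTA + TSV
#'
#' Inverse of [writeCatalog()]. All family invariants are validated on read;
#' in particular each FASTA sequence length must match both the `rul` column
#' and the length suffix of the family name, and the error message names the
#' offending family.
#'
#' @param fastaPath FASTA of consensus monomers, headers = family names.
#' @param tsvPath catalog table (see [writeCatalog()] for the dialect).
#' @param speciesAbbrev optional; derived from the first family name if
#'   omitted.
#' @return A [SatelliteCatalog-class].
#' @export
readCatalog <- function(fastaPath, tsvPath, speciesAbbrev = NULL) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  tab <- .readCatalogTsv(tsvPath)
  if (!setequal(names(seqs), tab$name))
    stop("FASTA and TSV disagree on family names")
  seqs <- seqs[tab$name]
  bad <- which(Biostrings::width(seqs) != tab$rul)
  if (length(bad))
    stop("consensus length does not match rul for family: ",
         paste(tab$name[bad], collapse = ", "))
  if (is.null(speciesAbbrev))
    speciesAbbrev <- sub("Sat.*$", "", tab$name[1])
  SatelliteCatalog(speciesAbbrev, tab,
                   consensus = stats::setNames(toupper(as.character(seqs)),
                                               tab$name))
}

#' Read a metadata-only catalog table
#'
#' Loads a satellitome table (TSV with the columns of [writeCatalog()]) into
#' a [SatelliteCatalog-class] without consensus sequences, as needed for
#' published catalogs whose monomer sequences are deposited elsewhere.
#' Because published tables are transcribed as printed, the name-implied
#' length is allowed to disagree with the `rul` column here (it is enforced
#' whenever sequences are present).
#'
#' @param tsvPath path to the table.
#' @param speciesAbbrev optional; derived from the first family name if
#'   omitted.
#' @return A metadata-only [SatelliteCatalog-class].
#' @export
readCatalogTable <- function(tsvPath, speciesAbbrev = NULL) {
  tab <- .readCatalogTsv(tsvPath)
  if (is.null(speciesAbbrev))
    speciesAbbrev <- sub("Sat.*$", "", tab$name[1])
  SatelliteCatalog(speciesAbbrev, tab)
}

#' Path to a bundled fixture file
#'
#' Convenience wrapper around `system.file()` for the small plain-text
#' fixtures shipped with the package (published catalog tables and homology
#' tables used in examples and tests).
#'
#' @param filename file name under `extdata/`, or empty to list the
#'   directory.
#' @return character(1) path.
#' @export
satellitomeExtdata <- function(filename = "") {
  p <- system.file("extdata", filename, package = "satellitome",
                   mustWork = FALSE)
  if (!nzchar(p)) stop("no bundled file named '", filename, "'")
  p
}
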