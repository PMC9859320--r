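#' Accessors for SatelliteCatalog and ReadSample
#'
#' `speciesAbbrev()` returns the species abbreviation, `consensusSeqs()` the
#' consensus monomers as a [Biostrings::DNAStringSet], `familyInfo()` the
#' family metadata [S4Vectors::DataFrame], `familyNames()` the family names,
#' `nFamilies()` the number of families, and `reads()` the read set of a
#' [ReadSample-class].
#'
#' @param x a [SatelliteCatalog-class] or [ReadSample-class] object.
#' @return See the description per accessor.
#' @name catalog-accessors
NULL

#' @rdname catalog-accessors
#' @export
setGeneric("speciesAbbrev", function(x) standardGeneric("speciesAbbrev"))
#' @rdname catalog-accessors
#' @export
setGeneric("consensusSeqs", function(x) standardGeneric("consensusSeqs"))
#' @rdname catalog-accessors
#' @export
setGeneric("familyInfo", function(x) standardGeneric("familyInfo"))
#' @rdname catalog-accessors
#' @export
setGeneric("familyNames", function(x) standardGeneric("familyNames"))
#' @rdname catalog-accessors
#' @export
setGeneric("nFamilies", function(x) standardGeneric("nFamilies"))
#' @rdname catalog-accessors
#' @export
setGeneric("reads", function(x) standardGeneric("reads"))

#' @rdname catalog-accessors
#' @export
setMethod("speciesAbbrev", "SatelliteCatalog", function(x) x@speciesAbbrev)
#' @rdname catalog-accessors
#' @export
setMethod("consensusSeqs", "SatelliteCatalog", function(x) x@consensus)
#' @rdname catalog-accessors
#' @export
setMethod("familyInfo", "SatelliteCatalog", function(x) x@familyData)
#' @rdname catalog-accessors
#' @export
setMethod("familyNames", "SatelliteCatalog", function(x) x@familyData$name)
#' @rdname catalog-accessors
#' @export
setMethod("nFamilies", "SatelliteCatalog", function(x) nrow(x@familyData))
#' @rdname catalog-accessors
#' @export
setMethod("reads", "ReadSample", function(x) x@reads)

#' @export
setMethod("length", "ReadSample", function(x) length(x@reads))

setMethod("show", "SatelliteCatalog", function(object) {
  fd <- object@familyData
  cat("SatelliteCatalog of", object@speciesAbbrev, "with", nrow(fd),
      "satDNA families\n")
  if (nrow(fd)) {
    cat("  RUL range:", min(fd$rul), "-", max(fd$rul), "bp;",
        "total abundance:", signif(sum(fd$abundance), 4), "\n")
    cat("  consensus sequences:",
        if (length(object@consensus)) "present" else "absent (metadata only)",
        "\n")
    show(head(as.data.frame(fd), 5L))
    if (nrow(fd) > 5L) cat("  ...", nrow(fd) - 5L, "more families\n")
  }
  invisible(NULL)
})

setMethod("show", "ReadSample", function(object) {
  cat("ReadSample of", length(object@reads), "reads",
      if (!is.na(object@readLength)) paste0("(", object@readLength, " bp)"),
      "\n")
  if (!is.na(object@coverage)) cat("  coverage:", object@coverage, "x\n")
  if (!is.na(object@errorRate)) cat("  error rate:", object@errorRate, "\n")
  invisible(NULL)
})
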