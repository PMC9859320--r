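#' Read a pipeline run configuration
#'
#' A single YAML file of key-value pairs drives the command-line pipeline;
#' recognized keys are file paths (`reads`, `catalog_fasta`, `catalog_tsv`,
#' `outdir`), the [discoveryParams()] fields under `discovery:`, the
#' quantification sample size (`quantify_reads`, default 4914670, i.e.
#' 2 x 2,457,335, scaled down at will), the comparison thresholds
#' (`min_share` 50, `min_conservation` 80, `merge_threshold` 95) and the
#' master `seed`. Unset keys take the defaults returned by
#' `defaultRunConfig()`.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return A list of class `"RunConfig"` with a `config_hash` field (a
#'   short digest of the normalized config, embedded in output headers).
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (k in names(user)) {
      if (k == "discovery" && is.list(user[[k]])) {
        for (dk in names(user[[k]])) cfg$discovery[[dk]] <- user[[k]][[dk]]
      } else cfg[[k]] <- user[[k]]
    }
  }
  stopifnot(cfg$min_share >= 0, cfg$min_share <= 100,
            cfg$min_conservation >= 0, cfg$min_conservation <= 100,
            cfg$merge_threshold >= 0, cfg$merge_threshold <= 100)
  cfg$config_hash <- .configHash(cfg)
  class(cfg) <- "RunConfig"
  cfg
}

#' @rdname readRunConfig
#' @export
defaultRunConfig <- function() {
  list(
    reads = NULL, catalog_fasta = NULL, catalog_tsv = NULL, outdir = ".",
    discovery = unclass(discoveryParams()),
    quantify_reads = 4914670L,
    min_share = 50, min_conservation = 80, merge_threshold = 95,
    seed = 1L)
}

## stable short hash of the config (sum-based; no digest dependency needed)
.configHash <- function(cfg) {
  cfg$config_hash <- NULL
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  v <- utf8ToInt(txt)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", h)
}

#' Output header lines for reproducibility
#'
#' Every TSV the pipeline writes starts with comment lines recording the
#' seed and the config hash so a run can be byte-reproduced.
#'
#' @param cfg a `RunConfig`.
#' @return character vector of header lines (without the leading `# `).
#' @export
runHeader <- function(cfg) {
  c(paste0("seed=", cfg$seed), paste0("config_hash=", cfg$config_hash))
}

#' Render a Markdown summary report
#'
#' Combines whatever stage outputs exist -- catalog tables, a shared-pair
#' table, a conservation table -- into a short Markdown report with catalog
#' summary lines and classification counts. Missing inputs are simply
#' skipped, so an empty invocation yields an empty (but valid) report.
#'
#' @param catalogTsvs named character vector of catalog TSV paths (names =
#'   species abbreviations), or NULL.
#' @param sharedTsv shared-pair TSV path or NULL.
#' @param conservationTsv conservation TSV path or NULL.
#' @param outPath output Markdown path.
#' @return Invisibly, `outPath`.
#' @export
renderReport <- function(catalogTsvs = NULL, sharedTsv = NULL,
                         conservationTsv = NULL, outPath) {
  lines <- c("# Satellitome report", "")
  for (sp in names(catalogTsvs)) {
    cat_i <- readCatalogTable(catalogTsvs[[sp]], speciesAbbrev = sp)
    s <- summarizeCatalog(cat_i)
    lines <- c(lines, sprintf("## %s", sp),
      sprintf("- %d satDNA families", s$n_families),
      sprintf("- RUL %d-%d bp (mean %.1f, median %.1f)",
              s$rul_min, s$rul_max, s$rul_mean, s$rul_median),
      sprintf("- A+T %.1f-%.1f%% (mean %.1f, median %.1f)",
              s$at_min, s$at_max, s$at_mean, s$at_median),
      sprintf("- long (>100 bp): %d, short (<100 bp): %d",
              s$n_long, s$n_short), "")
  }
  if (!is.null(sharedTsv)) {
    tab <- readSharedPairsTable(sharedTsv)
    cnt <- table(factor(tab$level, levels = names(.levelAbbrev)))
    lines <- c(lines, "## Shared satDNAs",
      sprintf("- %d cross-species pairs at >=50%% similarity", nrow(tab)),
      sprintf("- same variant: %d, variant: %d, superfamily: %d",
              cnt[["same_variant"]], cnt[["variant"]], cnt[["superfamily"]]),
      "")
  }
  if (!is.null(conservationTsv)) {
    m <- readConservationTable(conservationTsv)
    s <- summarizeConservation(m)
    lines <- c(lines, "## Multi-species conservation",
      sprintf("- %d homology groups across %d species", s$n_groups,
              ncol(m)),
      sprintf("- groups containing both %s and %s: %d", colnames(m)[1],
              colnames(m)[2], s$n_with_both),
      sprintf("- maximum monomer length: %s bp",
              ifelse(is.na(s$max_rul), "NA", s$max_rul)), "")
  }
  writeLines(lines, outPath)
  invisible(outPath)
}

#' Write a shared-pair table
#'
#' @param pairs output of [compareCatalogs()].
#' @param tsvPath destination.
#' @param header optional comment header lines (see [runHeader()]).
#' @return Invisibly, `tsvPath`.
#' @export
writeSharedPairs <- function(pairs, tsvPath, header = NULL) {
  df <- as.data.frame(pairs)
  df$classification <- .levelAbbrev[df$level]
  con <- file(tsvPath, "wt"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df[, c("family_a", "family_b", "similarity",
                     "classification")],
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsvPath)
}

#' Write a conservation matrix
#'
#' @param m output of [multiCatalogConservation()].
#' @param tsvPath destination.
#' @param header optional comment header lines.
#' @return Invisibly, `tsvPath`.
#' @export
writeConservation <- function(m, tsvPath, header = NULL) {
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  df[is.na(df)] <- "-"
  con <- file(tsvPath, "wt"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tsvPath)
}
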