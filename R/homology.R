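#' Rotation- and strand-invariant similarity of two monomers
#'
#' Tandem-repeat monomers are circular sequences with an arbitrary start
#' point and strand, so plain alignment understates their homology. Here the
#' monomer of one sequence is aligned semi-globally (free end gaps on the
#' subject side) against the head-to-tail self-concatenation of the other
#' ("dimerization"), on both strands, and the similarity is 100 x matches /
#' alignment columns (including internal gaps) of the best alignment. Both
#' orientations (either input as the dimerized subject) are tried and the
#' maximum taken, making the measure symmetric. Monomers shorter than
#' `tetramerBelow` bp are concatenated four times rather than twice so the
#' aligner has usable target length. Unaligned overhang of the longer
#' sequence does not penalize, by design: a short monomer embedded in a
#' longer one scores by its best placement.
#'
#' Scoring is deliberately gap-stringent (match +1, mismatch -1, gap open
#' -5, gap extend -3): monomer homology is dominated by substitution
#' divergence, and permissive gap costs let an optimizer stitch random
#' matches until unrelated sequences approach 50\% identity, defeating the
#' common-origin threshold. Under these costs random monomer pairs of
#' ordinary length score ~35-45\%, leaving the 50\% cut meaningful (very
#' short monomers retain an elevated chance floor; see the package
#' vignette).
#'
#' @param a,b consensus monomer sequences (character, A/C/G/T).
#' @param tetramerBelow monomer length below which the subject is
#'   concatenated four times (default 20).
#' @return numeric(1) similarity percent in \[0, 100\].
#' @examples
#' rotationalSimilarity("ACGTACGTTA", "GTTAACGTAC")  # a rotation: 100
#' @export
rotationalSimilarity <- function(a, b, tetramerBelow = 20L) {
  a <- .checkSeq(a, what = "monomer"); b <- .checkSeq(b, what = "monomer")
  one <- function(p, s) {
    copies <- if (nchar(s) < tetramerBelow) 4L else 2L
    subj <- Biostrings::DNAString(dimerize(s, copies = copies))
    pat <- Biostrings::DNAStringSet(c(p, .revcomp(p)))
    aln <- Biostrings::pairwiseAlignment(
      pat, subj, type = "global-local", substitutionMatrix = .subMat(),
      gapOpening = 5, gapExtension = 3)
    ## identity of the best-scoring alignment (forward strand on ties)
    Biostrings::pid(aln, type = "PID1")[which.max(Biostrings::score(aln))]
  }
  ## symmetrize over both orientations; a perfect first orientation cannot
  ## be beaten, so skip the converse then
  s1 <- one(a, b)
  if (s1 >= 100) return(100)
  max(s1, one(b, a))
}

#' Classify a monomer pair by similarity
#'
#' The standard three-tier homology classification of satDNA monomer pairs:
#' similarity above 95 percent makes the pair the same variant of one
#' satDNA, 80-95 percent makes them variants, 50-80 percent a superfamily,
#' and below 50 percent the pair is considered unrelated (no common origin
#' call). Boundary values: exactly 95 and exactly 80 classify as variant,
#' exactly 50 as superfamily.
#'
#' @param similarity numeric vector of percents in \[0, 100\].
#' @return character vector over `"same_variant"`, `"variant"`,
#'   `"superfamily"`, `"unrelated"`.
#' @examples
#' classifyPair(c(97.6, 87, 72.5, 49.9))
#' @export
classifyPair <- function(similarity) {
  if (any(is.na(similarity)) || any(similarity < 0 | similarity > 100))
    stop("similarity must lie in [0, 100]")
  ifelse(similarity > 95, "same_variant",
         ifelse(similarity >= 80, "variant",
                ifelse(similarity >= 50, "superfamily", "unrelated")))
}

.levelAbbrev <- c(same_variant = "SV", variant = "V", superfamily = "SF",
                  unrelated = "-")

#' Compare two satellite catalogs
#'
#' Computes the rotational similarity of every cross-catalog monomer pair
#' and reports those at or above `minShare` percent (the conventional
#' common-origin threshold, 50), with their classification level. A family
#' may appear in several pairs.
#'
#' @param catA,catB [SatelliteCatalog-class] objects with consensus
#'   sequences.
#' @param minShare minimum similarity percent to report (default 50).
#' @return [S4Vectors::DataFrame] with columns `family_a`, `family_b`,
#'   `similarity`, `level`, ordered by the rank of `family_a` then
#'   `family_b`.
#' @export
compareCatalogs <- function(catA, catB, minShare = 50) {
  stopifnot(is(catA, "SatelliteCatalog"), is(catB, "SatelliteCatalog"))
  if (length(consensusSeqs(catA)) == 0L || length(consensusSeqs(catB)) == 0L)
    stop("both catalogs need consensus sequences")
  sa <- as.character(consensusSeqs(catA)); sb <- as.character(consensusSeqs(catB))
  grid <- expand.grid(a = seq_along(sa), b = seq_along(sb))
  sim <- mapply(function(i, j) rotationalSimilarity(sa[i], sb[j]),
                grid$a, grid$b)
  keep <- sim >= minShare
  res <- S4Vectors::DataFrame(
    family_a = familyNames(catA)[grid$a[keep]],
    family_b = familyNames(catB)[grid$b[keep]],
    similarity = sim[keep],
    level = classifyPair(sim[keep]))
  res[order(match(res$family_a, familyNames(catA)),
            match(res$family_b, familyNames(catB))), , drop = FALSE]
}

.singleLinkageGroups <- function(vertexNames, edgeA, edgeB) {
  ia <- match(edgeA, vertexNames); ib <- match(edgeB, vertexNames)
  g <- igraph::graph_from_edgelist(cbind(ia, ib), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(vertexNames) -
                                     igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  lapply(split(seq_along(vertexNames), memb), function(i) vertexNames[i])
}

#' Group within-catalog superfamilies
#'
#' Single-linkage grouping of a catalog's families over pairs with
#' rotational similarity in \[50, 95\] percent (above 95 the pair would be
#' the same family; redundancy at that level is resolved during discovery).
#' Groups of size one are omitted.
#'
#' @param catalog a [SatelliteCatalog-class] with consensus sequences, or
#'   any catalog when `pairs` is supplied.
#' @param pairs optional precomputed pair table (data.frame with columns
#'   `family_a`, `family_b` and optionally `similarity`), e.g. transcribed
#'   from a published homology analysis; when given, sequences are not
#'   needed, and pairs lacking a similarity column are taken as already
#'   within range.
#' @return List of character vectors of family names, ordered by the rank
#'   of each group's highest-ranked member.
#' @export
groupSuperfamilies <- function(catalog, pairs = NULL) {
  stopifnot(is(catalog, "SatelliteCatalog"))
  if (is.null(pairs)) {
    if (length(consensusSeqs(catalog)) == 0L)
      stop("catalog has no consensus sequences; supply pairs")
    seqs <- as.character(consensusSeqs(catalog))
    nm <- familyNames(catalog)
    comb <- which(upper.tri(matrix(0, length(nm), length(nm))),
                  arr.ind = TRUE)
    sim <- vapply(seq_len(nrow(comb)), function(i)
      rotationalSimilarity(seqs[comb[i, 1]], seqs[comb[i, 2]]), numeric(1))
    pairs <- data.frame(family_a = nm[comb[, 1]], family_b = nm[comb[, 2]],
                        similarity = sim, stringsAsFactors = FALSE)
  }
  if (!is.null(pairs$similarity))
    pairs <- pairs[pairs$similarity >= 50 & pairs$similarity <= 95, ,
                   drop = FALSE]
  if (!nrow(pairs)) return(list())
  groups <- .singleLinkageGroups(familyNames(catalog),
                                 pairs$family_a, pairs$family_b)
  groups <- Filter(function(g) length(g) >= 2L, groups)
  ord <- order(vapply(groups, function(g)
    min(match(g, familyNames(catalog))), integer(1)))
  lapply(groups[ord], function(g) g[order(match(g, familyNames(catalog)))])
}

#' Cross-species conservation table
#'
#' Builds homology groups by single linkage over all cross-catalog pairs at
#' or above `minSimilarity` percent (default 80, the conventional
#' multi-species conservation threshold) and lays them out as a matrix with
#' one row per group and one column per species; cells carry the species'
#' family name in the group (the highest-ranked one if several) or NA. Rows
#' are ordered by the first species' family rank.
#'
#' @param catalogs list of two or more [SatelliteCatalog-class] objects with
#'   consensus sequences and distinct species abbreviations.
#' @param minSimilarity conservation threshold percent (default 80).
#' @return character matrix, rownames `group<k>`, colnames the species
#'   abbreviations.
#' @export
multiCatalogConservation <- function(catalogs, minSimilarity = 80) {
  if (length(catalogs) < 2L)
    stop("conservation analysis needs at least 2 catalogs")
  species <- vapply(catalogs, speciesAbbrev, character(1))
  if (anyDuplicated(species)) stop("species abbreviations must be distinct")
  allNames <- unlist(lapply(catalogs, familyNames))
  spOf <- rep(species, vapply(catalogs, nFamilies, integer(1)))
  names(spOf) <- allNames
  edges <- list()
  for (i in seq_along(catalogs)) for (j in seq_along(catalogs)) {
    if (i >= j) next
    p <- compareCatalogs(catalogs[[i]], catalogs[[j]],
                         minShare = minSimilarity)
    edges[[length(edges) + 1L]] <- as.data.frame(p)[, c("family_a",
                                                        "family_b")]
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges) || !nrow(edges)) {
    return(matrix(character(0), nrow = 0, ncol = length(species),
                  dimnames = list(NULL, species)))
  }
  groups <- .singleLinkageGroups(allNames, edges$family_a, edges$family_b)
  groups <- Filter(function(g) length(unique(spOf[g])) >= 2L, groups)
  firstRank <- vapply(groups, function(g) {
    k <- match(g, familyNames(catalogs[[1]]))
    if (all(is.na(k))) .Machine$integer.max else min(k, na.rm = TRUE)
  }, numeric(1))
  groups <- groups[order(firstRank)]
  m <- matrix(NA_character_, nrow = length(groups), ncol = length(species),
              dimnames = list(sprintf("group%d", seq_along(groups)),
                              species))
  for (gi in seq_along(groups)) for (sp in species) {
    fams <- groups[[gi]][spOf[groups[[gi]]] == sp]
    if (length(fams)) {
      cat_i <- catalogs[[match(sp, species)]]
      m[gi, sp] <- fams[order(match(fams, familyNames(cat_i)))][1]
    }
  }
  m
}

#' Read a shared-pair table
#'
#' Loads a cross-species homology table (TSV columns: `family_a`,
#' `family_b`, `similarity`, and optionally `classification`) such as the
#' published comparison of two satellitomes.
#'
#' @param tsvPath path to the table.
#' @return data.frame with a `level` column recomputed by [classifyPair()].
#' @export
readSharedPairsTable <- function(tsvPath) {
  tab <- read.delim(tsvPath, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  needed <- c("family_a", "family_b", "similarity")
  miss <- setdiff(needed, colnames(tab))
  if (length(miss))
    stop("shared-pair table is missing column(s): ",
         paste(miss, collapse = ", "))
  tab$level <- classifyPair(tab$similarity)
  tab
}

#' Read a multi-species conservation table
#'
#' Loads a conservation matrix (TSV, one column per species abbreviation,
#' cells = family name or "-" for absent) into the matrix layout of
#' [multiCatalogConservation()].
#'
#' @param tsvPath path to the table.
#' @return character matrix with NA for absent cells.
#' @export
readConservationTable <- function(tsvPath) {
  tab <- read.delim(tsvPath, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab)
  m[m == "-" | m == ""] <- NA_character_
  rownames(m) <- sprintf("group%d", seq_len(nrow(m)))
  m
}

#' Summarize a conservation matrix
#'
#' @param m conservation matrix (see [multiCatalogConservation()]).
#' @param focal character(2) species abbreviations whose joint presence is
#'   counted.
#' @return list with `n_groups`, `n_with_both` (groups containing both focal
#'   species) and `max_rul` (largest name-implied monomer length over all
#'   cells).
#' @export
summarizeConservation <- function(m, focal = colnames(m)[1:2]) {
  ruls <- suppressWarnings(as.integer(sub("^.*-", "", m[!is.na(m)])))
  list(n_groups = nrow(m),
       n_with_both = sum(!is.na(m[, focal[1]]) & !is.na(m[, focal[2]])),
       max_rul = if (length(ruls)) max(ruls, na.rm = TRUE) else NA_integer_)
}
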