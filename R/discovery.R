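#' Parameters of the iterative satDNA discovery loop
#'
#' @param readsPerIteration reads sampled into each detection round
#'   (default 500000, i.e. 2 x 250,000; scale down for small genomes).
#' @param k odd k-mer size between 11 and 31 for the overlap graph
#'   (default 21).
#' @param minKmerFreq minimum canonical (strand-summed) k-mer frequency for
#'   a k-mer to enter the graph (default 5, calibrated to ~0.5x coverage).
#' @param circularityThreshold minimum circularity score (cycle weight /
#'   component weight) for a graph candidate (default 0.5).
#' @param filterIdentity,filterCoverage thresholds of the between-round read
#'   subtraction: a read is removed when it aligns to a discovered consensus
#'   with at least `filterIdentity` percent identity over at least
#'   `filterCoverage` of its length (defaults 90 and 0.5).
#' @param maxIterations hard cap on discovery rounds (default 10).
#' @param maxShortPeriod largest period searched by the within-read
#'   periodicity detector (default 20; must stay below `k` and half the read
#'   length).
#' @param minPeriod smallest period considered (default 3; periods 1-2,
#'   i.e. homopolymers and dinucleotide repeats, are conventionally excluded
#'   from satellite catalogs).
#' @param minShortReads minimum supporting reads for a periodicity-derived
#'   candidate (default 5).
#' @param minSelfIdentity minimum within-read self-shift identity (percent)
#'   for a read to count as periodic (default 75). The self-shift compares
#'   one array copy against the next, so divergence counts twice: copies at
#'   d percent divergence from their consensus agree at roughly
#'   100 - 2d(1 - d/100) percent, and random sequence at ~25 percent, which
#'   leaves a wide margin.
#' @return A list of class `"DiscoveryParams"`.
#' @export
discoveryParams <- function(readsPerIteration = 500000L, k = 21L,
                            minKmerFreq = 5L, circularityThreshold = 0.5,
                            filterIdentity = 90, filterCoverage = 0.5,
                            maxIterations = 10L, maxShortPeriod = 20L,
                            minPeriod = 3L, minShortReads = 5L,
                            minSelfIdentity = 75) {
  stopifnot(k %% 2 == 1, k >= 11, k <= 31,
            circularityThreshold >= 0, circularityThreshold <= 1,
            filterIdentity >= 0, filterIdentity <= 100,
            filterCoverage > 0, filterCoverage <= 1,
            maxIterations >= 1, minPeriod >= 1,
            maxShortPeriod >= minPeriod, readsPerIteration >= 1)
  structure(list(readsPerIteration = as.integer(readsPerIteration),
                 k = as.integer(k), minKmerFreq = as.integer(minKmerFreq),
                 circularityThreshold = circularityThreshold,
                 filterIdentity = filterIdentity,
                 filterCoverage = filterCoverage,
                 maxIterations = as.integer(maxIterations),
                 maxShortPeriod = as.integer(maxShortPeriod),
                 minPeriod = as.integer(minPeriod),
                 minShortReads = as.integer(minShortReads),
                 minSelfIdentity = minSelfIdentity),
            class = "DiscoveryParams")
}

.emptyCandidates <- function() {
  S4Vectors::DataFrame(consensus = character(0),
                       circularity_score = numeric(0),
                       supporting_kmer_mass = numeric(0),
                       detection_round = integer(0),
                       method = character(0))
}

## all single-substitution mutants of a k-mer (plus the k-mer itself)
.mutants1 <- function(s) {
  v <- strsplit(s, "")[[1]]
  out <- character(3L * length(v) + 1L)
  out[1] <- s
  idx <- 1L
  for (i in seq_along(v)) for (b in setdiff(.BASES, v[i])) {
    x <- v; x[i] <- b
    idx <- idx + 1L
    out[idx] <- paste(x, collapse = "")
  }
  out
}

## smallest p such that x is an exact repetition of its p-prefix
.exactPeriod <- function(x) {
  n <- nchar(x)
  for (p in seq_len(n)) {
    if (n %% p != 0) next
    if (strrep(substr(x, 1L, p), n %/% p) == x) return(p)
  }
  n
}

#' Detect tandem-repeat monomers via k-mer overlap-graph cycles
#'
#' A tandem array of an m-bp monomer contributes m distinct k-mers forming
#' a directed cycle under (k-1)-overlap (this holds for m below k as well:
#' the windows of a periodic sequence repeat with its period). The detector
#' counts k-mers with strand-summed (canonical) frequencies, keeps those at
#' or above `minKmerFreq`, and builds the overlap graph on the retained
#' k-mers. From the heaviest node of each weakly connected component it
#' extracts the heaviest cycle by a greedy heaviest-successor walk; at each
#' step the four possible (k-1)-overlap successors are weighted by their
#' canonical frequency in the full (unthresholded) k-mer table, so that
#' consensus positions whose k-mer dipped below the retention threshold --
#' inevitable at low coverage over diverged copies -- are bridged by
#' majority vote instead of breaking the cycle. Positions where no intact
#' k-mer survives at all (every covering window carries an error) are
#' bridged by majority vote over a secondary `smallK`-mer table; at most
#' `k` consecutive such fallback steps are allowed, so walks through
#' genuinely unsupported sequence still terminate. Background sequence
#' yields path-shaped components whose walks never close and are discarded.
#'
#' The cycle's spelled sequence, canonicalized for rotation and strand, is
#' the candidate consensus; the circularity score is the fraction of the
#' component's retained k-mer mass lying on the cycle, and candidates
#' scoring below `circularityThreshold`, shorter than 6 bp, or with exact
#' period 1-2 (homopolymers, dinucleotide repeats) are dropped.
#' Mirror-image components (the two strands of one repeat) collapse to a
#' single candidate.
#'
#' @param sample a [ReadSample-class].
#' @param params a [discoveryParams()].
#' @param maxWalk cap on walk length before a non-closing walk is abandoned
#'   (default 10000, comfortably above the longest catalogued monomers).
#' @param smallK k-mer size of the fallback extension table (default 11).
#' @param polish refine each candidate consensus by column-majority vote of
#'   its matching reads before reporting (default TRUE).
#' @return Candidate table ([S4Vectors::DataFrame]) with columns
#'   `consensus`, `circularity_score`, `supporting_kmer_mass`,
#'   `detection_round` (NA here; filled by [runDiscoveryLoop()]), `method`.
#' @export
detectLongMonomers <- function(sample, params = discoveryParams(),
                               maxWalk = 10000L, smallK = 11L,
                               polish = TRUE) {
  readsChr <- as.character(reads(sample))
  names(readsChr) <- NULL
  k <- params$k
  if (!length(readsChr)) return(.emptyCandidates())
  if (k >= max(nchar(readsChr))) stop("k must be smaller than read length")
  km <- .kmerTable(readsChr, k)
  km <- km[!grepl("N", km$kmer, fixed = TRUE)]
  if (!nrow(km)) return(.emptyCandidates())
  cnt <- km[, list(n = .N), by = "kmer"]
  rcv <- .revcomp(cnt$kmer)
  cnt$ncan <- cnt$n + {
    m <- match(rcv, cnt$kmer)
    ifelse(is.na(m), 0L, cnt$n[m])
  }
  full <- data.table::data.table(kmer = cnt$kmer, ncan = cnt$ncan,
                                 key = "kmer")
  canFreq <- function(x) {
    f <- full[data.table::data.table(kmer = x), on = "kmer"]$ncan
    f[is.na(f)] <- 0L
    f
  }
  km2 <- .kmerTable(readsChr, smallK)
  km2 <- km2[!grepl("N", km2$kmer, fixed = TRUE)]
  cnt2 <- km2[, list(n = .N), by = "kmer"]
  rcv2 <- .revcomp(cnt2$kmer)
  cnt2$ncan <- cnt2$n + {
    m2 <- match(rcv2, cnt2$kmer)
    ifelse(is.na(m2), 0L, cnt2$n[m2])
  }
  full2 <- data.table::data.table(kmer = cnt2$kmer, ncan = cnt2$ncan,
                                  key = "kmer")
  canFreq2 <- function(x) {
    f <- full2[data.table::data.table(kmer = x), on = "kmer"]$ncan
    f[is.na(f)] <- 0L
    f
  }
  keep <- cnt[cnt$ncan >= params$minKmerFreq, ]
  if (!nrow(keep)) return(.emptyCandidates())
  ## overlap edges among retained k-mers define the components
  dt <- data.table::data.table(kmer = keep$kmer, w = keep$ncan)
  dt[, `:=`(pre = substr(kmer, 1L, k - 1L), suf = substr(kmer, 2L, k))]
  edges <- merge(dt[, list(from = kmer, key = suf)],
                 dt[, list(to = kmer, key = pre)],
                 by = "key", allow.cartesian = TRUE)[, c("from", "to")]
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = dt$kmer, w = dt$w))
  comp <- igraph::components(g, mode = "weak")
  membership <- comp$membership  # named by k-mer
  wts <- stats::setNames(dt$w, dt$kmer)
  compW <- vapply(split(wts[names(membership)], membership), sum,
                  numeric(1))
  ## every retained k-mer may seed a walk (heaviest first); walks from
  ## background dead-end or score ~0, so sensitivity costs no specificity
  starts <- dt$kmer[order(-dt$w, dt$kmer)]
  seen <- new.env(hash = TRUE)     # k-mers on an emitted cycle
  started <- new.env(hash = TRUE)  # k-mers already used as walk starts
  out <- list()
  for (start in starts) {
    if (!is.null(seen[[start]]) || !is.null(started[[start]])) next
    path <- character(0); posOf <- new.env(hash = TRUE)
    cur <- start
    cyc <- NULL
    fallbackRun <- 0L
    for (step in seq_len(maxWalk)) {
      if (!is.null(posOf[[cur]])) {
        cyc <- path[posOf[[cur]]:length(path)]
        break
      }
      posOf[[cur]] <- length(path) + 1L
      path <- c(path, cur)
      succ <- paste0(substr(cur, 2L, k), .BASES)
      wsucc <- canFreq(succ)
      if (max(wsucc) > 0L) {
        fallbackRun <- 0L
      } else {
        fallbackRun <- fallbackRun + 1L
        if (fallbackRun > k) break
        ## hamming-1 neighborhood evidence: tolerates one off-consensus
        ## base anywhere in the window (it shifts out within k steps)
        wsucc <- vapply(succ, function(s) sum(canFreq(.mutants1(s))),
                        numeric(1))
        if (max(wsucc) == 0L) {
          wsucc <- canFreq2(paste0(substr(cur, k - smallK + 2L, k), .BASES))
          if (max(wsucc) == 0L) break
        }
      }
      cur <- succ[order(-wsucc, succ)[1]]
    }
    ## retained k-mers on this walk (successful or not) never seed again:
    ## heaviest-first ordering means genuine repeats walk before stragglers
    for (x in path[!is.na(match(path, dt$kmer))]) started[[x]] <- TRUE
    if (is.null(cyc) || length(cyc) < 3L) next
    spelled <- paste(substr(cyc, k, k), collapse = "")
    if (nchar(spelled) < 6L) next
    if (.exactPeriod(spelled) <= 2L) next
    if (polish) spelled <- .polishConsensus(spelled, sample)
    ## score against the component the cycle predominantly lies in (a walk
    ## may be seeded by a satellite variant sitting in a side component)
    ret <- cyc[!is.na(match(cyc, names(membership)))]
    if (!length(ret)) next
    ci <- names(sort(table(membership[ret]), decreasing = TRUE))[1]
    onCycle <- intersect(cyc, names(membership)[membership == as.integer(ci)])
    score <- sum(wts[onCycle]) / compW[[ci]]
    if (score < params$circularityThreshold) next
    for (x in cyc) seen[[x]] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      consensus = canonicalMonomer(spelled), circularity_score = score,
      supporting_kmer_mass = sum(canFreq(cyc)), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.emptyCandidates())
  res <- do.call(rbind, out)
  ## mirror components spell the same canonical monomer: keep the heavier
  res <- res[order(res$consensus, -res$supporting_kmer_mass), ]
  res <- res[!duplicated(res$consensus), ]
  S4Vectors::DataFrame(consensus = res$consensus,
                       circularity_score = res$circularity_score,
                       supporting_kmer_mass = res$supporting_kmer_mass,
                       detection_round = NA_integer_,
                       method = "graph-cycle")
}

## best rotation x strand alignment of monomer b onto monomer a (equal
## length, hamming); returns list(identity, aligned)
.bestRotationOnto <- function(b, a) {
  cand <- c(.rotations(b), .rotations(.revcomp(b)))
  ids <- vapply(cand, .hammingIdentity, numeric(1), b = a)
  i <- which.max(ids)
  list(identity = ids[[i]], aligned = cand[[i]])
}

#' Detect short-period monomers by within-read periodicity
#'
#' The overlap-graph detector degrades for periods below the k-mer size, so
#' short monomers are recovered directly from reads: for each read the
#' smallest period `p` (between `minPeriod` and `maxShortPeriod`) whose
#' self-shift identity reaches `minSelfIdentity` percent is taken, the
#' read's monomer is estimated by majority vote over residue classes mod
#' `p`, and reads are grouped by period and rotation/strand-canonical
#' monomer (allowing for divergence) into clusters that each emit a
#' column-majority consensus.
#'
#' @param sample a [ReadSample-class] of uniform-length reads.
#' @param maxPeriod largest period searched; must be < readLength / 2.
#' @param params a [discoveryParams()] supplying `minPeriod`,
#'   `minShortReads` and `minSelfIdentity`.
#' @return Candidate table as in [detectLongMonomers()], `method`
#'   `"short-period"`.
#' @export
detectShortMonomers <- function(sample, maxPeriod = NULL,
                                params = discoveryParams()) {
  if (is.null(maxPeriod)) maxPeriod <- params$maxShortPeriod
  rd <- reads(sample)
  L <- if (!is.na(sample@readLength)) as.integer(sample@readLength) else
    min(Biostrings::width(rd))
  rd <- rd[Biostrings::width(rd) == L]
  if (maxPeriod >= L / 2) stop("maxPeriod must be < readLength / 2")
  if (!length(rd)) return(.emptyCandidates())
  readsChr <- as.character(rd); names(readsChr) <- NULL
  mat <- matrix(unlist(strsplit(readsChr, ""), use.names = FALSE), nrow = L)
  periods <- params$minPeriod:maxPeriod
  idMat <- vapply(periods, function(p)
    100 * colSums(mat[seq_len(L - p), , drop = FALSE] ==
                    mat[(p + 1L):L, , drop = FALSE]) / (L - p),
    numeric(ncol(mat)))
  idMat <- matrix(idMat, ncol = length(periods))
  hit <- idMat >= params$minSelfIdentity
  firstP <- apply(hit, 1L, function(z) if (any(z)) periods[which(z)[1]]
                  else NA_integer_)
  sel <- which(!is.na(firstP))
  if (!length(sel)) return(.emptyCandidates())
  ## per-read monomer by majority vote across repeat copies
  est <- vapply(sel, function(j) {
    p <- firstP[j]
    cls <- ((seq_len(L) - 1L) %% p) + 1L
    mono <- vapply(seq_len(p), function(i) {
      tb <- table(mat[cls == i, j])
      names(tb)[which.max(tb)]
    }, character(1))
    paste(mono, collapse = "")
  }, character(1))
  selfId <- vapply(seq_along(sel), function(ii)
    idMat[sel[ii], match(firstP[sel[ii]], periods)], numeric(1))
  keep <- !grepl("N", est, fixed = TRUE)
  est <- est[keep]; selfId <- selfId[keep]
  pvec <- firstP[sel][keep]
  out <- list()
  for (p in unique(pvec)) {
    mono <- canonicalMonomer(est[pvec == p])
    sid <- selfId[pvec == p]
    while (length(mono)) {
      tb <- sort(table(mono), decreasing = TRUE)
      seed <- names(tb)[1]
      fit <- lapply(mono, .bestRotationOnto, a = seed)
      member <- vapply(fit, function(f) f$identity >= 70, logical(1))
      aligned <- vapply(fit[member], function(f) f$aligned, character(1))
      if (sum(member) >= params$minShortReads) {
        am <- matrix(unlist(strsplit(aligned, ""), use.names = FALSE),
                     nrow = p)
        cons <- paste(apply(am, 1L, function(r) {
          tb2 <- table(r); names(tb2)[which.max(tb2)]
        }), collapse = "")
        if (.exactPeriod(cons) > 2L)
          out[[length(out) + 1L]] <- data.frame(
            consensus = canonicalMonomer(cons),
            circularity_score = min(1, mean(sid[member]) / 100),
            supporting_kmer_mass = sum(member), stringsAsFactors = FALSE)
      }
      mono <- mono[!member]; sid <- sid[!member]
    }
  }
  if (!length(out)) return(.emptyCandidates())
  res <- do.call(rbind, out)
  res <- res[order(res$consensus, -res$supporting_kmer_mass), ]
  res <- res[!duplicated(res$consensus), ]
  S4Vectors::DataFrame(consensus = res$consensus,
                       circularity_score = res$circularity_score,
                       supporting_kmer_mass = res$supporting_kmer_mass,
                       detection_round = NA_integer_,
                       method = "short-period")
}

.familySeqsOf <- function(catalog) {
  if (is(catalog, "SatelliteCatalog")) {
    seqs <- as.character(consensusSeqs(catalog))
    stats::setNames(as.list(seqs), familyNames(catalog))
  } else if (is.character(catalog)) {
    nm <- names(catalog)
    if (is.null(nm)) nm <- sprintf("family%02d", seq_along(catalog))
    stats::setNames(as.list(catalog), nm)
  } else stop("expected a SatelliteCatalog or named character vector")
}

#' Subtract reads matching known satDNA families
#'
#' Alignment-based read filtering between discovery rounds: a read is
#' removed when it aligns to any family's dimerized consensus (either
#' strand) with identity >= `filterIdentity` percent over at least
#' `filterCoverage` of its length. An empty catalog returns the sample
#' unchanged.
#'
#' @param sample a [ReadSample-class].
#' @param catalog a [SatelliteCatalog-class] with consensus sequences, or a
#'   (named) character vector of monomers.
#' @param filterIdentity,filterCoverage thresholds (defaults 90 percent and
#'   0.5 of the read length).
#' @param prefilter use the exact 12-mer seed prefilter before alignment
#'   (default TRUE; set FALSE to force full alignment of every read).
#' @return The surviving reads as a [ReadSample-class].
#' @export
filterMatchingReads <- function(sample, catalog, filterIdentity = 90,
                                filterCoverage = 0.5, prefilter = TRUE) {
  fam <- .familySeqsOf(catalog)
  if (!length(fam)) return(sample)
  hits <- .alignReadsToFamilies(sample, fam, prefilter = prefilter)
  rl <- if (!is.na(sample@readLength)) sample@readLength else
    max(Biostrings::width(reads(sample)))
  bad <- unique(hits$read[hits$identity >= filterIdentity &
                            hits$readBases >= filterCoverage * rl])
  keep <- setdiff(seq_along(reads(sample)), bad)
  ReadSample(as.character(reads(sample))[keep],
             readLength = sample@readLength, errorRate = sample@errorRate,
             coverage = sample@coverage, seed = sample@seed)
}

#' Merge redundant candidate monomers
#'
#' Single-linkage grouping of candidates whose pairwise rotational
#' similarity exceeds `threshold` (default 95 percent, the conventional
#' same-variant cut); each group is replaced by its highest-supporting-mass
#' member (ties broken by lexicographically smallest consensus).
#'
#' @param candidates candidate table as returned by the detectors.
#' @param threshold similarity percent above which candidates are the same
#'   family.
#' @return The deduplicated candidate table.
#' @export
mergeRedundant <- function(candidates, threshold = 95) {
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sim <- vapply(seq_len(nrow(pairs)), function(i)
    rotationalSimilarity(candidates$consensus[pairs[i, 1]],
                         candidates$consensus[pairs[i, 2]]), numeric(1))
  e <- pairs[sim > threshold, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(e[, 1], e[, 2]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  keep <- vapply(split(seq_len(n), memb), function(idx) {
    idx[order(-candidates$supporting_kmer_mass[idx],
              candidates$consensus[idx])][1]
  }, integer(1))
  candidates[sort(keep), , drop = FALSE]
}

#' Run the iterative discovery loop
#'
#' Alternates detection and read subtraction the way iterative satellitome
#' pipelines do: in each round a fixed-size read subsample (fresh
#' deterministic sub-seed per round) is scanned by both detectors, novel
#' candidates (rotational similarity <= 95 percent to everything found so
#' far) are added with their detection round, matching reads are filtered
#' from the pool, and the loop stops when a round adds nothing or
#' `maxIterations` is reached (the latter with a warning recorded in the run
#' log).
#'
#' @param sample a [ReadSample-class].
#' @param params a [discoveryParams()].
#' @param seed master seed for per-round subsampling.
#' @return Candidate table with `detection_round` filled; the per-round run
#'   log (a data.frame with reads in, new candidates, reads filtered, and
#'   the termination reason) is attached as attribute `"log"`.
#' @export
runDiscoveryLoop <- function(sample, params = discoveryParams(), seed = 1L) {
  found <- .emptyCandidates()
  pool <- sample
  log <- list()
  reason <- "max_iterations"
  for (r in seq_len(params$maxIterations)) {
    nIn <- length(reads(pool))
    if (nIn == 0L) { reason <- "reads_exhausted"; break }
    idx <- if (nIn > params$readsPerIteration)
      .withSeed(.subSeed(seed, r),
                sample.int(nIn, params$readsPerIteration)) else seq_len(nIn)
    sub <- ReadSample(as.character(reads(pool))[idx],
                      readLength = pool@readLength)
    cand <- rbind(detectLongMonomers(sub, params),
                  detectShortMonomers(sub, params = params))
    if (nrow(cand)) cand <- mergeRedundant(cand)
    novel <- if (nrow(cand) && nrow(found)) {
      isNew <- vapply(seq_len(nrow(cand)), function(i)
        all(vapply(found$consensus, function(f)
          rotationalSimilarity(cand$consensus[i], f), numeric(1)) <= 95),
        logical(1))
      cand[isNew, , drop = FALSE]
    } else cand
    if (nrow(novel) == 0L) {
      log[[r]] <- data.frame(round = r, reads_in = nIn, new_candidates = 0L,
                             reads_filtered = 0L)
      reason <- "no_new_candidates"
      break
    }
    novel$detection_round <- r
    found <- rbind(found, novel)
    before <- length(reads(pool))
    pool <- filterMatchingReads(pool, unlist(novel$consensus),
                                params$filterIdentity,
                                params$filterCoverage)
    log[[r]] <- data.frame(round = r, reads_in = nIn,
                           new_candidates = nrow(novel),
                           reads_filtered = before - length(reads(pool)))
  }
  if (reason == "max_iterations")
    warning("discovery stopped at maxIterations with candidates still ",
            "appearing; result may be partial")
  attr(found, "log") <- do.call(rbind, log)
  attr(found, "termination") <- reason
  found
}
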