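test_that("a pure tandem array yields exactly one graph candidate", {
  set.seed(201)
  mono <- randSeq(1, 150)
  rs <- arrayReads(mono, copies = 200, coverage = 3, errorRate = 0,
                   seed = 21)
  cand <- detectLongMonomers(rs, discoveryParams(minKmerFreq = 5))
  expect_equal(nrow(cand), 1L)
  expect_equal(rotationalSimilarity(cand$consensus[1], mono), 100)
  expect_equal(nchar(cand$consensus[1]), 150L)
  expect_gte(cand$circularity_score[1], 0.9)
})

test_that("random background at low coverage yields no candidates", {
  set.seed(202)
  bg <- randSeq(1, 300000)
  rs <- simulateReads(bg, coverage = 0.5, readLength = 101,
                      errorRate = 0.01, seed = 22)
  expect_equal(nrow(detectLongMonomers(rs, discoveryParams(minKmerFreq = 5))),
               0L)
  expect_equal(nrow(detectShortMonomers(rs)), 0L)
})

test_that("two repeats sharing no k-mers give two candidates", {
  set.seed(203)
  m1 <- randSeq(1, 120); m2 <- randSeq(1, 200)
  genome <- paste0(randSeq(1, 5000), strrep(m1, 60), randSeq(1, 5000),
                   strrep(m2, 40), randSeq(1, 5000))
  rs <- simulateReads(genome, coverage = 2, readLength = 101,
                      errorRate = 0, seed = 23)
  cand <- detectLongMonomers(rs, discoveryParams(minKmerFreq = 8))
  expect_equal(nrow(cand), 2L)
  sims <- vapply(cand$consensus, function(x)
    max(rotationalSimilarity(x, m1), rotationalSimilarity(x, m2)),
    numeric(1))
  expect_true(all(sims == 100))
})

test_that("raising minKmerFreq never increases the candidate count", {
  set.seed(204)
  genome <- paste0(randSeq(1, 8000), strrep(randSeq(1, 90), 60),
                   randSeq(1, 8000), strrep(randSeq(1, 45), 60),
                   randSeq(1, 8000))
  rs <- simulateReads(genome, coverage = 1, readLength = 101,
                      errorRate = 0.01, seed = 24)
  counts <- vapply(c(5, 8, 15, 30, 80), function(f)
    nrow(detectLongMonomers(rs, discoveryParams(minKmerFreq = f))),
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("periodicity detector recovers short monomers", {
  ## perfect hexamer repeat
  rs <- ReadSample(rep(substr(strrep("ACGTAT", 20), 1, 101), 10),
                   readLength = 101)
  cand <- detectShortMonomers(rs)
  expect_equal(nrow(cand), 1L)
  expect_equal(nchar(cand$consensus[1]), 6L)
  expect_equal(cand$consensus[1], canonicalMonomer("ACGTAT"))
  ## homopolymer reads are degenerate and excluded
  rsT <- ReadSample(rep(strrep("T", 101), 10), readLength = 101)
  expect_equal(nrow(detectShortMonomers(rsT)), 0L)
})

test_that("periodicity detector tolerates 10% copy divergence", {
  set.seed(205)
  mono <- randSeq(1, 21)
  arr <- paste(vapply(1:300, function(i)
    substituteBases(mono, sample(21, rbinom(1, 21, 0.1))), character(1)),
    collapse = "")
  rs <- simulateReads(arr, coverage = 4, readLength = 101, errorRate = 0.01,
                      seed = 25)
  cand <- detectShortMonomers(rs, maxPeriod = 25)
  expect_gte(nrow(cand), 1L)
  best <- max(vapply(cand$consensus, rotationalSimilarity, numeric(1),
                     b = mono))
  expect_gte(best, 95)
})

test_that("read filtering removes exactly the matching reads", {
  set.seed(206)
  mono <- randSeq(1, 80)
  satReads <- arrayReads(mono, copies = 100, coverage = 1, errorRate = 0,
                         seed = 26)
  bgReads <- simulateReads(randSeq(1, 30000), coverage = 0.3,
                           readLength = 101, errorRate = 0, seed = 27)
  mixed <- ReadSample(c(as.character(reads(satReads)),
                        as.character(reads(bgReads))), readLength = 101)
  cat1 <- assignNames(mono, 0.01, "Tst")
  ## empty catalog: unchanged
  empty <- assignNames(character(0), numeric(0), "Tst")
  expect_identical(as.character(reads(filterMatchingReads(mixed, empty))),
                   as.character(reads(mixed)))
  filtered <- filterMatchingReads(mixed, cat1, 90, 0.5)
  expect_equal(length(reads(filtered)), length(reads(bgReads)))
  ## verbatim reads from the consensus are all removed
  self <- filterMatchingReads(satReads, cat1, 90, 0.5)
  expect_equal(length(reads(self)), 0L)
})

test_that("seed prefilter decisions equal brute-force full alignment", {
  set.seed(207)
  mono <- randSeq(1, 60)
  satArr <- paste(vapply(1:60, function(i)
    substituteBases(mono, sample(60, rbinom(1, 60, 0.05))), character(1)),
    collapse = "")
  genome <- paste0(randSeq(1, 15000), satArr, randSeq(1, 15000))
  rs <- simulateReads(genome, coverage = 1, readLength = 101,
                      errorRate = 0.01, seed = 28)
  stopifnot(length(reads(rs)) <= 500)
  cat1 <- assignNames(c(mono, randSeq(1, 130)), c(0.01, 0.005), "Tst")
  fast <- filterMatchingReads(rs, cat1, 90, 0.5, prefilter = TRUE)
  full <- filterMatchingReads(rs, cat1, 90, 0.5, prefilter = FALSE)
  expect_identical(as.character(reads(fast)), as.character(reads(full)))
  ## filtering soundness: survivors have no qualifying hit
  hits <- mapReads(fast, cat1, minIdentity = 90, minCoverage = 0.5,
                   prefilter = FALSE)
  expect_equal(nrow(hits), 0L)
})

test_that("mergeRedundant collapses same-variant candidates transitively", {
  set.seed(208)
  mono <- randSeq(1, 100)
  rot <- rotStr(mono, 37)
  cands <- S4Vectors::DataFrame(
    consensus = c(mono, rot), circularity_score = c(1, 1),
    supporting_kmer_mass = c(10, 5), detection_round = c(1L, 1L),
    method = "graph-cycle")
  merged <- mergeRedundant(cands)
  expect_equal(nrow(merged), 1L)
  expect_identical(merged$consensus, mono)  # higher mass representative
  ## ~90% similar pairs are variants and stay separate
  v90 <- substituteBases(mono, seq(5, 95, by = 10))
  expect_lt(rotationalSimilarity(mono, v90), 95)
  cands2 <- S4Vectors::DataFrame(
    consensus = c(mono, v90), circularity_score = c(1, 1),
    supporting_kmer_mass = c(10, 5), detection_round = c(1L, 1L),
    method = "graph-cycle")
  expect_equal(nrow(mergeRedundant(cands2)), 2L)
  ## single-linkage chain: A~B and B~C merge all three even if A~C < 95
  b <- substituteBases(mono, c(3, 23, 43))
  c3 <- substituteBases(b, c(13, 33, 53))
  expect_gt(rotationalSimilarity(mono, b), 95)
  expect_gt(rotationalSimilarity(b, c3), 95)
  cands3 <- S4Vectors::DataFrame(
    consensus = c(mono, b, c3), circularity_score = 1,
    supporting_kmer_mass = c(10, 5, 3), detection_round = 1L,
    method = "graph-cycle")
  expect_equal(nrow(mergeRedundant(cands3)), 1L)
})

test_that("discovery loop terminates and records rounds deterministically", {
  set.seed(209)
  mono <- randSeq(1, 100)
  genome <- paste0(randSeq(1, 40000), strrep(mono, 100), randSeq(1, 40000))
  rs <- simulateReads(genome, coverage = 1, readLength = 101,
                      errorRate = 0.01, seed = 29)
  p <- discoveryParams(minKmerFreq = 8)
  res1 <- runDiscoveryLoop(rs, p, seed = 30)
  res2 <- runDiscoveryLoop(rs, p, seed = 30)
  expect_identical(res1$consensus, res2$consensus)
  expect_identical(attr(res1, "termination"), "no_new_candidates")
  log <- attr(res1, "log")
  expect_true(is.data.frame(log) && all(c("round", "reads_in",
                                          "new_candidates") %in% names(log)))
  expect_equal(res1$detection_round[1], 1L)
  expect_gte(log$reads_filtered[1], 1)
  ## maxIterations = 1 equals a single detection pass
  p1 <- discoveryParams(minKmerFreq = 8, maxIterations = 1)
  single <- suppressWarnings(runDiscoveryLoop(rs, p1, seed = 30))
  direct <- mergeRedundant(rbind(detectLongMonomers(rs, p1),
                                 detectShortMonomers(rs, params = p1)))
  expect_setequal(single$consensus, direct$consensus)
  ## background-only input terminates after round 1 with nothing
  bg <- simulateReads(randSeq(1, 100000), coverage = 0.5, readLength = 101,
                      errorRate = 0.01, seed = 31)
  res0 <- runDiscoveryLoop(bg, discoveryParams(), seed = 32)
  expect_equal(nrow(res0), 0L)
  expect_lte(nrow(attr(res0, "log")), 1L)
})
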