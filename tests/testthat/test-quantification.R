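test_that("a monomer-junction read maps at identity 100", {
  set.seed(301)
  mono <- randSeq(1, 60)
  junction <- paste0(substr(mono, 31, 60), mono, substr(mono, 1, 11))
  expect_equal(nchar(junction), 101L)
  cat1 <- assignNames(c(mono, randSeq(1, 80)), c(0.01, 0.005), "Tst")
  h <- mapReads(ReadSample(junction, readLength = 101), cat1)
  expect_equal(nrow(h), 1L)
  expect_identical(h$family, familyNames(cat1)[match(
    mono, as.character(consensusSeqs(cat1)))])
  expect_equal(h$identity, 100)
  expect_equal(h$aligned_length, 101L)
})

test_that("random background reads produce no hits at 80% identity", {
  set.seed(302)
  cat1 <- assignNames(c(randSeq(1, 60), randSeq(1, 150), randSeq(1, 21)),
                      c(0.01, 0.005, 0.001), "Tst")
  bg <- ReadSample(randSeq(200, 101), readLength = 101)
  expect_equal(nrow(mapReads(bg, cat1, minIdentity = 80)), 0L)
  expect_equal(nrow(mapReads(bg, cat1, minIdentity = 80,
                             prefilter = FALSE)), 0L)
})

test_that("identity arithmetic: 10 substitutions in 101 bp gives 91/101", {
  set.seed(303)
  mono <- randSeq(1, 200)
  read <- substr(paste0(mono, mono), 20, 120)
  ## substitutions clustered mid-read: both read ends stay exact, so the
  ## score-optimal local alignment spans the full read
  read10 <- substituteBases(read, seq(30, 75, by = 5))
  cat1 <- assignNames(mono, 0.01, "Tst")
  h <- mapReads(ReadSample(read10, readLength = 101), cat1)
  expect_equal(h$identity, 100 * 91 / 101, tolerance = 1e-9)
  expect_equal(h$mismatches, 10L)
})

test_that("abundance accounting conserves nucleotides", {
  set.seed(304)
  mono <- randSeq(1, 70)
  sat <- arrayReads(mono, copies = 80, coverage = 1, errorRate = 0,
                    seed = 33)
  cat1 <- assignNames(c(mono, randSeq(1, 90)), c(0.01, 0.005), "Tst")
  ## all reads verbatim from one family: its abundance is 1, others 0
  hits <- mapReads(sat, cat1)
  ab <- estimateAbundance(hits, cat1, sat)
  expect_equal(ab$abundance[1] + ab$abundance[2], 1, tolerance = 1e-12)
  expect_equal(ab$abundance[ab$family == familyNames(cat1)[2]], 0)
  meta <- attr(ab, "sampleMeta")
  expect_equal(sum(ab$abundance) + meta$unmapped_fraction, 1,
               tolerance = 1e-12)
  ## no hits at all: zero abundance everywhere
  none <- estimateAbundance(hits[0, ], cat1, sat)
  expect_true(all(none$abundance == 0))
  expect_true(all(is.na(none$divergence)))
  ## a zero-nucleotide sample is an error
  expect_error(estimateAbundance(hits, cat1, ReadSample(character(0))),
               "zero")
  ## hits must reference catalog families
  badHits <- hits; badHits$family <- "Nope"
  expect_error(estimateAbundance(badHits, cat1, sat), "unknown")
})

test_that("best-hit assignment matches brute-force on a small sample", {
  set.seed(305)
  m1 <- randSeq(1, 80); m2 <- substituteBases(m1, seq(2, 78, by = 6))
  genome <- paste0(randSeq(1, 8000), strrep(m1, 40), randSeq(1, 4000),
                   strrep(m2, 40), randSeq(1, 8000))
  rs <- simulateReads(genome, coverage = 1, readLength = 101,
                      errorRate = 0.01, seed = 34)
  stopifnot(length(reads(rs)) <= 500)
  cat1 <- assignNames(c(m1, m2), c(0.01, 0.008), "Tst")
  fast <- mapReads(rs, cat1)
  full <- mapReads(rs, cat1, prefilter = FALSE)
  expect_equal(as.data.frame(fast), as.data.frame(full))
})

test_that("abundance estimates track planted fractions and their ranking", {
  spec <- speciesPairSpec(
    genomeLength = 500000,
    sharedLibrary = list(plantedFamilySpec(120, 0.012, 3),
                         plantedFamilySpec(60, 0.005, 3),
                         plantedFamilySpec(200, 0.002, 3)),
    seed = 35)
  g <- generateSpeciesPair(spec)
  truth <- g$truth$speciesA$families
  cat1 <- assignNames(truth$consensus, truth$fraction, "Tru")
  rs <- simulateReads(g$genomeA, coverage = 8, readLength = 101,
                      errorRate = 0.01, seed = 36)
  ab <- estimateAbundance(mapReads(rs, cat1), cat1, rs)
  est <- ab$abundance[match(familyNames(cat1), ab$family)]
  tr <- familyInfo(cat1)$abundance
  ## planted fractions differ >= 2x, so the ranking must be exact
  expect_identical(order(-est), order(-tr))
  expect_true(all(abs(est - tr) / tr < 0.2))
  ## doubling the sample moves each estimate by less than 3 binomial SEs
  rs2 <- simulateReads(g$genomeA, coverage = 16, readLength = 101,
                       errorRate = 0.01, seed = 37)
  ab2 <- estimateAbundance(mapReads(rs2, cat1), cat1, rs2)
  est2 <- ab2$abundance[match(familyNames(cat1), ab2$family)]
  nReads <- length(reads(rs))
  se <- sqrt(tr * (1 - tr) / nReads) * 1  # fraction-scale SE per read
  expect_true(all(abs(est2 - est) < 3 * sqrt(tr / nReads) + 3 *
                    sqrt(tr / (2 * nReads))))
})

test_that("repeat landscape conserves abundance mass per family", {
  set.seed(306)
  mono <- randSeq(1, 90)
  rs <- arrayReads(mono, copies = 60, coverage = 1, errorRate = 0,
                   seed = 38)
  cat1 <- assignNames(c(mono, randSeq(1, 50)), c(0.01, 0.002), "Tst")
  hits <- mapReads(rs, cat1)
  ab <- estimateAbundance(hits, cat1, rs)
  land <- repeatLandscape(hits, cat1, rs, binWidth = 1)
  ## error-free undiverged reads: all mass in the [0,1) bin
  expect_equal(sum(land[1, -1]), 0)
  expect_gt(land[1, 1], 0)
  ## row sums equal the abundance estimates
  expect_equal(unname(rowSums(land)),
               ab$abundance[match(rownames(land), ab$family)],
               tolerance = 1e-12)
})

test_that("landscape mode sits near the planted divergence", {
  set.seed(307)
  mono <- randSeq(1, 120)
  arr <- paste(vapply(1:80, function(i)
    substituteBases(mono, sample(120, rbinom(1, 120, 0.1))), character(1)),
    collapse = "")
  rs <- simulateReads(arr, coverage = 2, readLength = 101, errorRate = 0,
                      seed = 39)
  cat1 <- assignNames(mono, 0.01, "Tst")
  hits <- mapReads(rs, cat1)
  land <- repeatLandscape(hits, cat1, rs, binWidth = 1)
  modal <- which.max(land[1, ])  # bin [modal-1, modal)
  expect_lte(abs((modal - 0.5) - 10), 2.5)
})
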