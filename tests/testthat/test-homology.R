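test_that("rotational similarity is rotation-, strand- and order-invariant", {
  set.seed(401)
  for (i in 1:25) {
    L <- sample(6:300, 1)
    a <- randSeq(1, L)
    expect_equal(rotationalSimilarity(a, rotStr(a, sample(L, 1))), 100)
    expect_equal(rotationalSimilarity(a, rcStr(a)), 100)
    b <- randSeq(1, sample(6:300, 1))
    expect_equal(rotationalSimilarity(a, b), rotationalSimilarity(b, a))
  }
  expect_error(rotationalSimilarity("", "ACGT"), "empty")
})

test_that("one substitution in a rotated 10-mer scores 90", {
  set.seed(402)
  for (i in 1:10) {
    a <- randSeq(1, 10)
    b <- substituteBases(rotStr(a, sample(10, 1)), sample(10, 1))
    s <- rotationalSimilarity(a, b)
    expect_equal(s, bruteRotSim(a, b))
    ## the correct rotation leaves 9/10 matches, so 90 is a floor (a
    ## degenerate monomer can coincidentally score higher)
    expect_gte(s, 90 - 1e-9)
  }
})

test_that("similarity equals the all-rotations oracle for short monomers", {
  set.seed(403)
  for (i in 1:30) {
    L <- sample(6:30, 1)
    a <- randSeq(1, L)
    b <- substituteBases(rotStr(a, sample(L, 1)), sample(L, 1))
    expect_equal(rotationalSimilarity(a, b), bruteRotSim(a, b))
  }
})

test_that("classification thresholds and boundaries are exact", {
  expect_identical(classifyPair(97.6), "same_variant")
  expect_identical(classifyPair(87), "variant")
  expect_identical(classifyPair(72.5), "superfamily")
  expect_identical(classifyPair(49.9), "unrelated")
  ## boundary assignment: 95 and 80 are variants, 50 is a superfamily
  expect_identical(classifyPair(c(95, 80, 50)),
                   c("variant", "variant", "superfamily"))
  expect_error(classifyPair(101), "0, 100", fixed = TRUE)
  expect_error(classifyPair(-1), "0, 100", fixed = TRUE)
  ## total monotone step function
  x <- seq(0, 100, by = 0.5)
  lv <- match(classifyPair(x),
              c("unrelated", "superfamily", "variant", "same_variant"))
  expect_true(all(diff(lv) >= 0))
})

test_that("the published shared-satDNA table classifies consistently", {
  tab <- readSharedPairsTable(satellitomeExtdata("shared_pairs.tsv"))
  expect_equal(nrow(tab), 21L)
  map <- c(same_variant = "SV", variant = "V", superfamily = "SF")
  expect_identical(unname(map[tab$level]), tab$classification)
})

test_that("a catalog compared with itself pairs every family at 100", {
  set.seed(404)
  cat1 <- randomCatalog(4, rulRange = c(30L, 80L))
  pairs <- compareCatalogs(cat1, cat1, minShare = 50)
  self <- pairs[pairs$family_a == pairs$family_b, ]
  expect_equal(nrow(self), 4L)
  expect_true(all(self$similarity == 100))
  expect_true(all(self$level == "same_variant"))
})

test_that("cross-catalog comparison recovers shared synthetic families", {
  spec <- speciesPairSpec(
    genomeLength = 60000,
    sharedLibrary = list(plantedFamilySpec(150, 0.01, 0),
                         plantedFamilySpec(80, 0.008, 0)),
    crossSpeciesDivergence = 5,
    privateA = list(plantedFamilySpec(120, 0.005, 0)),
    privateB = list(plantedFamilySpec(200, 0.005, 0)),
    seed = 40)
  g <- generateSpeciesPair(spec)
  tA <- g$truth$speciesA$families; tB <- g$truth$speciesB$families
  catA <- assignNames(tA$consensus, tA$fraction, "Spa")
  catB <- assignNames(tB$consensus, tB$fraction, "Spb")
  pairs <- compareCatalogs(catA, catB, minShare = 50)
  shared <- g$truth$shared
  for (i in seq_len(nrow(shared))) {
    nmA <- familyNames(catA)[match(
      tA$consensus[tA$family == shared$family[i]],
      as.character(consensusSeqs(catA)))]
    nmB <- familyNames(catB)[match(
      tB$consensus[tB$family == shared$family[i]],
      as.character(consensusSeqs(catB)))]
    expect_true(any(pairs$family_a == nmA & pairs$family_b == nmB))
  }
  privA <- familyNames(catA)[match(
    tA$consensus[tA$family == "privateA01"],
    as.character(consensusSeqs(catA)))]
  expect_false(privA %in% pairs$family_a)
})

test_that("superfamily grouping reproduces the published within-catalog relations", {
  pme <- readCatalogTable(satellitomeExtdata("pme_catalog.tsv"))
  pmePairs <- read.delim(satellitomeExtdata("pme_superfamily_pairs.tsv"))
  gr <- groupSuperfamilies(pme, pairs = pmePairs)
  expect_equal(length(gr), 1L)
  expect_setequal(gr[[1]], c("PmeSat01-508", "PmeSat02-143"))
  cma <- readCatalogTable(satellitomeExtdata("cma_catalog.tsv"))
  cmaPairs <- read.delim(satellitomeExtdata("cma_superfamily_pairs.tsv"))
  gr2 <- groupSuperfamilies(cma, pairs = cmaPairs)
  expect_equal(length(gr2), 4L)
  expect_true(any(vapply(gr2, function(g)
    setequal(g, c("CmaSat02-543", "CmaSat08-285")), logical(1))))
})

test_that("superfamily grouping from sequences respects the 50-95 window", {
  set.seed(405)
  base <- randSeq(1, 100)
  related <- substituteBases(base, seq(2, 98, by = 4))  # ~75% similar
  cat1 <- assignNames(c(base, related, randSeq(1, 90)),
                      c(0.01, 0.005, 0.002), "Tst")
  sim <- rotationalSimilarity(base, related)
  expect_true(sim >= 50 && sim <= 95)
  gr <- groupSuperfamilies(cat1)
  expect_equal(length(gr), 1L)
  expect_equal(length(gr[[1]]), 2L)
  ## no pair in range: empty result
  cat2 <- assignNames(c(randSeq(1, 100), randSeq(1, 120)), c(0.01, 0.005),
                      "Tst")
  expect_equal(length(groupSuperfamilies(cat2)), 0L)
})

test_that("conservation matrix spans catalogs and orders by rank", {
  set.seed(406)
  base <- randSeq(1, 80)
  mk <- function(abbrev, extraLen) {
    v <- substituteBases(base, sample(80, 4))  # ~95%: well above 80
    assignNames(c(v, randSeq(1, extraLen)), c(0.01, 0.004), abbrev)
  }
  cats <- list(mk("Aaa", 120), mk("Bbb", 140), mk("Ccc", 160))
  m <- multiCatalogConservation(cats, minSimilarity = 80)
  expect_equal(dim(m), c(1L, 3L))
  expect_false(any(is.na(m[1, ])))
  ## two catalogs with identical consensuses: one row per family
  cat1 <- randomCatalog(3, abbrev = "Idd", rulRange = c(40L, 80L))
  cat2 <- assignNames(as.character(consensusSeqs(cat1)),
                      familyInfo(cat1)$abundance, "Jee")
  m2 <- multiCatalogConservation(list(cat1, cat2), minSimilarity = 80)
  expect_equal(nrow(m2), 3L)
  expect_error(multiCatalogConservation(list(cat1)), "2 catalogs")
})

test_that("the published conservation table summarizes as printed", {
  m <- readConservationTable(
    satellitomeExtdata("characiformes_conservation.tsv"))
  expect_equal(ncol(m), 7L)
  s <- summarizeConservation(m, focal = c("Cma", "Pme"))
  expect_equal(s$n_groups, 10L)
  expect_equal(s$n_with_both, 9L)
  expect_equal(s$max_rul, 76L)
})
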