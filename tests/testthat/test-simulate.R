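# Synthetic-data generators: determinism, injected damage statistics,
# fragment lengths, hit-table consistency, geochronological inputs.

test_that("taxonomy/reference simulation honours sizes and divergence", {
  one <- simulateTaxonomyRefs(1, 1, 1000, seed = 7)
  expect_equal(length(one$taxonomy), 4L)       # root-family-genus-species
  expect_equal(length(one$refs), 1L)

  sim <- simulateTaxonomyRefs(3, 2, 5000, seed = 1, divergence = 0.06)
  expect_equal(length(sim$speciesNodes), 6L)
  nd <- taxNodes(sim$taxonomy)
  # sibling pairwise identity matches the configured divergence within 1%
  for (g in nd$id[nd$rank == "genus"]) {
    sibs <- as.character(nd$id[nd$parent == g])
    a <- strsplit(as.character(sim$refs[[sibs[1]]]), "")[[1]]
    b <- strsplit(as.character(sim$refs[[sibs[2]]]), "")[[1]]
    expect_lt(abs(mean(a != b) - 0.06), 0.01)
  }

  sim2 <- simulateTaxonomyRefs(3, 2, 5000, seed = 1, divergence = 0.06)
  expect_identical(as.character(sim$refs), as.character(sim2$refs))
  expect_error(simulateTaxonomyRefs(0, 1, 1000), "positive")
})

test_that("read simulation is seed-deterministic with a bijective truth table", {
  sim <- simulateTaxonomyRefs(2, 2, 3000, seed = 3)
  ab <- setNames(rep(1, 4), sim$speciesNodes)
  cfg <- simulationConfig(ab, nReads = 500, seed = 11)
  r1 <- simulateReads(sim$refs, cfg)
  r2 <- simulateReads(sim$refs, cfg)
  expect_identical(as.character(r1$reads), as.character(r2$reads))
  expect_identical(r1$truth, r2$truth)
  # bijection: every emitted read appears exactly once in the truth table
  expect_setequal(names(r1$reads), r1$truth$read_id)
  expect_false(anyDuplicated(r1$truth$read_id) > 0)

  ht1 <- simulateHitTable(r1$reads, r1$truth, sim$refs, sim$taxonomy,
                          seed = 5)
  ht2 <- simulateHitTable(r2$reads, r2$truth, sim$refs, sim$taxonomy,
                          seed = 5)
  expect_identical(hits(ht1), hits(ht2))

  iso1 <- simulateIsotopePairs(2, 6.75, noiseCv = 0.05, seed = 8)
  iso2 <- simulateIsotopePairs(2, 6.75, noiseCv = 0.05, seed = 8)
  expect_identical(iso1, iso2)
})

test_that("terminal damage frequencies follow A(1-q)^(x-1)+c", {
  sim <- simulateTaxonomyRefs(1, 1, 8000, seed = 2)
  ab <- setNames(1, sim$speciesNodes)
  cfg <- simulationConfig(ab, A = 0.4, q = 0.3, c = 0.01,
                          nReads = 20000, seed = 13)
  rd <- simulateReads(sim$refs, cfg)
  # position-1 frequency ~ 0.41 within 3 binomial SE
  f1 <- terminalCTFreq(rd$reads, rd$truth, sim$refs, x = 1L)
  se <- sqrt(0.41 * 0.59 / f1$n)
  expect_lt(abs(f1$freq - 0.41), 3 * se)
  # decay into the read: positions 1, 3, 6 follow the geometric curve
  for (x in c(3L, 6L)) {
    fx <- terminalCTFreq(rd$reads, rd$truth, sim$refs, x = x)
    mu <- 0.4 * 0.7^(x - 1) + 0.01
    expect_lt(abs(fx$freq - mu), 3 * sqrt(mu * (1 - mu) / fx$n))
  }
})

test_that("full contamination reduces terminal damage to the background", {
  sim <- simulateTaxonomyRefs(1, 1, 8000, seed = 2)
  cfg <- simulationConfig(setNames(1, sim$speciesNodes), A = 0.4, q = 0.3,
                          c = 0.01, contaminationFraction = 1,
                          nReads = 20000, seed = 17)
  rd <- simulateReads(sim$refs, cfg)
  expect_true(all(!rd$truth$damaged))
  f1 <- terminalCTFreq(rd$reads, rd$truth, sim$refs, x = 1L)
  expect_lt(abs(f1$freq - 0.01), 3 * sqrt(0.01 * 0.99 / f1$n))
})

test_that("requested mean fragment length of 50 bp is realized within 5%", {
  sim <- simulateTaxonomyRefs(1, 1, 8000, seed = 2)
  cfg <- simulationConfig(setNames(1, sim$speciesNodes), fragMean = 50,
                          nReads = 5000, seed = 19)
  rd <- simulateReads(sim$refs, cfg)
  expect_lt(abs(mean(rd$truth$length) - 50) / 50, 0.05)
  expect_gte(min(rd$truth$length), 30)
})

test_that("hit tables are consistent with their mismatch lists", {
  sim <- simulateTaxonomyRefs(2, 2, 3000, seed = 4, divergence = 0.03)
  ab <- setNames(rep(1, 4), sim$speciesNodes)
  # undamaged, zero background: source hits are perfect
  cfg <- simulationConfig(ab, A = 0, q = 0.3, c = 0,
                          contaminationFraction = 1, nReads = 300,
                          seed = 23)
  rd <- simulateReads(sim$refs, cfg)
  ht <- simulateHitTable(rd$reads, rd$truth, sim$refs, sim$taxonomy,
                         seed = 29)
  h <- hits(ht)
  mm <- mismatchRecords(ht)
  own <- h[h$node == rd$truth$node[match(h$read_id, rd$truth$read_id)], ]
  expect_true(all(own$identity == 1))
  # identity == 1 - mismatches/length exactly for every hit
  nmm <- table(factor(paste(mm$read_id, mm$node),
                      levels = paste(h$read_id, h$node)))
  expect_equal(h$identity, 1 - as.numeric(nmm) / h$length)
  # sibling identity gap ~ configured divergence (3 points)
  sib <- h[h$node != rd$truth$node[match(h$read_id, rd$truth$read_id)], ]
  expect_lt(abs(mean(1 - sib$identity) - 0.03), 0.01)
  # unknown read is rejected
  bad <- rd$reads[1]
  names(bad) <- "not_in_truth"
  expect_error(simulateHitTable(bad, rd$truth, sim$refs, sim$taxonomy),
               "unknown read")
})

test_that("isotope pairs decay from the true age and histories hit the MAT", {
  cfg <- burialConfig(R0 = 6.75)
  iso0 <- simulateIsotopePairs(0, 6.75, noiseCv = 0, seed = 1)
  expect_equal(iso0$N26 / iso0$N10, rep(6.75, 3))
  tHalf <- log(2) / (cfg$lambda26 - cfg$lambda10)
  isoH <- simulateIsotopePairs(tHalf, 6.75, noiseCv = 0, seed = 1)
  expect_equal(isoH$N26 / isoH$N10, rep(6.75 / 2, 3), tolerance = 1e-12)
  expect_error(simulateIsotopePairs(-1, 6.75), ">= 0")

  h <- simulateTemperatureHistory(2e6, matC = -17, glacialCooling = 0)
  expect_true(all(h$tempK == 256.15))
})
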