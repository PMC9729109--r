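# Mismatch tallies and the beta-binomial damage / constant-rate null fit.

# tiny helper: one-read hit table against a given reference string
oneReadFixture <- function(readSeq, refSeq, node = 4L) {
  reads <- Biostrings::DNAStringSet(readSeq)
  names(reads) <- "r1"
  rc <- strsplit(readSeq, "")[[1]]
  fc <- strsplit(refSeq, "")[[1]]
  mm <- which(rc != fc)
  ht <- HitTable(
    data.frame(read_id = "r1", node = node,
               identity = 1 - length(mm) / length(rc),
               length = length(rc), strand = "+",
               stringsAsFactors = FALSE),
    if (length(mm)) data.frame(read_id = "r1", node = node, pos = mm,
                               ref = fc[mm], obs = rc[mm],
                               stringsAsFactors = FALSE) else NULL)
  list(reads = reads, ht = ht,
       asg = data.frame(read_id = "r1", node = node))
}

test_that("tallies count terminal substitutions and propagate to ancestors", {
  tax <- toyTaxonomy()
  # reference starts with C, read starts with T: one C->T at position 1
  fx <- oneReadFixture("TAAGAAAAAAAAAAAAAAAG", "CAAGAAAAAAAAAAAAAAAG")
  tal <- tallyMismatches(fx$ht, fx$asg, fx$reads, tax, K = 5)
  i <- match(4L, tal@nodes)
  expect_equal(tal@counts[i, 1, "k5"], 1)
  expect_equal(tal@counts[i, 1, "n5"], 1)
  expect_equal(sum(tal@counts[i, , "k5"]), 1)
  # G at 3' position 1 is an opportunity, not a hit
  expect_equal(tal@counts[i, 1, "n3"], 1)
  expect_equal(tal@counts[i, 1, "k3"], 0)
  # ancestors carry the subtree tallies
  for (anc in c(3L, 2L, 1L))
    expect_equal(tal@counts[match(anc, tal@nodes), 1, "k5"], 1)
  expect_error(tallyMismatches(fx$ht, fx$asg, fx$reads, tax, K = 1),
               ">= 2")
})

test_that("genus tallies equal the sum over species (subtree conservation)", {
  sim <- simulateTaxonomyRefs(1, 2, 3000, seed = 8, divergence = 0.2)
  ab <- setNames(c(1, 1), sim$speciesNodes)
  cfg <- simulationConfig(ab, nReads = 400, seed = 41)
  rd <- simulateReads(sim$refs, cfg)
  ht <- simulateHitTable(rd$reads, rd$truth, sim$refs, sim$taxonomy,
                         seed = 43, includeRelatives = FALSE)
  a <- assignReads(ht, sim$taxonomy, assignConfig(window = c(0, 1)))
  tal <- tallyMismatches(ht, a, rd$reads, sim$taxonomy)
  nd <- taxNodes(sim$taxonomy)
  g <- nd$id[nd$rank == "genus"]
  sp <- nd$id[nd$parent == g & nd$rank == "species"]
  gi <- match(g, tal@nodes)
  si <- match(sp, tal@nodes)
  expect_equal(tal@counts[gi, , ], tal@counts[si[1], , ] +
                 tal@counts[si[2], , ])
})

test_that("tally is invariant to read order and additive over batches", {
  sim <- simulateTaxonomyRefs(1, 1, 3000, seed = 9)
  cfg <- simulationConfig(setNames(1, sim$speciesNodes), nReads = 300,
                          seed = 47)
  rd <- simulateReads(sim$refs, cfg)
  ht <- simulateHitTable(rd$reads, rd$truth, sim$refs, sim$taxonomy,
                         seed = 49, includeRelatives = FALSE)
  a <- assignReads(ht, sim$taxonomy, assignConfig(window = c(0, 1)))
  tal <- tallyMismatches(ht, a, rd$reads, sim$taxonomy)
  # permuted read order
  perm <- withr::with_seed(1, sample(nrow(a)))
  talP <- tallyMismatches(ht, a[perm, ], rd$reads, sim$taxonomy)
  expect_equal(tal@counts, talP@counts)
  # split in halves and add
  h1 <- a[1:150, ]
  h2 <- a[151:300, ]
  t1 <- tallyMismatches(ht, h1, rd$reads, sim$taxonomy)
  t2 <- tallyMismatches(ht, h2, rd$reads, sim$taxonomy)
  expect_equal(tal@counts, t1@counts + t2@counts)
})

test_that("constant-rate data fit as null; damaged data recover the curve", {
  sim <- simulateTaxonomyRefs(1, 1, 6000, seed = 10)
  ab <- setNames(1, sim$speciesNodes)
  # null: no positional excess, c = 0.01, many reads
  cfg0 <- simulationConfig(ab, A = 0.4, q = 0.3, c = 0.01,
                           contaminationFraction = 1, nReads = 10000,
                           seed = 53)
  rd0 <- simulateReads(sim$refs, cfg0)
  ht0 <- simulateHitTable(rd0$reads, rd0$truth, sim$refs, sim$taxonomy,
                          seed = 59, includeRelatives = FALSE)
  a0 <- assignReads(ht0, sim$taxonomy, assignConfig(window = c(0, 1)))
  f0 <- fitDamage(tallyMismatches(ht0, a0, rd0$reads, sim$taxonomy), 1L)
  expect_lt(lambdaLR(f0), 1.5)
  expect_lt(abs(dmax(f0) - 0.01), 0.01)

  # damaged: A = 0.4, q = 0.3 recovered
  cfg1 <- simulationConfig(ab, A = 0.4, q = 0.3, c = 0.01,
                           nReads = 5000, seed = 61)
  rd1 <- simulateReads(sim$refs, cfg1)
  ht1 <- simulateHitTable(rd1$reads, rd1$truth, sim$refs, sim$taxonomy,
                          seed = 67, includeRelatives = FALSE)
  a1 <- assignReads(ht1, sim$taxonomy, assignConfig(window = c(0, 1)))
  f1 <- fitDamage(tallyMismatches(ht1, a1, rd1$reads, sim$taxonomy), 1L)
  expect_lt(abs(dmax(f1) - 0.41), 0.05)
  expect_gte(lambdaLR(f1), 1.5)
})

test_that("degenerate inputs give finite fits or clean errors", {
  tax <- toyTaxonomy()
  # zero observed mismatches anywhere: A -> 0, lambda ~ 0
  fx <- oneReadFixture(paste(rep("CAGT", 10), collapse = ""),
                       paste(rep("CAGT", 10), collapse = ""))
  # replicate the read 50 times for a stable fit
  reads <- fx$reads[rep(1, 50)]
  names(reads) <- sprintf("r%d", 1:50)
  h <- fx$ht@hits[rep(1, 50), ]
  h$read_id <- names(reads)
  ht <- HitTable(h)
  asg <- data.frame(read_id = names(reads), node = 4L)
  f <- fitDamage(tallyMismatches(ht, asg, reads, tax), 4L)
  expect_lt(f@A, 0.01)
  expect_lt(lambdaLR(f), 0.1)
  expect_true(is.finite(dmax(f)))
  # node with no opportunities errors
  tal <- tallyMismatches(ht, asg, reads, tax)
  expect_error(fitDamage(tal, 6L), "opportunities|undefined")
})

test_that("lambda-LR grows with injected damage strength", {
  sim <- simulateTaxonomyRefs(1, 1, 4000, seed = 12)
  ab <- setNames(1, sim$speciesNodes)
  lrs <- vapply(c(0, 0.1, 0.25, 0.4), function(A) {
    cfg <- simulationConfig(ab, A = max(A, 1e-9), q = 0.3, c = 0.01,
                            contaminationFraction = as.numeric(A == 0),
                            nReads = 3000, seed = 71)
    rd <- simulateReads(sim$refs, cfg)
    ht <- simulateHitTable(rd$reads, rd$truth, sim$refs, sim$taxonomy,
                           seed = 73, includeRelatives = FALSE)
    a <- assignReads(ht, sim$taxonomy, assignConfig(window = c(0, 1)))
    lambdaLR(fitDamage(tallyMismatches(ht, a, rd$reads, sim$taxonomy), 1L))
  }, 0)
  expect_true(all(diff(lrs) > 0))
  expect_true(all(lrs >= 0))
})

test_that("authenticity thresholds apply as stated", {
  mk <- function(d, l) new("DamageFit", node = 1L, A = d - 0.005,
                           q = 0.3, c = 0.005, phi = 100, dmax = d,
                           lambdaLR = l, nReads = 1000L, logLik = 0,
                           logLikNull = -l / 2)
  expect_true(classifyAuthentic(mk(0.407, 10)))
  expect_false(classifyAuthentic(mk(0.24, 10)))
  expect_false(classifyAuthentic(mk(0.40, 1.49)))
  expect_true(classifyAuthentic(mk(0.25, 1.5)))   # inclusive bounds
  df <- data.frame(dmax = c(0.407, 0.24), lambda_LR = c(10, 10))
  expect_equal(classifyAuthentic(df), c(TRUE, FALSE))
})
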