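# Reference-genome validation statistics and the retention filter.

test_that("uniform tiling yields breadth ratio ~1 and evenness 1", {
  gl <- 1000L
  # depth exactly 2 everywhere: the same tiling on both strands
  aln <- do.call(rbind, lapply(c("+", "-"), function(s)
    data.frame(start = seq(1, gl, by = 100), end = seq(100, gl, by = 100),
               strand = s, ani = 98)))
  st <- referenceMapStats(aln, gl)
  expect_equal(st$breadth, 1)
  expect_equal(st$expectedBreadth, 1 - exp(-2))
  expect_equal(st$breadthRatio, 1)
  expect_equal(st$evenness, 1)
})

test_that("a single read matches the Poisson closed form", {
  st <- referenceMapStats(
    data.frame(start = 101, end = 200, strand = "+", ani = 99), 10000L)
  expect_equal(st$breadth, 0.01)
  expect_equal(st$expectedBreadth, 1 - exp(-0.01))
  expect_equal(st$breadthRatio, 1)   # 0.01 / (1 - e^-0.01) > 1, capped
  expect_equal(st$reads, 1L)
})

test_that("duplicates collapse and identical reads give 100% ANI", {
  aln <- data.frame(start = c(1, 1, 1, 201), end = c(100, 100, 100, 300),
                    strand = c("+", "+", "-", "+"), ani = 100)
  st <- referenceMapStats(aln, 1000L)
  expect_equal(st$reads, 3L)         # two identical (+) rows collapse
  expect_equal(st$meanANI, 100)
  st0 <- referenceMapStats(data.frame(start = numeric(), end = numeric(),
                                      strand = character(),
                                      ani = numeric()), 1000L)
  expect_true(st0$flagged)
  expect_equal(st0$reads, 0L)
})

test_that("evenness decreases as depth concentrates", {
  flat <- rep(4L, 100)
  expect_equal(coverageEvenness(flat), 1)
  # same total depth on fewer positions
  lumpy1 <- c(rep(8L, 50), rep(0L, 50))
  lumpy2 <- c(rep(16L, 25), rep(0L, 75))
  e <- c(coverageEvenness(flat), coverageEvenness(lumpy1),
         coverageEvenness(lumpy2))
  expect_true(all(diff(e) < 0))
  # low coverage falls back to breadth
  expect_equal(coverageEvenness(c(1L, rep(0L, 9))), 0.1)
})

test_that("breadth ratio is invariant to proportional rescaling", {
  aln <- data.frame(start = c(1, 301), end = c(200, 400), strand = "+",
                    ani = 97)
  st1 <- referenceMapStats(aln, 1000L)
  aln2 <- data.frame(start = c(1, 601), end = c(400, 800), strand = "+",
                     ani = 97)
  st2 <- referenceMapStats(aln2, 2000L)
  expect_equal(st1$breadthRatio, st2$breadthRatio, tolerance = 1e-9)
})

test_that("elbow detection matches the exhaustive chord-distance oracle", {
  # straight line: ties broken toward the lowest interior cutoff
  expect_equal(aniElbow(90:100, seq(1000, 0, by = -100)), 91)
  # hockey stick: a flat shoulder, a cliff, then a slow tail; the corner
  # sits at 93 (verified by exhaustive chord-distance computation)
  cut <- 90:100
  reads <- c(5000, 4975, 4950, 400, 320, 260, 210, 160, 120, 80, 50)
  expect_equal(aniElbow(cut, reads), 93)
  # brute-force oracle on convex curves
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(5:15, 1)
      cuts <- sort(sample(80:100, n))
      y <- sort(exp(runif(n, 0, 5)), decreasing = TRUE)
      x01 <- (cuts - cuts[1]) / (cuts[n] - cuts[1])
      y01 <- (y - min(y)) / diff(range(y))
      dist <- vapply(seq_len(n), function(j) {
        p1 <- c(x01[1], y01[1]); p2 <- c(x01[n], y01[n])
        v <- p2 - p1
        w <- c(x01[j], y01[j]) - p1
        abs(v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))
      }, 0)
      best <- cuts[setdiff(order(-dist), c(1, n))[1]]
      expect_equal(aniElbow(cuts, y), best, info = sprintf("case %d", i))
    }
  })
  expect_error(aniElbow(c(90, 95), c(1, 2)), ">= 3")
})

test_that("genome retention applies the stated boundary semantics", {
  base <- data.frame(genome = "g", reads = 600L, meanANI = 95,
                     breadth = 0.8, expectedBreadth = 0.9,
                     breadthRatio = 0.9, evenness = 0.9, flagged = FALSE)
  fits <- data.frame(genome = "g", dmax = 0.4, lambda_LR = 5)
  expect_true(selectGenomes(base, fits)$retained)
  low <- base; low$reads <- 499L
  expect_false(selectGenomes(low, fits)$retained)
  expect_equal(selectGenomes(low, fits)$rule, "min_reads")
  ani <- base; ani$meanANI <- 92.9
  expect_false(selectGenomes(ani, fits)$retained)
  # equality passes the >= thresholds; lambda-LR is strict
  eq <- base; eq$meanANI <- 93; eq$breadthRatio <- 0.75
  eq$evenness <- 0.75
  fitsEq <- data.frame(genome = "g", dmax = 0.25, lambda_LR = 1.5001)
  expect_true(selectGenomes(eq, fitsEq)$retained)
  fitsLR <- data.frame(genome = "g", dmax = 0.25, lambda_LR = 1.5)
  expect_false(selectGenomes(eq, fitsLR)$retained)
})
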