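# Thermal-age integration, depurination fragment length, and 26Al/10Be
# burial dating.

test_that("Arrhenius rate ratio matches hand-evaluated values", {
  cfg <- thermalConfig()
  expect_equal(arrheniusRatio(283.15, cfg), 1)
  expect_equal(arrheniusRatio(300, thermalConfig(Ea = 0)), 1)
  # -17 C vs 10 C at Ea = 127 kJ/mol: exponent -15274.6 * 3.72264e-4,
  # hand-evaluated ratio ~ 1/295
  r <- arrheniusRatio(256.15, cfg)
  expect_equal(1 / r, 295, tolerance = 0.01)
  expect_error(arrheniusRatio(-5), "> 0")
})

test_that("thermal age integrates closed-form histories exactly", {
  cfg <- thermalConfig()
  hRef <- temperatureHistory(c(0, 1e4), c(283.15, 283.15))
  expect_equal(thermalAge(hRef, 1000, cfg), 1000, tolerance = 1e-9)
  # constant -17 C over 2 Myr
  hCold <- temperatureHistory(c(0, 2e6), c(256.15, 256.15))
  tau <- thermalAge(hCold, 2e6, cfg)
  expect_equal(tau, 2e6 * arrheniusRatio(256.15, cfg), tolerance = 1e-9)
  # two-segment step history: half at Tref, half at rate ratio 0.5
  Thalf <- 1 / (1 / 283.15 + cfg$R * log(2) / cfg$Ea)
  h2 <- temperatureHistory(c(0, 1000, 2000), c(283.15, Thalf, Thalf),
                           interpolation = "constant")
  expect_equal(thermalAge(h2, 2000, cfg), 1500, tolerance = 1e-6)
  # additivity over concatenated spans and linearity in duration
  expect_equal(thermalAge(hCold, 2e6, cfg),
               thermalAge(hCold, 1.2e6, cfg) +
                 0.8e6 * arrheniusRatio(256.15, cfg), tolerance = 1e-6)
  # altitude correction cools the history before integrating
  cfgAlt <- thermalConfig(altitudeKm = 1)
  expect_equal(thermalAge(hRef, 1000, cfgAlt),
               1000 * arrheniusRatio(283.15 - 6.49, cfg),
               tolerance = 1e-9)
  expect_error(thermalAge(hRef, 2e4, cfg), "shorter")
})

test_that("expected fragment length is 1/(k tau)", {
  expect_equal(expectedFragmentLength(1e-5, 2000), 50)  # k*tau = 0.02
  expect_equal(expectedFragmentLength(0.5, 2), 1)
  expect_equal(expectedFragmentLength(1e-5, 4000),
               expectedFragmentLength(1e-5, 2000) / 2)
  expect_error(expectedFragmentLength(0, 10), "k")
})

test_that("burial-age point estimates follow the closed form", {
  cfg <- burialConfig(R0 = 6.75)
  expect_equal(burialAgePoint(6.75e4, 1e4, cfg), 0)
  # R0/2: ln 2 / (l26 - l10) = 0.705*1.387/(1.387-0.705) = 1.4338 Myr
  tHalf <- burialAgePoint(6.75e4 / 2, 1e4, cfg)
  expect_equal(tHalf, 1.4338, tolerance = 1e-4)
  # ratio above R0 clamps to 0 with a flag
  flagged <- burialAgePoint(7e4, 1e4, cfg)
  expect_equal(as.numeric(flagged), 0)
  expect_match(attr(flagged, "flag"), "post-burial")
  # strictly decreasing in R, increasing in R0_eff
  ages <- burialAgePoint(c(6e4, 5e4, 4e4), rep(1e4, 3), cfg)
  expect_true(all(diff(ages) > 0))
  # steady erosion lowers the effective initial ratio, hence the age
  cfgE <- burialConfig(R0 = 6.75, erosion = "steady", erosionRate = 1e-3)
  expect_lt(burialAgePoint(5e4, 1e4, cfgE), burialAgePoint(5e4, 1e4, cfg))
  # inverse consistency at zero noise
  for (t in c(0.5, 1.7, 3.2)) {
    R <- 6.75 * exp(-t * (cfg$lambda26 - cfg$lambda10))
    expect_equal(burialAgePoint(R * 1e4, 1e4, cfg), t, tolerance = 1e-10)
  }
})

test_that("age PDFs integrate to one and combine like Gaussian products", {
  grid <- seq(0, 6, by = 0.005)
  g <- gaussianAgePDF(grid, 2.0, 0.2)
  expect_equal(trapezoid(ageGrid(g), ageDensity(g)), 1, tolerance = 1e-9)
  comb <- combinePDFs(list(g, g, g))
  s <- summaryStats(comb)
  # three identical N(mu, s^2) multiply to N(mu, s^2/3)
  sdComb <- (s[["hi1s"]] - s[["lo1s"]]) / 2
  expect_equal(sdComb, 0.2 / sqrt(3), tolerance = 0.02)
  expect_equal(s[["median"]], 2.0, tolerance = 0.005)
  # commutative and associative
  h <- gaussianAgePDF(grid, 2.3, 0.3)
  ab <- combinePDFs(list(combinePDFs(list(g, h))))
  ba <- combinePDFs(list(h, g))
  expect_equal(ageDensity(combinePDFs(list(g, h))), ageDensity(ba),
               tolerance = 1e-9)
  # disjoint support errors
  far <- gaussianAgePDF(grid, 0.2, 0.01)
  expect_error(combinePDFs(list(far, gaussianAgePDF(grid, 5.8, 0.01))),
               "inconsistent")
})

test_that("Monte-Carlo PDFs recover the generating age", {
  cfg <- burialConfig(R0 = 6.75)
  pair <- simulateIsotopePairs(2.0, 6.75, noiseCv = 0.05, nSamples = 1,
                               seed = 3)
  pdf <- burialAgePDF(pair, cfg, nDraws = 5e4, seed = 4)
  s <- summaryStats(pdf)
  # one sample at cv 5%: age sd ~ sqrt(2)*0.05/0.4834 ~ 0.146 Myr
  expect_lt(abs(s[["median"]] - 2.0), 3 * 0.15)
  expect_equal(s[["hi1s"]] - s[["lo1s"]], 2 * 0.146, tolerance = 0.25)
  # seed determinism
  pdf2 <- burialAgePDF(pair, cfg, nDraws = 5e4, seed = 4)
  expect_identical(ageDensity(pdf), ageDensity(pdf2))
})

test_that("endmember summary takes the midpoint of the extreme 3-sigma limits", {
  grid <- seq(0, 6, by = 0.005)
  a <- gaussianAgePDF(grid, 2.0, 0.1)
  b <- gaussianAgePDF(grid, 2.4, 0.1)
  s <- summarizeMaxAge(list(a, b))
  expect_equal(s[["lo3s"]], 2.0 - 0.3, tolerance = 0.01)
  expect_equal(s[["hi3s"]], 2.4 + 0.3, tolerance = 0.01)
  expect_equal(s[["midpoint"]], 2.2, tolerance = 0.01)
  expect_equal(s[["halfRange"]], 0.5, tolerance = 0.01)
})
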