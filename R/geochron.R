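# Geochronological calculators: Arrhenius thermal age of DNA, expected
# fragment length under depurination kinetics, and 26Al/10Be simple
# burial dating with Monte-Carlo uncertainty and combined age PDFs.

#' Thermal-age configuration
#'
#' @param Ea activation energy for DNA depurination, J/mol (default
#'   127 kJ/mol).
#' @param Tref reference temperature in kelvin (default 283.15 K = 10 C,
#'   the convention thermal ages are quoted at).
#' @param lapseRate environmental lapse rate, K per km (default 6.49).
#' @param altitudeKm site altitude in km; the whole temperature history is
#'   cooled by \code{lapseRate * altitudeKm} before integration.
#' @param R gas constant, J/(mol K).
#' @return a validated list of class \code{"ThermalConfig"}.
#' @export
thermalConfig <- function(Ea = 127e3, Tref = 283.15, lapseRate = 6.49,
                          altitudeKm = 0, R = 8.31446) {
  .assertScalarNumber(Ea, "Ea", 0, Inf)
  .assertScalarNumber(Tref, "Tref", 1e-9, Inf)
  structure(list(Ea = Ea, Tref = Tref, lapseRate = lapseRate,
                 altitudeKm = altitudeKm, R = R),
            class = "ThermalConfig")
}

#' Arrhenius rate ratio k(T)/k(Tref)
#'
#' @param T temperature(s) in kelvin (> 0).
#' @param config a [thermalConfig()].
#' @return \eqn{\exp(-Ea/R \cdot (1/T - 1/T_{ref}))}; 1 at
#'   \eqn{T = T_{ref}} and for \eqn{Ea = 0}.
#' @examples
#' arrheniusRatio(256.15)     # -17 C vs 10 C: about 1/295
#' @export
arrheniusRatio <- function(T, config = thermalConfig()) {
  if (any(T <= 0)) stop("'T' must be > 0 K", call. = FALSE)
  exp(-config$Ea / config$R * (1 / T - 1 / config$Tref))
}

#' Thermal age of a deposit
#'
#' Integrates the Arrhenius rate ratio over the site's temperature
#' history: \eqn{\tau = \int_0^{dur} k(T(t))/k(T_{ref})\,dt}, giving the
#' equivalent number of years at the reference temperature.  Step
#' ("constant") histories are integrated segment-exactly; linear
#' histories by the trapezoid rule on the rate over a refined grid.  The
#' altitude correction is applied to the whole history first.
#'
#' @param history a [temperatureHistory()] spanning at least
#'   \code{durationYr}.
#' @param durationYr deposit age in years.
#' @param config a [thermalConfig()].
#' @param gridN refinement for linear interpolation (ignored for step
#'   histories).
#' @return thermal age in years at \code{Tref}.
#' @examples
#' h <- temperatureHistory(c(0, 2e6), c(256.15, 256.15))
#' thermalAge(h, 2e6)          # about 2e6 / 295 years
#' @export
thermalAge <- function(history, durationYr, config = thermalConfig(),
                       gridN = 2048L) {
  stopifnot(inherits(history, "TemperatureHistory"))
  .assertScalarNumber(durationYr, "durationYr", 1e-12, Inf)
  if (max(history$time) < durationYr)
    stop("temperature history shorter than requested duration",
         call. = FALSE)
  tempK <- history$tempK - config$lapseRate * config$altitudeKm
  interp <- attr(history, "interpolation")
  if (identical(interp, "constant")) {
    # left-continuous step function: T(t) = tempK[i] on [time[i], time[i+1])
    bounds <- sort(unique(c(history$time[history$time < durationYr],
                            durationYr)))
    idx <- findInterval(bounds[-length(bounds)], history$time)
    return(sum(arrheniusRatio(tempK[idx], config) * diff(bounds)))
  }
  tt <- sort(unique(c(seq(0, durationYr, length.out = gridN),
                      history$time[history$time <= durationYr])))
  Tt <- approx(history$time, tempK, xout = tt, rule = 2)$y
  trapz(tt, arrheniusRatio(Tt, config))
}

#' Expected surviving fragment length under depurination
#'
#' With cumulative depurination-driven strand breaks at site rate
#' \eqn{k} (per site per year at the reference temperature) over thermal
#' age \eqn{\tau}, the mean surviving fragment length is
#' \eqn{1/(k \tau)} bp.
#'
#' @param k strand-break rate per site per year at the reference
#'   temperature (> 0).
#' @param thermalAgeYr thermal age in years (> 0).
#' @return expected mean fragment length in bp.
#' @examples
#' expectedFragmentLength(1e-5, 2000)  # k*tau = 0.02 -> 50 bp
#' @export
expectedFragmentLength <- function(k, thermalAgeYr) {
  .assertScalarNumber(k, "k", 1e-300, Inf)
  .assertScalarNumber(thermalAgeYr, "thermalAgeYr", 1e-300, Inf)
  1 / (k * thermalAgeYr)
}

# ---- 26Al/10Be simple burial dating ----------------------------------

#' Burial-dating configuration
#'
#' @param R0 surface 26Al:10Be production ratio; the endmembers used for
#'   the convolved age range are 6.75 and 7.42.
#' @param halfLife26,halfLife10 radionuclide half-lives in Myr (defaults
#'   0.705 and 1.387).
#' @param erosion \code{"zero"} or \code{"steady"}.
#' @param erosionRate steady-state surface erosion rate, cm/yr.
#' @param rho regolith density, g/cm^3.
#' @param Lambda nucleon attenuation length, g/cm^2.
#' @param ageGrid age grid in Myr for PDFs (default 0-6 Myr at 0.005).
#' @return a validated list of class \code{"BurialConfig"} with derived
#'   decay constants \code{lambda26}, \code{lambda10} (1/Myr).
#' @export
burialConfig <- function(R0 = 6.75, halfLife26 = 0.705,
                         halfLife10 = 1.387,
                         erosion = c("zero", "steady"),
                         erosionRate = 0, rho = 2.65, Lambda = 160,
                         ageGrid = seq(0, 6, by = 0.005)) {
  erosion <- match.arg(erosion)
  if (R0 <= 1) stop("'R0' must be > 1", call. = FALSE)
  l26 <- log(2) / halfLife26
  l10 <- log(2) / halfLife10
  if (!(l26 > l10))
    stop("26Al must decay faster than 10Be", call. = FALSE)
  structure(list(R0 = R0, lambda26 = l26, lambda10 = l10,
                 erosion = erosion, erosionRate = erosionRate, rho = rho,
                 Lambda = Lambda, ageGrid = ageGrid),
            class = "BurialConfig")
}

# Effective initial ratio at burial.  Under steady pre-burial erosion the
# surface inventory ratio is R0 * (lambda10 + rho*eps/Lambda) /
# (lambda26 + rho*eps/Lambda) <= R0.
.effectiveR0 <- function(config) {
  if (config$erosion == "zero") return(config$R0)
  mu <- config$rho * config$erosionRate / config$Lambda * 1e6  # 1/Myr
  config$R0 * (config$lambda10 + mu) / (config$lambda26 + mu)
}

#' Point estimate of a simple burial age
#'
#' \eqn{t = \ln(R_{0,eff}/R) / (\lambda_{26} - \lambda_{10})} where
#' \eqn{R = N_{26}/N_{10}} is the measured ratio and \eqn{R_{0,eff}} the
#' (erosion-adjusted) initial ratio.  A measured ratio above
#' \eqn{R_{0,eff}} (post-burial production or inheritance) returns age 0
#' with attribute \code{flag}.
#'
#' @param N26,N10 measured concentrations (atoms/g), or a one-row
#'   data.frame with columns \code{N26}, \code{N10} as \code{N26}.
#' @param config a [burialConfig()].
#' @return burial age in Myr (attribute \code{flag} set when clamped).
#' @examples
#' cfg <- burialConfig(R0 = 6.75)
#' burialAgePoint(6.75 / 2 * 1e4, 1e4, cfg)   # ln 2 / (l26 - l10) = 1.434
#' @export
burialAgePoint <- function(N26, N10 = NULL, config = burialConfig()) {
  if (is.data.frame(N26)) {
    N10 <- N26$N10
    N26 <- N26$N26
  }
  R <- N26 / N10
  R0eff <- .effectiveR0(config)
  flagged <- R > R0eff
  t <- log(R0eff / pmin(R, R0eff)) / (config$lambda26 - config$lambda10)
  if (any(flagged))
    attr(t, "flag") <- "post-burial production or inheritance"
  t
}

#' Monte-Carlo burial-age PDF for one sample
#'
#' Propagates the measurement uncertainties of (N10, N26) through
#' [burialAgePoint()]: concentrations are drawn from independent normals,
#' non-positive draws rejected, and the resulting ages binned onto the
#' configured age grid.
#'
#' @param pair one-row data.frame with \code{N10}, \code{sN10},
#'   \code{N26}, \code{sN26}.
#' @param config a [burialConfig()].
#' @param nDraws Monte-Carlo draws (default 1e5).
#' @param seed integer seed.
#' @return an [AgePDF-class].
#' @export
burialAgePDF <- function(pair, config = burialConfig(), nDraws = 1e5,
                         seed = 1L) {
  withSeed(seed, {
    n26 <- rnorm(nDraws, pair$N26, pair$sN26)
    n10 <- rnorm(nDraws, pair$N10, pair$sN10)
    ok <- n26 > 0 & n10 > 0
    ages <- burialAgePoint(n26[ok], n10[ok], config)
    grid <- config$ageGrid
    step <- diff(grid[1:2])
    breaks <- c(grid - step / 2, max(grid) + step / 2)
    cnt <- tabulate(findInterval(pmin(ages, max(breaks) - 1e-12), breaks),
                    nbins = length(grid))
    AgePDF(grid, cnt / (sum(cnt) * step))
  })
}

#' Combine age PDFs as a joint constraint
#'
#' Pointwise product of the densities on a shared grid, renormalized --
#' the convolved probability distribution for several samples
#' constraining a single common burial age.  Commutative and associative.
#'
#' @param pdfs list of [AgePDF-class] objects on identical grids.
#' @return an [AgePDF-class]; PDFs with disjoint support raise an error.
#' @export
combinePDFs <- function(pdfs) {
  if (!length(pdfs)) stop("no PDFs to combine", call. = FALSE)
  grid <- ageGrid(pdfs[[1]])
  dens <- rep(1, length(grid))
  for (p in pdfs) {
    if (!isTRUE(all.equal(ageGrid(p), grid)))
      stop("PDFs must share the age grid", call. = FALSE)
    dens <- dens * ageDensity(p)
  }
  if (all(dens == 0) || trapz(grid, dens) <= 0)
    stop("inconsistent samples: combined PDF has no support",
         call. = FALSE)
  AgePDF(grid, dens)
}

#' Summary statistics of an age PDF
#'
#' @param pdf an [AgePDF-class].
#' @return named vector: \code{mode}, \code{median}, \code{lo1s},
#'   \code{hi1s}, \code{lo3s}, \code{hi3s} (quantiles at the Gaussian
#'   1-sigma and 3-sigma tail probabilities).
#' @export
summaryStats <- function(pdf) {
  stopifnot(is(pdf, "AgePDF"))
  g <- ageGrid(pdf)
  d <- ageDensity(pdf)
  cdf <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * diff(g)))
  cdf <- cdf / cdf[length(cdf)]
  qat <- function(p) {
    i <- findInterval(p, cdf, all.inside = TRUE)
    w <- (p - cdf[i]) / max(cdf[i + 1] - cdf[i], 1e-300)
    g[i] + w * (g[i + 1] - g[i])
  }
  c(mode = g[which.max(d)], median = qat(0.5),
    lo1s = qat(pnorm(-1)), hi1s = qat(pnorm(1)),
    lo3s = qat(pnorm(-3)), hi3s = qat(pnorm(3)))
}

#' @importFrom stats pnorm
NULL

#' Maximum-age summary across endmember scenarios
#'
#' Given combined PDFs for the endmember production ratios and erosion
#' scenarios, takes the midpoint between the lowest -3 sigma limit and
#' the highest +3 sigma limit across scenarios.
#'
#' @param pdfs list of combined [AgePDF-class] objects, one per
#'   endmember scenario.
#' @return named vector: \code{midpoint}, \code{halfRange}, \code{lo3s},
#'   \code{hi3s} (all Myr).
#' @export
summarizeMaxAge <- function(pdfs) {
  stats <- vapply(pdfs, summaryStats, numeric(6))
  lo <- min(stats["lo3s", ])
  hi <- max(stats["hi3s", ])
  c(midpoint = (lo + hi) / 2, halfRange = (hi - lo) / 2,
    lo3s = lo, hi3s = hi)
}
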