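# Reference-genome validation statistics for marine eukaryotic
# metagenome-assembled genomes (SMAGs): mean read ANI, breadth-of-coverage
# ratio against the Poisson expectation, coverage evenness, data-driven
# ANI cutoff by elbow detection, and the retention filter.

#' Coverage evenness score
#'
#' \eqn{E = (1/\lfloor \bar d \rfloor) \sum_{i=1}^{\lfloor \bar d \rfloor}
#' F_i} where \eqn{F_i} is the fraction of genome positions with depth at
#' least \eqn{i} and \eqn{\bar d} is the mean depth; when
#' \eqn{\bar d < 1}, \eqn{E = F_1}.  Perfectly uniform coverage gives 1;
#' concentrating the same total depth on fewer positions lowers the score.
#'
#' @param depth integer vector of per-position depths.
#' @return evenness in [0, 1].
#' @export
coverageEvenness <- function(depth) {
  if (!length(depth) || all(depth == 0)) return(0)
  dbar <- mean(depth)
  if (dbar < 1) return(mean(depth >= 1))
  m <- floor(dbar)
  mean(vapply(seq_len(m), function(i) mean(depth >= i), 0))
}

#' Mapping statistics for one reference genome
#'
#' Computes reads mapped, mean read ANI, breadth of coverage, the
#' Poisson-expected breadth \eqn{1 - e^{-\bar d}}, their ratio (capped at
#' 1) and the coverage evenness.  Alignments with identical start, end and
#' strand are collapsed as duplicates before depth is computed.
#'
#' @param alignments data.frame with columns \code{start}, \code{end}
#'   (1-based, inclusive), \code{strand} and \code{ani} (percent).
#' @param genomeLength reference length in bp (> 0).
#' @param genome optional genome id copied into the result.
#' @return one-row data.frame: \code{genome}, \code{reads}, \code{meanANI},
#'   \code{breadth}, \code{expectedBreadth}, \code{breadthRatio},
#'   \code{evenness}, \code{flagged} (TRUE when no reads mapped).
#' @examples
#' aln <- data.frame(start = c(1, 51), end = c(60, 110), strand = "+",
#'                   ani = c(98, 97))
#' referenceMapStats(aln, genomeLength = 1000)
#' @export
referenceMapStats <- function(alignments, genomeLength, genome = NA) {
  if (genomeLength <= 0) stop("'genomeLength' must be > 0", call. = FALSE)
  a <- alignments
  if (!is.null(a) && nrow(a)) {
    if (is.null(a$strand)) a$strand <- "+"
    a <- a[!duplicated(a[, c("start", "end", "strand")]), , drop = FALSE]
  }
  if (is.null(a) || !nrow(a)) {
    return(data.frame(genome = genome, reads = 0L, meanANI = 0,
                      breadth = 0, expectedBreadth = 0, breadthRatio = 0,
                      evenness = 0, flagged = TRUE,
                      stringsAsFactors = FALSE))
  }
  # depth by difference array
  delta <- numeric(genomeLength + 1L)
  s <- pmax(1L, as.integer(a$start))
  e <- pmin(genomeLength, as.integer(a$end))
  for (i in seq_along(s)) {
    delta[s[i]] <- delta[s[i]] + 1
    delta[e[i] + 1L] <- delta[e[i] + 1L] - 1
  }
  depth <- cumsum(delta[seq_len(genomeLength)])
  breadth <- mean(depth >= 1)
  dbar <- sum(e - s + 1) / genomeLength
  expBreadth <- 1 - exp(-dbar)
  data.frame(genome = genome, reads = nrow(a),
             meanANI = mean(a$ani),
             breadth = breadth, expectedBreadth = expBreadth,
             breadthRatio = min(1, breadth / expBreadth),
             evenness = coverageEvenness(depth), flagged = FALSE,
             stringsAsFactors = FALSE)
}

#' Elbow point of a reads-vs-ANI-cutoff curve
#'
#' Returns the cutoff maximizing the perpendicular distance to the chord
#' joining the curve's endpoints; distance ties are broken toward the
#' lower cutoff, and the endpoints themselves are never returned (a
#' straight line yields the first interior point).
#'
#' @param cutoffs ascending ANI cutoffs (percent); at least 3 points.
#' @param reads mapped-read counts at each cutoff.
#' @return the elbow cutoff.
#' @export
aniElbow <- function(cutoffs, reads) {
  n <- length(cutoffs)
  if (n < 3L || length(reads) != n)
    stop("need >= 3 (cutoff, reads) points", call. = FALSE)
  if (any(diff(cutoffs) <= 0))
    stop("'cutoffs' must be ascending", call. = FALSE)
  # scale both axes to [0,1] so the distance is unit-free
  x <- (cutoffs - cutoffs[1]) / (cutoffs[n] - cutoffs[1])
  y <- if (diff(range(reads)) > 0)
    (reads - min(reads)) / diff(range(reads)) else rep(0, n)
  dx <- x[n] - x[1]
  dy <- y[n] - y[1]
  d <- abs(dy * x - dx * y + dx * y[1] - dy * x[1]) / sqrt(dx^2 + dy^2)
  interior <- 2:(n - 1L)
  cutoffs[interior[which.max(d[interior])]]
}

#' Marine reference-genome retention filter
#'
#' Retains a genome iff reads mapped >= \code{minReads}, mean read ANI >=
#' \code{minANI}, breadth ratio >= \code{minBreadthRatio}, evenness >=
#' \code{minEvenness}, D-max >= \code{dmaxMin} and lambda-LR strictly >
#' \code{lrMin} (boundary semantics follow the removal rules: strictly
#' below a threshold is removed).
#'
#' @param stats data.frame of per-genome statistics (rows as returned by
#'   [referenceMapStats()]).
#' @param fits data.frame with columns \code{genome}, \code{dmax},
#'   \code{lambda_LR}.
#' @param minReads,minANI,minBreadthRatio,minEvenness,dmaxMin,lrMin
#'   thresholds; defaults are the study's.
#' @return \code{stats} with added columns \code{dmax}, \code{lambda_LR},
#'   \code{retained} and \code{rule} (first failing rule, or "pass").
#' @export
selectGenomes <- function(stats, fits, minReads = 500L, minANI = 93,
                          minBreadthRatio = 0.75, minEvenness = 0.75,
                          dmaxMin = 0.25, lrMin = 1.5) {
  i <- match(stats$genome, fits$genome)
  if (anyNA(i))
    stop("damage fits missing for some genomes", call. = FALSE)
  stats$dmax <- fits$dmax[i]
  stats$lambda_LR <- fits$lambda_LR[i]
  rule <- rep("pass", nrow(stats))
  rule[stats$lambda_LR <= lrMin] <- "lambda_LR"
  rule[stats$dmax < dmaxMin] <- "dmax"
  rule[stats$evenness < minEvenness] <- "evenness"
  rule[stats$breadthRatio < minBreadthRatio] <- "breadth_ratio"
  rule[stats$meanANI < minANI] <- "mean_ani"
  rule[stats$reads < minReads] <- "min_reads"
  stats$retained <- rule == "pass"
  stats$rule <- rule
  stats
}
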