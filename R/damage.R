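# Positional deamination tallies and the damage-vs-null likelihood test.
#
# Ancient molecules show an excess of C->T substitutions at the 5' terminus
# (and the complementary G->A at the 3' terminus) decaying geometrically
# into the read.  Per taxonomic node we tally, at positions 1..K from each
# end, the substitution count k out of n aligned reference
# cytosines/guanines, fit f(x) = A(1-q)^(x-1) + c under beta-binomial
# sampling, and compare it with a constant-rate null f(x) = c by the
# likelihood-ratio statistic lambda-LR = 2 * delta log-likelihood.

#' Tally terminal substitutions per taxonomic node
#'
#' Uses, for each assigned read, its best hit (highest identity; ties go
#' to the lowest node id) and reconstructs the aligned reference from the
#' read sequence plus the hit's mismatch list.  For reverse-strand
#' alignments, bases are complemented so substitutions are counted in the
#' read's 5'->3' frame.  Counts are accumulated at the read's assigned
#' node and at all of its ancestors, so a node's matrix covers all reads
#' in its subtree.
#'
#' @param hitTable a [HitTable-class].
#' @param assignments data.frame from [assignReads()].
#' @param reads named \code{DNAStringSet} holding the read sequences.
#' @param taxonomy a [Taxonomy-class].
#' @param K number of terminal positions per end (default 15; must be
#'   >= 2).
#' @return a [MismatchMatrix-class].
#' @export
tallyMismatches <- function(hitTable, assignments, reads, taxonomy,
                            K = 15L) {
  if (K < 2L) stop("'K' must be >= 2", call. = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  h <- hits(hitTable)
  mm <- mismatchRecords(hitTable)
  a <- assignments[!is.na(assignments$node), , drop = FALSE]
  nd <- taxNodes(taxonomy)
  nodeIds <- nd$id
  counts <- array(0, dim = c(length(nodeIds), K, 4L),
                  dimnames = list(as.character(nodeIds), NULL,
                                  c("k5", "n5", "k3", "n3")))
  nReads <- integer(length(nodeIds))
  names(nReads) <- as.character(nodeIds)
  # ancestor paths once per distinct assigned node
  paths <- lapply(unique(a$node), function(id)
    as.character(ancestorsOf(taxonomy, id)))
  names(paths) <- as.character(unique(a$node))
  mmKey <- split(seq_len(nrow(mm)), paste(mm$read_id, mm$node))
  readSplit <- strsplit(as.character(reads), "")
  names(readSplit) <- names(reads)
  # best hit per read: highest identity, ties to the lowest node id
  hOrd <- h[order(h$read_id, -h$identity, h$node), , drop = FALSE]
  bestPerRead <- hOrd[!duplicated(hOrd$read_id), , drop = FALSE]
  bestIdx <- match(a$read_id, bestPerRead$read_id)
  bestNode <- bestPerRead$node[bestIdx]
  bestStrand <- bestPerRead$strand[bestIdx]
  for (i in seq_len(nrow(a))) {
    rid <- a$read_id[i]
    s <- readSplit[[rid]]
    L <- length(s)
    # reconstruct the aligned reference in the read's as-sequenced frame:
    # matches copy the read base; mismatch positions take the reference
    # base from the hit (complemented for reverse-strand alignments).
    rows <- mmKey[[paste(rid, bestNode[i])]]
    ref <- s
    obsAt <- s
    if (length(rows)) {
      refBase <- mm$ref[rows]
      if (identical(bestStrand[i], "-")) refBase <- comp[refBase]
      ref[mm$pos[rows]] <- refBase
    }
    kk <- min(K, L)
    x5 <- seq_len(kk)
    n5 <- as.numeric(ref[x5] == "C")
    k5 <- as.numeric(ref[x5] == "C" & obsAt[x5] == "T")
    p3 <- L - x5 + 1L
    n3 <- as.numeric(ref[p3] == "G")
    k3 <- as.numeric(ref[p3] == "G" & obsAt[p3] == "A")
    path <- paths[[as.character(a$node[i])]]
    counts[path, x5, "k5"] <- counts[path, x5, "k5"] +
      rep(k5, each = length(path))
    counts[path, x5, "n5"] <- counts[path, x5, "n5"] +
      rep(n5, each = length(path))
    counts[path, x5, "k3"] <- counts[path, x5, "k3"] +
      rep(k3, each = length(path))
    counts[path, x5, "n3"] <- counts[path, x5, "n3"] +
      rep(n3, each = length(path))
    nReads[path] <- nReads[path] + 1L
  }
  new("MismatchMatrix", counts = counts, nodes = nodeIds,
      nReads = unname(nReads))
}

# Beta-binomial log-likelihood for counts k of n with mean mu, conc phi.
.bbLogLik <- function(k, n, mu, phi) {
  mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
  a <- mu * phi
  b <- (1 - mu) * phi
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

.fitDamageCore <- function(k, n, x) {
  keep <- n > 0
  k <- k[keep]; n <- n[keep]; x <- x[keep]
  if (!length(n)) stop("undefined fit: all-zero opportunities",
                       call. = FALSE)
  f <- k / n
  fTerm <- f[x == 1][1]
  fTail <- sum(k[x > max(x) / 2]) / max(1, sum(n[x > max(x) / 2]))
  negllD <- function(p) {
    mu <- p[1] * (1 - p[2])^(x - 1) + p[3]
    -.bbLogLik(k, n, mu, exp(p[4]))
  }
  negll0 <- function(p) -.bbLogLik(k, n, rep(p[1], length(x)), exp(p[2]))
  starts <- list(
    c(max(fTerm - fTail, 0.01, na.rm = TRUE), 0.3, max(fTail, 1e-4), log(100)),
    c(0.05, 0.2, max(fTail, 1e-4), log(100)),
    c(0.20, 0.5, 0.01, log(1000)),
    c(0.50, 0.3, 0.005, log(100)),
    c(0.01, 0.8, 0.02, log(10)))
  lower <- c(0, 1e-3, 1e-8, log(1))
  upper <- c(0.999, 0.999, 0.5, 25)
  bestD <- NULL
  for (p0 in starts) {
    p0 <- pmin(pmax(p0, lower), upper)
    fit <- tryCatch(optim(p0, negllD, method = "L-BFGS-B", lower = lower,
                          upper = upper,
                          control = list(factr = 1e4, maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(bestD) || fit$value < bestD$value))
      bestD <- fit
  }
  best0 <- NULL
  for (c0 in unique(pmin(pmax(c(fTail, fTerm, 0.01), 1e-6), 0.5))) {
    if (is.na(c0)) next
    fit <- tryCatch(optim(c(c0, log(100)), negll0, method = "L-BFGS-B",
                          lower = c(1e-8, log(1)), upper = c(0.5, 25),
                          control = list(factr = 1e4, maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best0) || fit$value < best0$value))
      best0 <- fit
  }
  if (is.null(bestD) || is.null(best0))
    stop("undefined fit: optimizer failed", call. = FALSE)
  list(A = bestD$par[1], q = bestD$par[2], c = bestD$par[3],
       phi = exp(bestD$par[4]), logLik = -bestD$value,
       logLikNull = -best0$value,
       lambdaLR = max(0, 2 * (best0$value - bestD$value)))
}

#' Fit the positional damage model for one node
#'
#' Maximum-likelihood fit of \eqn{f(x) = A(1-q)^{x-1} + c} with
#' beta-binomial overdispersion (concentration \eqn{\phi}), jointly over
#' the 5' C->T and 3' G->A tallies with shared parameters, against the
#' constant-rate null \eqn{f(x) = c}.  Optimization is bounded
#' quasi-Newton (L-BFGS-B) from five deterministic starts.
#'
#' @param mm a [MismatchMatrix-class].
#' @param node node id (must be a row of \code{mm}).
#' @param dmaxFromA if \code{TRUE}, report \code{dmax = A} instead of the
#'   default \code{A + c} (fitted frequency at position 1).
#' @return a [DamageFit-class].
#' @examples
#' \donttest{
#' sim <- simulateTaxonomyRefs(1, 1, 5000, seed = 1)
#' cfg <- simulationConfig(
#'   taxonAbundances = setNames(1, sim$speciesNodes),
#'   A = 0.4, q = 0.3, c = 0.01, nReads = 2000, seed = 2)
#' rd <- simulateReads(sim$refs, cfg)
#' ht <- simulateHitTable(rd$reads, rd$truth, sim$refs, sim$taxonomy)
#' asg <- assignReads(ht, sim$taxonomy)
#' tal <- tallyMismatches(ht, asg, rd$reads, sim$taxonomy)
#' fitDamage(tal, node = 1)   # root node sees every read
#' }
#' @export
fitDamage <- function(mm, node, dmaxFromA = FALSE) {
  stopifnot(is(mm, "MismatchMatrix"))
  key <- as.character(node)
  if (!key %in% as.character(mm@nodes))
    stop(sprintf("node %s not in mismatch matrix", key), call. = FALSE)
  i <- match(as.integer(node), mm@nodes)
  K <- dim(mm@counts)[2]
  k <- c(mm@counts[i, , "k5"], mm@counts[i, , "k3"])
  n <- c(mm@counts[i, , "n5"], mm@counts[i, , "n3"])
  x <- c(seq_len(K), seq_len(K))
  if (sum(n) == 0)
    stop("undefined fit: all-zero opportunities", call. = FALSE)
  core <- .fitDamageCore(k, n, x)
  new("DamageFit", node = as.integer(node), A = core$A, q = core$q,
      c = core$c, phi = core$phi,
      dmax = min(1, if (dmaxFromA) core$A else core$A + core$c),
      lambdaLR = core$lambdaLR, nReads = mm@nReads[i],
      logLik = core$logLik, logLikNull = core$logLikNull)
}

#' Fit the damage model for every node with data
#'
#' @param mm a [MismatchMatrix-class].
#' @param minReads only fit nodes with at least this many subtree reads.
#' @param dmaxFromA see [fitDamage()].
#' @return data.frame with one row per fitted node: \code{node}, \code{A},
#'   \code{q}, \code{c}, \code{phi}, \code{dmax}, \code{lambda_LR},
#'   \code{n_reads}.
#' @export
fitDamageAll <- function(mm, minReads = 10L, dmaxFromA = FALSE) {
  stopifnot(is(mm, "MismatchMatrix"))
  idx <- which(mm@nReads >= minReads)
  rows <- lapply(idx, function(i) {
    f <- tryCatch(fitDamage(mm, mm@nodes[i], dmaxFromA = dmaxFromA),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    data.frame(node = f@node, A = f@A, q = f@q, c = f@c, phi = f@phi,
               dmax = f@dmax, lambda_LR = f@lambdaLR,
               n_reads = f@nReads, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(node = integer(), A = numeric(), q = numeric(),
                      c = numeric(), phi = numeric(), dmax = numeric(),
                      lambda_LR = numeric(), n_reads = integer())
  out
}

#' Authenticity decision for a damage fit
#'
#' A taxonomic node is treated as carrying authentic ancient DNA when its
#' fitted terminal damage and likelihood-ratio statistic both clear the
#' thresholds: D-max >= 0.25 and lambda-LR >= 1.5 by default.
#'
#' @param fit a [DamageFit-class], or a data.frame with columns
#'   \code{dmax} and \code{lambda_LR} (e.g. from [fitDamageAll()]).
#' @param dmaxMin,lrMin thresholds (both inclusive).
#' @return logical (vector for data.frame input).
#' @export
classifyAuthentic <- function(fit, dmaxMin = 0.25, lrMin = 1.5) {
  if (is(fit, "DamageFit"))
    return(is.finite(fit@dmax) && is.finite(fit@lambdaLR) &&
             fit@dmax >= dmaxMin && fit@lambdaLR >= lrMin)
  stopifnot(is.data.frame(fit))
  fit$dmax >= dmaxMin & fit$lambda_LR >= lrMin
}
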