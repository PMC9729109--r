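#' Taxonomy: a rooted tree of named, ranked nodes
#'
#' Container for an NCBI-style taxonomy: every node has an integer id, a
#' parent id, a rank label and a scientific name.  The root is its own
#' parent.  Validity checks enforce a single root, no cycles and no
#' dangling parent references.
#'
#' @slot nodes a \code{data.frame} with columns \code{id}, \code{parent},
#'   \code{rank}, \code{name}; one row per node.
#'
#' @seealso [readTaxonomyDump()], [lca()], [ancestorsOf()]
#' @export
setClass("Taxonomy", representation(nodes = "data.frame"))

.validTaxonomy <- function(object) {
  nd <- object@nodes
  msgs <- character()
  req <- c("id", "parent", "rank", "name")
  if (!all(req %in% names(nd)))
    return(paste("nodes must have columns", paste(req, collapse = ", ")))
  if (anyDuplicated(nd$id)) msgs <- c(msgs, "duplicated node ids")
  roots <- nd$id[nd$id == nd$parent]
  if (length(roots) != 1L)
    msgs <- c(msgs, sprintf("expected exactly one root, found %d",
                            length(roots)))
  dangling <- setdiff(nd$parent, nd$id)
  if (length(dangling))
    msgs <- c(msgs, sprintf("parent id(s) not present as nodes: %s",
                            paste(head(dangling, 5L), collapse = ", ")))
  if (!length(msgs)) {
    # cycle check: every node must reach the root within n steps
    par <- nd$parent[match(nd$id, nd$id)]
    names(par) <- as.character(nd$id)
    n <- nrow(nd)
    for (i in seq_len(n)) {
      cur <- nd$id[i]
      steps <- 0L
      repeat {
        nxt <- par[[as.character(cur)]]
        if (nxt == cur) break
        cur <- nxt
        steps <- steps + 1L
        if (steps > n) {
          msgs <- c(msgs, sprintf("cycle detected involving node %d",
                                  nd$id[i]))
          break
        }
      }
      if (length(msgs)) break
    }
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("Taxonomy", .validTaxonomy)

#' Construct a Taxonomy from a node table
#'
#' @param nodes data.frame with columns \code{id}, \code{parent},
#'   \code{rank}, \code{name}.
#' @return a [Taxonomy-class] object.
#' @examples
#' tax <- Taxonomy(data.frame(
#'   id = 1:4, parent = c(1, 1, 2, 3),
#'   rank = c("root", "family", "genus", "species"),
#'   name = c("root", "FamA", "GenA", "GenA sp1")))
#' tax
#' @export
Taxonomy <- function(nodes) {
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- as.integer(nodes$parent)
  nodes$rank <- as.character(nodes$rank)
  nodes$name <- as.character(nodes$name)
  rownames(nodes) <- NULL
  new("Taxonomy", nodes = nodes)
}

setMethod("show", "Taxonomy", function(object) {
  nd <- object@nodes
  cat(sprintf("Taxonomy with %d nodes (root: %s)\n", nrow(nd),
              nd$name[nd$id == nd$parent]))
  tab <- table(nd$rank)
  cat("  ranks:", paste(sprintf("%s (%d)", names(tab), tab),
                        collapse = ", "), "\n")
})

#' Number of nodes in a Taxonomy
#' @param x a [Taxonomy-class]
#' @export
setMethod("length", "Taxonomy", function(x) nrow(x@nodes))

#' Node table accessor
#' @param x a [Taxonomy-class]
#' @return the node \code{data.frame}
#' @export
taxNodes <- function(x) {
  stopifnot(is(x, "Taxonomy"))
  x@nodes
}

#' HitTable: per-read competitive alignment hits
#'
#' Stores, for each read, its candidate alignments: target taxonomy node,
#' fractional identity, aligned length, strand, and the list of mismatches
#' (1-based position from the 5' end of the read as sequenced, reference
#' base, read base).
#'
#' @slot hits data.frame with columns \code{read_id}, \code{node},
#'   \code{identity}, \code{length}, \code{strand}.
#' @slot mismatches data.frame with columns \code{read_id}, \code{node},
#'   \code{pos}, \code{ref}, \code{obs}.
#' @export
setClass("HitTable",
         representation(hits = "data.frame", mismatches = "data.frame"))

.validHitTable <- function(object) {
  h <- object@hits
  m <- object@mismatches
  msgs <- character()
  reqh <- c("read_id", "node", "identity", "length", "strand")
  reqm <- c("read_id", "node", "pos", "ref", "obs")
  if (!all(reqh %in% names(h))) return("missing hit columns")
  if (!all(reqm %in% names(m))) return("missing mismatch columns")
  if (nrow(h) && (any(h$identity < 0) || any(h$identity > 1)))
    msgs <- c(msgs, "identities must lie in [0, 1]")
  if (nrow(m) && any(m$pos < 1L))
    msgs <- c(msgs, "mismatch positions are 1-based from the 5' end")
  if (length(msgs)) msgs else TRUE
}
setValidity("HitTable", .validHitTable)

#' Construct a HitTable
#' @param hits data.frame of hits (see [HitTable-class]).
#' @param mismatches data.frame of per-hit mismatches; may be empty.
#' @export
HitTable <- function(hits, mismatches = NULL) {
  if (is.null(mismatches))
    mismatches <- data.frame(read_id = character(), node = integer(),
                             pos = integer(), ref = character(),
                             obs = character(), stringsAsFactors = FALSE)
  hits$node <- as.integer(hits$node)
  rownames(hits) <- rownames(mismatches) <- NULL
  new("HitTable", hits = hits, mismatches = mismatches)
}

setMethod("show", "HitTable", function(object) {
  cat(sprintf("HitTable: %d hits over %d reads (%d mismatch records)\n",
              nrow(object@hits), length(unique(object@hits$read_id)),
              nrow(object@mismatches)))
})

#' Hits accessor
#' @param x a [HitTable-class]
#' @export
hits <- function(x) { stopifnot(is(x, "HitTable")); x@hits }

#' Mismatch-record accessor
#' @param x a [HitTable-class]
#' @export
mismatchRecords <- function(x) { stopifnot(is(x, "HitTable")); x@mismatches }

#' DamageFit: fitted terminal-damage model for one taxonomic node
#'
#' Maximum-likelihood fit of the positional damage model
#' \eqn{f(x) = A(1-q)^{x-1} + c} under beta-binomial sampling, against a
#' constant-rate null \eqn{f(x) = c}.  \code{dmax} is the fitted damage
#' frequency at the terminal position (\eqn{A + c}); \code{lambdaLR} is the
#' likelihood-ratio statistic \eqn{2(\ell_{damage} - \ell_{null})}.
#'
#' @slot node taxonomy node id the fit refers to.
#' @slot A,q,c,phi model parameters (excess terminal damage, positional
#'   decay, background rate, beta-binomial concentration).
#' @slot dmax fitted damage frequency at position 1.
#' @slot lambdaLR likelihood-ratio statistic (2 * delta log-likelihood).
#' @slot nReads number of reads contributing to the tallies.
#' @slot logLik,logLikNull optimized log-likelihoods of the two models.
#' @export
setClass("DamageFit",
         representation(node = "integer", A = "numeric", q = "numeric",
                        c = "numeric", phi = "numeric", dmax = "numeric",
                        lambdaLR = "numeric", nReads = "integer",
                        logLik = "numeric", logLikNull = "numeric"))

setValidity("DamageFit", function(object) {
  msgs <- character()
  if (object@A < 0) msgs <- c(msgs, "A must be >= 0")
  if (object@c < 0 || object@c > 1) msgs <- c(msgs, "c must be in [0, 1]")
  if (object@dmax > 1 + 1e-9) msgs <- c(msgs, "dmax must be <= 1")
  if (object@lambdaLR < -1e-6)
    msgs <- c(msgs, "lambdaLR must be nonnegative up to tolerance")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "DamageFit", function(object) {
  cat(sprintf(paste0("DamageFit (node %d, %d reads)\n",
                     "  A=%.4f q=%.4f c=%.5f phi=%.1f\n",
                     "  D-max=%.4f lambda-LR=%.3f\n"),
              object@node, object@nReads, object@A, object@q, object@c,
              object@phi, object@dmax, object@lambdaLR))
})

#' D-max accessor
#' @param x a [DamageFit-class]
#' @export
dmax <- function(x) { stopifnot(is(x, "DamageFit")); x@dmax }

#' lambda-LR accessor
#' @param x a [DamageFit-class]
#' @export
lambdaLR <- function(x) { stopifnot(is(x, "DamageFit")); x@lambdaLR }

#' MismatchMatrix: positional substitution tallies per taxonomic node
#'
#' For each node and position \eqn{x = 1..K} from the 5' end, the number of
#' C->T substitutions observed (\code{k5}) out of aligned reference
#' cytosines (\code{n5}); mirrored from the 3' end for G->A (\code{k3} out
#' of \code{n3}).  Tallies at a node include all reads assigned to the node
#' or any of its descendants.
#'
#' @slot counts numeric array with dim (nodes, K, 4); the four layers are
#'   \code{k5}, \code{n5}, \code{k3}, \code{n3}.
#' @slot nodes integer vector of node ids (rows of \code{counts}).
#' @slot nReads integer vector: reads contributing per node.
#' @export
setClass("MismatchMatrix",
         representation(counts = "array", nodes = "integer",
                        nReads = "integer"))

setValidity("MismatchMatrix", function(object) {
  d <- dim(object@counts)
  if (length(d) != 3L || d[3] != 4L)
    return("counts must be a (nodes x K x 4) array")
  if (d[1] != length(object@nodes)) return("nodes/counts mismatch")
  k <- object@counts[, , c(1L, 3L), drop = FALSE]
  n <- object@counts[, , c(2L, 4L), drop = FALSE]
  if (any(k > n)) return("observed counts exceed opportunities")
  if (any(object@counts < 0)) return("negative counts")
  TRUE
})

setMethod("show", "MismatchMatrix", function(object) {
  cat(sprintf("MismatchMatrix: %d nodes x %d positions per end\n",
              length(object@nodes), dim(object@counts)[2]))
})

#' AgePDF: probability density over burial age on a fixed grid
#'
#' @slot grid age grid in Myr, strictly increasing.
#' @slot density nonnegative densities integrating to 1 (trapezoid rule).
#' @export
setClass("AgePDF", representation(grid = "numeric", density = "numeric"))

setValidity("AgePDF", function(object) {
  if (length(object@grid) != length(object@density))
    return("grid and density lengths differ")
  if (any(diff(object@grid) <= 0)) return("grid must be strictly increasing")
  if (any(object@density < 0)) return("densities must be nonnegative")
  tot <- trapz(object@grid, object@density)
  if (abs(tot - 1) > 1e-6)
    return(sprintf("density integrates to %.8f, not 1", tot))
  TRUE
})

#' Construct an AgePDF (renormalizing to integrate to exactly 1)
#' @param grid age grid (Myr)
#' @param density nonnegative density values on the grid
#' @export
AgePDF <- function(grid, density) {
  tot <- trapz(grid, density)
  if (!is.finite(tot) || tot <= 0)
    stop("density must have positive mass", call. = FALSE)
  new("AgePDF", grid = as.numeric(grid), density = as.numeric(density) / tot)
}

setMethod("show", "AgePDF", function(object) {
  s <- summaryStats(object)
  cat(sprintf(
    "AgePDF on [%.3g, %.3g] Myr: mode %.3f, median %.3f, 1s [%.3f, %.3f]\n",
    min(object@grid), max(object@grid), s["mode"], s["median"],
    s["lo1s"], s["hi1s"]))
})

#' Age-grid accessor
#' @param x an [AgePDF-class]
#' @export
ageGrid <- function(x) { stopifnot(is(x, "AgePDF")); x@grid }

#' Density accessor
#' @param x an [AgePDF-class]
#' @export
ageDensity <- function(x) { stopifnot(is(x, "AgePDF")); x@density }
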