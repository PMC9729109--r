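# Shared fixtures: a small hand-built taxonomy, a random-tree generator,
# and a naive LCA oracle kept independent of the package implementation.

toyTaxonomy <- function() {
  Taxonomy(data.frame(
    id = 1:6, parent = c(1, 1, 2, 3, 3, 2),
    rank = c("root", "family", "genus", "species", "species", "genus"),
    name = c("root", "FamA", "GenA", "GenA sp1", "GenA sp2", "GenB"),
    stringsAsFactors = FALSE))
}

# Random rooted tree: node i (i > 1) gets a parent drawn from 1..(i-1).
randomTaxonomy <- function(nNodes, seed) {
  withr::with_seed(seed, {
    parent <- c(1L, vapply(2:nNodes, function(i)
      sample.int(i - 1L, 1L), 1L))
    Taxonomy(data.frame(id = seq_len(nNodes), parent = parent,
                        rank = "clade",
                        name = sprintf("n%d", seq_len(nNodes)),
                        stringsAsFactors = FALSE))
  })
}

# Brute-force LCA: full ancestor set (self included) per node by parent
# climbing, intersect all sets, return the element with maximal depth.
lcaOracle <- function(tax, ids) {
  nd <- taxNodes(tax)
  par <- nd$parent
  names(par) <- as.character(nd$id)
  ancestorSet <- function(id) {
    out <- integer()
    cur <- id
    repeat {
      out <- c(out, cur)
      nxt <- par[[as.character(cur)]]
      if (nxt == cur) break
      cur <- nxt
    }
    out
  }
  common <- Reduce(intersect, lapply(ids, ancestorSet))
  depths <- vapply(common, function(id) length(ancestorSet(id)), 1L)
  common[which.max(depths)]
}

# Empirical C->T frequency at 5' position x over a simulated read set,
# computed from the references and the truth table (not from hit tables).
terminalCTFreq <- function(reads, truth, refs, x = 1L) {
  refChar <- as.character(refs)
  isC <- isT <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    refBase <- substr(refChar[[as.character(tr$node)]],
                      tr$start + x - 1L, tr$start + x - 1L)
    if (refBase == "C") {
      isC <- isC + 1L
      obs <- substr(as.character(reads[[tr$read_id]]), x, x)
      if (obs == "T") isT <- isT + 1L
    }
  }
  list(k = isT, n = isC, freq = isT / isC)
}

# Gaussian density restricted to a grid, as an AgePDF.
gaussianAgePDF <- function(grid, mu, sigma) {
  AgePDF(grid, dnorm(grid, mu, sigma))
}

# local trapezoid rule (kept independent of package internals)
trapezoid <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
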