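# Similarity-windowed LCA assignment and per-sample taxonomic profiles.

#' Assignment configuration
#'
#' @param window absolute identity window \code{c(lo, hi)} a hit must fall
#'   inside (inclusive) to be accepted; the study classifies reads with
#'   95-100\% similarity.
#' @param minLength minimum read length in bp (reads shorter than this are
#'   never assigned); the study retains reads >= 30 bp.
#' @return a validated list of class \code{"AssignConfig"}.
#' @export
assignConfig <- function(window = c(0.95, 1.00), minLength = 30L) {
  if (length(window) != 2L || window[1] > window[2] ||
      window[1] < 0 || window[2] > 1)
    stop("'window' must satisfy 0 <= lo <= hi <= 1", call. = FALSE)
  structure(list(window = window, minLength = as.integer(minLength)),
            class = "AssignConfig")
}

#' Assign reads to taxa by windowed LCA
#'
#' Per read, hits whose identity lies inside the absolute similarity
#' window are kept (duplicate hits to the same node collapse to one
#' membership) and the read is assigned to the lowest common ancestor of
#' the surviving nodes.  Reads with no accepted hit, or shorter than the
#' configured minimum length, are left unassigned.
#'
#' @param hitTable a [HitTable-class].
#' @param taxonomy a [Taxonomy-class] covering all hit nodes.
#' @param config an [assignConfig()].
#' @return data.frame with one row per read: \code{read_id}, \code{node}
#'   (NA when unassigned).
#' @examples
#' tax <- Taxonomy(data.frame(id = 1:5, parent = c(1, 1, 2, 3, 3),
#'   rank = c("root", "family", "genus", "species", "species"),
#'   name = c("r", "f", "g", "s1", "s2")))
#' ht <- HitTable(data.frame(read_id = c("r1", "r1"), node = c(4L, 5L),
#'   identity = c(0.98, 0.96), length = 50L, strand = "+"))
#' assignReads(ht, tax)  # r1 -> node 3 (the genus)
#' @export
assignReads <- function(hitTable, taxonomy, config = assignConfig()) {
  h <- hits(hitTable)
  known <- h$node %in% taxNodes(taxonomy)$id
  if (!all(known))
    stop(sprintf("hit references unknown taxonomy node %d",
                 h$node[!known][1L]), call. = FALSE)
  ok <- h$identity >= config$window[1] & h$identity <= config$window[2] &
    h$length >= config$minLength
  acc <- h[ok, , drop = FALSE]
  allReads <- unique(h$read_id)
  byRead <- split(acc$node, acc$read_id)
  assigned <- vapply(byRead, function(nodes) lca(taxonomy, nodes), 1L)
  data.frame(read_id = allReads,
             node = unname(assigned[match(allReads, names(assigned))]),
             stringsAsFactors = FALSE)
}

#' TaxonProfile: per-sample taxonomic read counts
#'
#' A \code{SummarizedExperiment} whose rows are taxonomy nodes and whose
#' columns are samples.  Assay \code{"counts"} holds reads assigned
#' exactly at each node; assay \code{"subtree"} holds the
#' subtree-aggregated counts (node plus all descendants).  \code{rowData}
#' carries rank and name; \code{colData} carries the sample sheet (site,
#' unit, layer, replicate).  Per-sample unassigned-read tallies live in
#' \code{metadata()$unassigned}.
#'
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("TaxonProfile", contains = "SummarizedExperiment")

setValidity("TaxonProfile", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "subtree") %in% a))
    return("assays 'counts' and 'subtree' are required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0)) return("counts must be nonnegative")
  TRUE
})

setMethod("show", "TaxonProfile", function(object) {
  cat(sprintf("TaxonProfile: %d taxonomy nodes x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  assigned reads: %d; unassigned: %d\n",
              sum(SummarizedExperiment::assay(object, "counts")),
              sum(S4Vectors::metadata(object)$unassigned)))
})

#' Build a taxonomic profile from per-sample assignments
#'
#' @param assignments named list (one element per sample) of data.frames
#'   from [assignReads()].
#' @param taxonomy a [Taxonomy-class].
#' @param metadata data.frame with one row per sample (rownames or column
#'   \code{sample} matching \code{names(assignments)}) and columns such as
#'   \code{site}, \code{unit}, \code{layer}, \code{replicate}.
#' @return a [TaxonProfile-class].  For every sample,
#'   assigned + unassigned equals the number of reads in its assignment
#'   table.
#' @export
buildProfile <- function(assignments, taxonomy, metadata = NULL) {
  nd <- taxNodes(taxonomy)
  samples <- names(assignments)
  if (is.null(samples)) stop("'assignments' must be named", call. = FALSE)
  counts <- matrix(0L, nrow(nd), length(samples),
                   dimnames = list(as.character(nd$id), samples))
  unassigned <- integer(length(samples))
  names(unassigned) <- samples
  for (s in samples) {
    a <- assignments[[s]]
    unassigned[s] <- sum(is.na(a$node))
    tab <- table(a$node[!is.na(a$node)])
    counts[names(tab), s] <- as.integer(tab)
  }
  subtree <- apply(counts, 2, function(v) {
    names(v) <- rownames(counts)
    subtreeSums(taxonomy, v)[rownames(counts)]
  })
  subtree <- matrix(subtree, nrow = nrow(counts),
                    dimnames = dimnames(counts))
  if (is.null(metadata))
    metadata <- data.frame(sample = samples, row.names = samples)
  if (!is.null(metadata$sample))
    rownames(metadata) <- metadata$sample
  metadata <- metadata[samples, , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, subtree = subtree),
    rowData = S4Vectors::DataFrame(id = nd$id, rank = nd$rank,
                                   name = nd$name),
    colData = S4Vectors::DataFrame(metadata))
  obj <- new("TaxonProfile", se)
  S4Vectors::metadata(obj)$unassigned <- unassigned
  validObject(obj)
  obj
}

#' Assign all samples and build the profile in one step
#'
#' @param hitTables named list of [HitTable-class] objects, one per sample.
#' @param taxonomy a [Taxonomy-class].
#' @param config an [assignConfig()].
#' @param metadata per-sample metadata sheet (see [buildProfile()]).
#' @return a [TaxonProfile-class].
#' @export
assignAndProfile <- function(hitTables, taxonomy, config = assignConfig(),
                             metadata = NULL) {
  assignments <- lapply(hitTables, assignReads, taxonomy = taxonomy,
                        config = config)
  buildProfile(assignments, taxonomy, metadata)
}

#' Subtree-count accessor
#' @param x a [TaxonProfile-class]
#' @return matrix of subtree-aggregated counts (nodes x samples)
#' @export
subtreeCounts <- function(x) {
  stopifnot(is(x, "TaxonProfile"))
  SummarizedExperiment::assay(x, "subtree")
}

#' Direct-assignment count accessor
#' @param x a [TaxonProfile-class]
#' @export
assignedCounts <- function(x) {
  stopifnot(is(x, "TaxonProfile"))
  SummarizedExperiment::assay(x, "counts")
}
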