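# Taxonomy loading, traversal and lowest-common-ancestor assignment.

.parentLookup <- function(tax) {
  nd <- taxNodes(tax)
  par <- nd$parent
  names(par) <- as.character(nd$id)
  par
}

#' Path from a node to the root
#'
#' @param tax a [Taxonomy-class]
#' @param id a node id present in \code{tax}
#' @return integer vector of node ids from \code{id} (first) up to the
#'   root (last), inclusive.
#' @export
ancestorsOf <- function(tax, id) {
  par <- .parentLookup(tax)
  key <- as.character(id)
  if (is.na(par[key]))
    stop(sprintf("node %s not in taxonomy", key), call. = FALSE)
  path <- integer(length(par))
  i <- 0L
  cur <- as.integer(id)
  repeat {
    i <- i + 1L
    path[i] <- cur
    nxt <- par[[as.character(cur)]]
    if (nxt == cur) break
    cur <- nxt
  }
  path[seq_len(i)]
}

#' Depth of every node (root = 0)
#'
#' @param tax a [Taxonomy-class]
#' @return named integer vector of depths, names are node ids.
#' @export
nodeDepths <- function(tax) {
  nd <- taxNodes(tax)
  par <- .parentLookup(tax)
  depth <- rep(NA_integer_, nrow(nd))
  names(depth) <- as.character(nd$id)
  root <- nd$id[nd$id == nd$parent]
  depth[as.character(root)] <- 0L
  # iterate until all assigned (tree height passes)
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    for (i in todo) {
      p <- as.character(par[[i]])
      if (!is.na(depth[p])) depth[i] <- depth[p] + 1L
    }
  }
  depth
}

#' Lowest common ancestor of a set of nodes
#'
#' Returns the deepest node that is an ancestor-or-self of every node in
#' \code{ids}.  Idempotent on singletons and invariant to the order of
#' \code{ids}.
#'
#' @param tax a [Taxonomy-class]
#' @param ids nonempty vector of node ids
#' @return a single node id
#' @examples
#' tax <- Taxonomy(data.frame(id = 1:5, parent = c(1, 1, 2, 3, 3),
#'   rank = c("root", "family", "genus", "species", "species"),
#'   name = c("r", "f", "g", "s1", "s2")))
#' lca(tax, c(4, 5))  # the genus, node 3
#' @export
lca <- function(tax, ids) {
  ids <- unique(as.integer(ids))
  if (!length(ids)) stop("'ids' must be nonempty", call. = FALSE)
  common <- ancestorsOf(tax, ids[1L])  # ordered deepest -> root
  for (id in ids[-1L]) {
    if (length(common) == 1L) break    # already at root
    common <- common[common %in% ancestorsOf(tax, id)]
  }
  common[1L]
}

#' Read a taxonomy from nodes.dmp/names.dmp streams
#'
#' Parses the NCBI taxonomy dump dialect: fields separated by
#' \code{"\t|\t"} with a trailing \code{"\t|"}.  \code{nodes.dmp} supplies
#' (id, parent, rank); \code{names.dmp} supplies scientific names.  Nodes
#' without a name entry get the placeholder \code{"node <id>"}.
#'
#' @param nodesFile path to the nodes dump
#' @param namesFile path to the names dump
#' @return a [Taxonomy-class]; a dangling parent or cycle raises an error
#'   naming the offending node.
#' @export
readTaxonomyDump <- function(nodesFile, namesFile) {
  parseDump <- function(f) {
    lines <- readLines(f)
    lines <- lines[nzchar(lines)]
    lapply(strsplit(sub("\t\\|$", "", lines), "\t|\t", fixed = TRUE),
           trimws)
  }
  nrec <- parseDump(nodesFile)
  nodes <- data.frame(
    id = as.integer(vapply(nrec, `[`, "", 1L)),
    parent = as.integer(vapply(nrec, `[`, "", 2L)),
    rank = vapply(nrec, `[`, "", 3L),
    stringsAsFactors = FALSE)
  nmrec <- parseDump(namesFile)
  cls <- vapply(nmrec, function(x) if (length(x) >= 4L) x[4L] else
                "scientific name", "")
  nmrec <- nmrec[cls == "scientific name"]
  nm <- data.frame(id = as.integer(vapply(nmrec, `[`, "", 1L)),
                   name = vapply(nmrec, `[`, "", 2L),
                   stringsAsFactors = FALSE)
  nodes$name <- nm$name[match(nodes$id, nm$id)]
  miss <- is.na(nodes$name)
  nodes$name[miss] <- sprintf("node %d", nodes$id[miss])
  dangling <- setdiff(nodes$parent, nodes$id)
  if (length(dangling))
    stop(sprintf("taxonomy format error: parent %d referenced but absent",
                 dangling[1L]), call. = FALSE)
  tax <- Taxonomy(nodes)
  validObject(tax)
  tax
}

#' Write a taxonomy as nodes.dmp/names.dmp
#'
#' Inverse of [readTaxonomyDump()]: a write-then-read round trip
#' reproduces the original node table.
#'
#' @param tax a [Taxonomy-class]
#' @param nodesFile,namesFile output paths
#' @export
writeTaxonomyDump <- function(tax, nodesFile, namesFile) {
  nd <- taxNodes(tax)
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|", nd$id, nd$parent, nd$rank),
             nodesFile)
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     nd$id, nd$name), namesFile)
  invisible(c(nodesFile, namesFile))
}

# Subtree aggregation: given per-node values (named by node id), return
# per-node sums over the node and all of its descendants.
subtreeSums <- function(tax, values) {
  nd <- taxNodes(tax)
  depth <- nodeDepths(tax)
  out <- rep(0, nrow(nd))
  names(out) <- as.character(nd$id)
  out[names(values)] <- out[names(values)] + values
  ord <- order(depth[as.character(nd$id)], decreasing = TRUE)
  for (i in ord) {
    id <- as.character(nd$id[i])
    p <- as.character(nd$parent[i])
    if (p != id) out[p] <- out[p] + out[id]
  }
  out
}
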