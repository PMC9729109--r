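# Post-authentication filter cascade: damage authentication, taxon
# abundance (median/2), sample depth (median/2), replicate support, then
# proportion normalization.

#' Filter-cascade configuration
#'
#' @param dmaxMin minimum fitted terminal damage (D-max) for a node to be
#'   treated as authentic (default 0.25).
#' @param lrMin minimum likelihood-ratio statistic (default 1.5).
#' @param medianDivisor a taxon (sample) is retained only if its total
#'   reads strictly exceed the median across taxa (samples) divided by
#'   this value (default 2).
#' @param minReplicates minimum number of distinct replicate samples a
#'   taxon must survive in (default 3).
#' @param stageOrder order of the four stages; the default applies damage
#'   authentication, then the taxon-median rule, then the sample-median
#'   rule, then the replicate rule.
#' @return a validated list of class \code{"FilterConfig"}.
#' @export
filterConfig <- function(dmaxMin = 0.25, lrMin = 1.5, medianDivisor = 2,
                         minReplicates = 3L,
                         stageOrder = c("damage", "taxon_median",
                                        "sample_median", "replicates")) {
  for (v in c(dmaxMin, lrMin, medianDivisor, minReplicates))
    if (v < 0) stop("thresholds must be >= 0", call. = FALSE)
  stageOrder <- match.arg(stageOrder, several.ok = TRUE)
  structure(list(dmaxMin = dmaxMin, lrMin = lrMin,
                 medianDivisor = medianDivisor,
                 minReplicates = as.integer(minReplicates),
                 stageOrder = stageOrder),
            class = "FilterConfig")
}

# Core cascade on a plain (taxa x samples) count matrix.  Returns the
# retained matrix plus a log of removals.  `replicateOf` maps sample ->
# replicate (biological sample) id.
.filterMatrix <- function(counts, authentic, config, replicateOf = NULL) {
  if (is.null(replicateOf)) {
    replicateOf <- colnames(counts)
    names(replicateOf) <- colnames(counts)
  }
  log <- data.frame(item = character(), kind = character(),
                    stage = character(), value = numeric(),
                    threshold = numeric(), stringsAsFactors = FALSE)
  drop <- function(item, kind, stage, value, threshold) {
    rbind(log, data.frame(item = item, kind = kind, stage = stage,
                          value = value, threshold = threshold,
                          stringsAsFactors = FALSE))
  }
  m <- counts
  for (stage in config$stageOrder) {
    if (!nrow(m) || !ncol(m)) break
    if (stage == "damage") {
      ok <- rownames(m) %in% names(authentic)[authentic]
      for (tx in rownames(m)[!ok])
        log <- drop(tx, "taxon", "damage", NA, NA)
      m <- m[ok, , drop = FALSE]
    } else if (stage == "taxon_median") {
      tot <- rowSums(m)
      thr <- median(tot) / config$medianDivisor
      ok <- tot > thr                       # strict ">", per the rule
      for (tx in rownames(m)[!ok])
        log <- drop(tx, "taxon", "taxon_median", tot[tx], thr)
      m <- m[ok, , drop = FALSE]
    } else if (stage == "sample_median") {
      tot <- colSums(m)
      thr <- median(tot) / config$medianDivisor
      ok <- tot > thr
      for (sm in colnames(m)[!ok])
        log <- drop(sm, "sample", "sample_median", tot[sm], thr)
      m <- m[, ok, drop = FALSE]
    } else if (stage == "replicates") {
      reps <- apply(m > 0, 1, function(v)
        length(unique(replicateOf[colnames(m)[v]])))
      ok <- reps >= config$minReplicates
      for (tx in rownames(m)[!ok])
        log <- drop(tx, "taxon", "replicates", reps[tx],
                    config$minReplicates)
      m <- m[ok, , drop = FALSE]
    }
  }
  list(counts = m, log = log)
}

#' Apply the abundance/depth/replicate filter cascade
#'
#' Stages, in the configured order and with medians recomputed after each
#' stage: (1) keep only damage-authenticated taxa (D-max and lambda-LR
#' thresholds, see [classifyAuthentic()]); (2) drop taxa whose total reads
#' do not strictly exceed the median across retained taxa divided by
#' \code{medianDivisor}; (3) drop samples whose totals do not strictly
#' exceed the median across samples divided by \code{medianDivisor};
#' (4) drop taxa detected in fewer than \code{minReplicates} distinct
#' replicate samples.  Totals are subtree-aggregated counts computed
#' across the whole dataset.
#'
#' @param profile a [TaxonProfile-class], or a plain (taxa x samples)
#'   count matrix.
#' @param fits data.frame from [fitDamageAll()] (per-node damage fits);
#'   ignored when the \code{"damage"} stage is absent from
#'   \code{config$stageOrder}.
#' @param config a [filterConfig()].
#' @param taxa optional node ids to treat as candidate taxa; defaults to
#'   every node with a nonzero subtree count (matrix input: all rows).
#' @return list with \code{counts} (retained matrix), \code{log}
#'   (data.frame of removals: item, kind, stage, value, threshold) and
#'   \code{retained} (retained taxon ids).
#' @examples
#' m <- matrix(c(100, 10, 4, 1), 4, 1,
#'             dimnames = list(c("A", "B", "C", "D"), "s1"))
#' cfg <- filterConfig(stageOrder = "taxon_median")
#' applyFilters(m, fits = NULL, config = cfg)$retained  # A, B, C
#' @export
applyFilters <- function(profile, fits = NULL, config = filterConfig(),
                         taxa = NULL) {
  if (is(profile, "TaxonProfile")) {
    m <- subtreeCounts(profile)
    if (is.null(taxa)) taxa <- rownames(m)[rowSums(m) > 0]
    m <- m[as.character(taxa), , drop = FALSE]
    cd <- SummarizedExperiment::colData(profile)
    replicateOf <- if ("replicate" %in% names(cd))
      as.character(cd$replicate) else colnames(m)
    names(replicateOf) <- colnames(m)
  } else {
    m <- as.matrix(profile)
    if (!is.null(taxa)) m <- m[as.character(taxa), , drop = FALSE]
    replicateOf <- NULL
  }
  authentic <- logical(0)
  if ("damage" %in% config$stageOrder) {
    if (is.null(fits) || !nrow(fits))
      stop("damage stage requested but no fits supplied", call. = FALSE)
    ok <- classifyAuthentic(fits, config$dmaxMin, config$lrMin)
    authentic <- ok
    names(authentic) <- as.character(fits$node)
  }
  res <- .filterMatrix(m, authentic, config, replicateOf)
  res$retained <- rownames(res$counts)
  res
}

#' Normalize retained counts to proportions
#'
#' @param counts retained (taxa x samples) count matrix, e.g.
#'   \code{applyFilters(...)$counts}.
#' @return matrix of per-sample proportions; each column sums to 1.
#' @export
normalizeProportions <- function(counts) {
  m <- as.matrix(counts)
  tot <- colSums(m)
  bad <- which(tot <= 0)
  if (length(bad))
    stop(sprintf("sample '%s' has zero total reads", colnames(m)[bad[1]]),
         call. = FALSE)
  sweep(m, 2, tot, "/")
}
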