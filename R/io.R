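# Plain-text I/O: FASTQ, the TSV hit-table dialect, profiles, and output
# headers carrying version/config-hash/seed provenance.

.provHeader <- function(seed = NA, configHash = NA) {
  sprintf("# sedaDNA %s; config_md5=%s; seed=%s",
          as.character(packageVersion("sedaDNA")),
          as.character(configHash), as.character(seed))
}

.writeTSV <- function(df, path, seed = NA, configHash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provHeader(seed, configHash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTSV <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Write simulated reads as FASTQ (phred+33)
#'
#' @param reads named \code{DNAStringSet}.
#' @param path output path.
#' @param quality uniform base-quality character (default "I", Q40).
#' @export
writeReadsFastq <- function(reads, path, quality = "I") {
  q <- Biostrings::BStringSet(vapply(Biostrings::width(reads), function(w)
    paste(rep(quality, w), collapse = ""), ""))
  qr <- Biostrings::QualityScaledDNAStringSet(
    reads, Biostrings::PhredQuality(q))
  Biostrings::writeQualityScaledXStringSet(qr, path)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#' @param path FASTQ path.
#' @export
readReadsFastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write a hit table as TSV
#'
#' One row per hit with the mismatch list packed as
#' \code{"pos:REF>OBS;..."} (\code{"."} when empty); positions are
#' 1-based from the 5' end of the read as sequenced.
#'
#' @param hitTable a [HitTable-class].
#' @param path output path.
#' @param seed,configHash provenance recorded in the header line.
#' @export
writeHitTable <- function(hitTable, path, seed = NA, configHash = NA) {
  h <- hits(hitTable)
  mm <- mismatchRecords(hitTable)
  key <- paste(h$read_id, h$node)
  packed <- vapply(split(mm, factor(paste(mm$read_id, mm$node),
                                    levels = key)),
                   function(d) .packMismatches(d$pos, d$ref, d$obs), "")
  h$mismatches <- unname(packed[key])
  h$mismatches[is.na(h$mismatches)] <- "."
  .writeTSV(h, path, seed, configHash)
}

#' Read a hit table written by [writeHitTable()]
#' @param path TSV path.
#' @return a [HitTable-class].
#' @export
readHitTable <- function(path) {
  h <- .readTSV(path)
  mmList <- lapply(seq_len(nrow(h)), function(i) {
    d <- .unpackMismatches(h$mismatches[i])
    if (!nrow(d)) return(NULL)
    cbind(data.frame(read_id = h$read_id[i], node = h$node[i],
                     stringsAsFactors = FALSE), d)
  })
  mm <- do.call(rbind, mmList[!vapply(mmList, is.null, TRUE)])
  h$mismatches <- NULL
  HitTable(h, mm)
}

#' Read a hit table from a SAM subset
#'
#' Accepts headered SAM with primary and secondary alignments; the NM and
#' MD tags are required to derive identity and the mismatch list.  Rows
#' whose CIGAR contains indels or clipping are rejected with a warning
#' (identity is defined over gap-free alignments here).  Reference names
#' must be interpretable as taxonomy node ids (or mapped via
#' \code{refToNode}).
#'
#' @param path SAM path.
#' @param refToNode optional named vector mapping reference names to node
#'   ids.
#' @return a [HitTable-class].
#' @export
readHitTableSAM <- function(path, refToNode = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  hitRows <- list()
  mmRows <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L)) next              # unmapped
    cigar <- f[6]
    if (grepl("[IDNSHP]", cigar)) {
      warning(sprintf("skipping alignment with indels/clipping: %s", f[1]),
              call. = FALSE)
      next
    }
    seq <- f[10]
    L <- nchar(seq)
    tags <- f[-(1:11)]
    md <- sub("^MD:Z:", "", grep("^MD:Z:", tags, value = TRUE))
    if (!length(md))
      stop("SAM record lacks the required MD tag", call. = FALSE)
    node <- if (is.null(refToNode)) as.integer(f[3]) else
      as.integer(refToNode[[f[3]]])
    strand <- if (bitwAnd(flag, 16L)) "-" else "+"
    # parse MD: numbers are matches, letters are reference bases at
    # mismatches (no ^ deletions here since indels were rejected)
    toks <- regmatches(md, gregexpr("\\d+|[A-Z]", md))[[1]]
    pos <- 0L
    mpos <- integer()
    mref <- character()
    for (tk in toks) {
      if (grepl("^\\d+$", tk)) pos <- pos + as.integer(tk)
      else { pos <- pos + 1L; mpos <- c(mpos, pos); mref <- c(mref, tk) }
    }
    ident <- 1 - length(mpos) / L
    hitRows[[length(hitRows) + 1L]] <-
      data.frame(read_id = f[1], node = node, identity = ident,
                 length = L, strand = strand, stringsAsFactors = FALSE)
    if (length(mpos)) {
      obs <- substring(seq, mpos, mpos)
      mmRows[[length(mmRows) + 1L]] <-
        data.frame(read_id = f[1], node = node, pos = mpos, ref = mref,
                   obs = obs, stringsAsFactors = FALSE)
    }
  }
  HitTable(do.call(rbind, hitRows), do.call(rbind, mmRows))
}

#' Write a taxonomic profile as TSV
#'
#' Long format: sample, node, rank, name, count, subtree_count.
#'
#' @param profile a [TaxonProfile-class].
#' @param path output path.
#' @param seed,configHash provenance for the header line.
#' @param dropEmpty drop rows with zero subtree count (default TRUE).
#' @export
writeProfile <- function(profile, path, seed = NA, configHash = NA,
                         dropEmpty = TRUE) {
  cnt <- assignedCounts(profile)
  sub <- subtreeCounts(profile)
  rd <- SummarizedExperiment::rowData(profile)
  long <- do.call(rbind, lapply(colnames(cnt), function(s)
    data.frame(sample = s, node = rd$id, rank = rd$rank, name = rd$name,
               count = cnt[, s], subtree_count = sub[, s],
               stringsAsFactors = FALSE)))
  if (dropEmpty) long <- long[long$subtree_count > 0, , drop = FALSE]
  .writeTSV(long, path, seed, configHash)
}

#' Write isotope pairs / generic tables as TSV with provenance
#' @param df data.frame.
#' @param path output path.
#' @param seed,configHash provenance for the header line.
#' @export
writeTable <- function(df, path, seed = NA, configHash = NA) {
  .writeTSV(df, path, seed, configHash)
}

#' Read a TSV table written by this package
#' @param path TSV path.
#' @export
readTable <- function(path) .readTSV(path)
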