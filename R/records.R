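# Harmonized comparison of DNA, macrofossil and pollen records: synonym
# resolution and the four-way overlap classification.

#' Harmonize taxon names through a synonym map
#'
#' Resolves each name through the synonym map (chains are followed to
#' their canonical end; cycles raise an error).  Names absent from the map
#' pass through unchanged and are flagged.
#'
#' @param names character vector of taxon names.
#' @param synonyms data.frame with columns \code{from}, \code{to} (e.g.
#'   \code{"Gramineae" -> "Poaceae"}).
#' @return data.frame with columns \code{input}, \code{name} (canonical)
#'   and \code{mapped} (FALSE for pass-through names).
#' @examples
#' syn <- data.frame(from = "Gramineae", to = "Poaceae")
#' harmonizeTaxa(c("Gramineae", "Salix"), syn)
#' @export
harmonizeTaxa <- function(names, synonyms) {
  lut <- synonyms$to
  names(lut) <- synonyms$from
  resolve <- function(nm) {
    seen <- character()
    cur <- nm
    while (cur %in% names(lut)) {
      if (cur %in% seen)
        stop(sprintf("cyclic synonym chain at '%s'", cur), call. = FALSE)
      seen <- c(seen, cur)
      cur <- lut[[cur]]
    }
    cur
  }
  out <- vapply(names, resolve, "")
  data.frame(input = names, name = unname(out),
             mapped = unname(out != names | names %in% names(lut)),
             stringsAsFactors = FALSE)
}

#' Classify taxa into DNA/fossil overlap categories
#'
#' Every taxon appearing in any record is assigned exactly one category:
#' \describe{
#'   \item{1}{identical taxon recorded by DNA and by macrofossils or
#'     pollen (genus-genus, or identical family-family match);}
#'   \item{2}{genus recorded by DNA whose family appears in the
#'     macrofossil or pollen record (genus contained within a
#'     family-level classification);}
#'   \item{3}{taxa recorded only by DNA;}
#'   \item{4}{taxa recorded only by macrofossils or pollen.}
#' }
#' Taxa recorded only above family rank fall into a residual
#' \code{"unclassifiable"} bucket rather than being forced into 1-4.
#' When both a genus-level and a family-level match apply, the most
#' specific (category 1) wins.
#'
#' @param records list with elements \code{dna}, \code{macrofossil},
#'   \code{pollen}; each a data.frame with columns \code{name} and
#'   \code{rank} (one of \code{"genus"}, \code{"family"},
#'   \code{"higher"}).
#' @param genusFamily data.frame with columns \code{genus}, \code{family}
#'   giving the family of each genus (for category-2 resolution).
#' @return list with \code{taxa} (data.frame: name, rank, category) and
#'   \code{summary} (counts and fractions per category).  Category counts
#'   sum to the size of the union of the record sets.
#' @export
categorizeOverlap <- function(records, genusFamily) {
  req <- c("dna", "macrofossil", "pollen")
  if (!all(req %in% names(records)))
    stop("records must contain dna, macrofossil and pollen", call. = FALSE)
  recs <- lapply(records[req], function(df) {
    stopifnot(all(c("name", "rank") %in% names(df)))
    if (!all(df$rank %in% c("genus", "family", "higher")))
      stop("rank must be genus, family or higher", call. = FALSE)
    unique(df[, c("name", "rank")])
  })
  famOf <- genusFamily$family
  names(famOf) <- genusFamily$genus
  fossil <- unique(rbind(recs$macrofossil, recs$pollen))
  fossilGenera <- fossil$name[fossil$rank == "genus"]
  fossilFamilies <- unique(c(fossil$name[fossil$rank == "family"],
                             unname(famOf[fossilGenera])))
  dnaGenera <- recs$dna$name[recs$dna$rank == "genus"]
  dnaFamilies <- unique(c(recs$dna$name[recs$dna$rank == "family"],
                          unname(famOf[dnaGenera])))
  allTaxa <- unique(rbind(recs$dna, fossil))
  classify <- function(name, rank) {
    inDNA <- name %in% recs$dna$name
    inFossil <- name %in% fossil$name
    if (rank == "higher") return("unclassifiable")
    if (rank == "genus") {
      if (inDNA && inFossil) return("1")
      if (inDNA) {
        fam <- famOf[name]
        if (!is.na(fam) && fam %in% fossil$name[fossil$rank == "family"])
          return("2")
        return("3")
      }
      return("4")                      # fossil-only genus
    }
    # family rank
    if (inDNA && inFossil) return("1")
    if (inDNA) return("3")
    return("4")
  }
  cat <- mapply(classify, allTaxa$name, allTaxa$rank)
  taxa <- data.frame(name = allTaxa$name, rank = allTaxa$rank,
                     category = unname(cat), stringsAsFactors = FALSE)
  lev <- c("1", "2", "3", "4", "unclassifiable")
  counts <- table(factor(taxa$category, levels = lev))
  summary <- data.frame(category = lev, count = as.integer(counts),
                        fraction = as.numeric(counts) / nrow(taxa),
                        stringsAsFactors = FALSE)
  list(taxa = taxa, summary = summary)
}
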