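# Synthetic-data generators: taxonomy + reference sequences, damaged read
# sets with truth tables, competitive hit tables, and geochronological
# inputs.  Every downstream module can be exercised offline on these.

.BASES <- c("A", "C", "G", "T")

#' Simulation configuration
#'
#' Bundles the knobs of the read simulator.  Defaults describe the study
#' conditions the pipeline targets: strongly damaged ancient molecules
#' (high terminal C->T excess decaying geometrically into the read, small
#' constant background), short lognormal fragment lengths retained at
#' >= 30 bp, and an undamaged contaminant fraction.
#'
#' @param taxonAbundances named numeric vector: species node id ->
#'   relative weight (nonnegative, at least one positive).
#' @param A excess damage frequency at the terminal position.
#' @param q per-position geometric decay of the damage excess, in (0, 1).
#' @param c background mismatch rate (applies to all reads).
#' @param fragMean target mean fragment length in bp.
#' @param fragSdLog lognormal dispersion (sd of log length).
#' @param fragRange retained fragment-length range in bp; the study retains
#'   reads >= 30 bp.
#' @param contaminationFraction proportion of reads that are modern
#'   (undamaged) contaminants, in [0, 1].
#' @param nReads number of reads to simulate.
#' @param seed integer seed; identical configs and seeds give
#'   byte-identical outputs.
#' @return a validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(taxonAbundances, A = 0.40, q = 0.30, c = 0.01,
                             fragMean = 50, fragSdLog = 0.25,
                             fragRange = c(30, 150),
                             contaminationFraction = 0, nReads = 1000L,
                             seed = 1L) {
  if (!length(taxonAbundances) || any(taxonAbundances < 0) ||
      !any(taxonAbundances > 0))
    stop("abundances must be nonnegative with at least one positive",
         call. = FALSE)
  if (is.null(names(taxonAbundances)))
    stop("'taxonAbundances' must be named by species node id", call. = FALSE)
  .assertScalarNumber(A, "A", 0, 1)
  .assertScalarNumber(q, "q", 1e-6, 1 - 1e-6)
  .assertScalarNumber(c, "c", 0, 1)
  if (A + c > 1) stop("A + c must be <= 1", call. = FALSE)
  .assertScalarNumber(contaminationFraction, "contaminationFraction", 0, 1)
  .assertScalarNumber(nReads, "nReads", 1, Inf)
  .assertScalarNumber(fragMean, "fragMean", fragRange[1], fragRange[2])
  structure(list(taxonAbundances = taxonAbundances, A = A, q = q, c = c,
                 fragMean = fragMean, fragSdLog = fragSdLog,
                 fragRange = fragRange,
                 contaminationFraction = contaminationFraction,
                 nReads = as.integer(nReads), seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a taxonomy with reference sequences
#'
#' Builds a rooted tree root -> family -> genus -> species and one
#' reference sequence per species.  Genus ancestors diverge from a common
#' family ancestor; each species then mutates its genus ancestor at
#' \code{divergence/2} of sites placed uniformly at random, so sibling
#' species differ at approximately \code{divergence} of sites (no indels).
#'
#' @param nGenera,speciesPerGenus tree dimensions (both >= 1).
#' @param refLength reference length in bp (>= 100).
#' @param seed integer seed.
#' @param divergence target pairwise proportion of differing sites between
#'   sibling species.
#' @param genusDivergence per-genus divergence from the family ancestor.
#' @return list with elements \code{taxonomy} (a [Taxonomy-class]),
#'   \code{refs} (a named [Biostrings::DNAStringSet], names are species
#'   node ids) and \code{speciesNodes} (integer vector).
#' @examples
#' sim <- simulateTaxonomyRefs(3, 2, 5000, seed = 1)
#' sim$taxonomy
#' @export
simulateTaxonomyRefs <- function(nGenera, speciesPerGenus, refLength,
                                 seed = 1L, divergence = 0.06,
                                 genusDivergence = 0.12) {
  if (nGenera < 1 || speciesPerGenus < 1)
    stop("tree dimensions must be positive", call. = FALSE)
  if (refLength < 100) stop("'refLength' must be >= 100", call. = FALSE)
  withSeed(seed, {
    mutate <- function(seq, rate) {
      n <- max(0L, round(rate * length(seq)))
      if (n == 0L) return(seq)
      sites <- sample.int(length(seq), n)
      old <- seq[sites]
      seq[sites] <- vapply(old, function(b)
        sample(setdiff(.BASES, b), 1L), "")
      seq
    }
    famSeq <- sample(.BASES, refLength, replace = TRUE)
    ids <- list(root = 1L, family = 2L)
    rows <- data.frame(id = c(1L, 2L), parent = c(1L, 1L),
                       rank = c("root", "family"),
                       name = c("root", "Family1"),
                       stringsAsFactors = FALSE)
    nextId <- 3L
    refs <- character(0)
    speciesNodes <- integer(0)
    for (g in seq_len(nGenera)) {
      gid <- nextId; nextId <- nextId + 1L
      rows <- rbind(rows, data.frame(
        id = gid, parent = 2L, rank = "genus",
        name = sprintf("Genus%d", g), stringsAsFactors = FALSE))
      genSeq <- mutate(famSeq, genusDivergence)
      for (s in seq_len(speciesPerGenus)) {
        sid <- nextId; nextId <- nextId + 1L
        rows <- rbind(rows, data.frame(
          id = sid, parent = gid, rank = "species",
          name = sprintf("Genus%d sp%d", g, s), stringsAsFactors = FALSE))
        refs[as.character(sid)] <- paste(mutate(genSeq, divergence / 2),
                                         collapse = "")
        speciesNodes <- c(speciesNodes, sid)
      }
    }
    tax <- Taxonomy(rows)
    validObject(tax)
    list(taxonomy = tax,
         refs = Biostrings::DNAStringSet(refs),
         speciesNodes = speciesNodes)
  })
}

# Damage probability at 1-based position x from the terminus.
damageCurve <- function(x, A, q, c) A * (1 - q)^(x - 1) + c

#' Simulate ancient reads with terminal deamination damage
#'
#' Draws fragments from the references in proportion to the configured
#' abundances, with lognormal lengths truncated to the retained range.
#' Ancient reads receive C->T substitutions at 5' position \eqn{x} with
#' probability \eqn{A(1-q)^{x-1} + c} at reference cytosines, and the
#' mirrored G->A substitutions measured from the 3' end (double-strand
#' damage model, equal parameters both ends).  Contaminant reads receive
#' only the background rate \eqn{c} at both base classes.
#'
#' @param refs named \code{DNAStringSet} of reference sequences (names are
#'   species node ids), e.g. from [simulateTaxonomyRefs()].
#' @param config a [simulationConfig()].
#' @return list with \code{reads} (named \code{DNAStringSet}) and
#'   \code{truth}, a data.frame with one row per read: \code{read_id},
#'   \code{node}, \code{damaged}, \code{length}, \code{start}, and the
#'   injected mismatches packed as \code{"pos:REF>OBS;..."}.
#' @export
simulateReads <- function(refs, config) {
  if (!inherits(config, "SimulationConfig"))
    stop("'config' must come from simulationConfig()", call. = FALSE)
  if (!length(refs)) stop("'refs' must be nonempty", call. = FALSE)
  ab <- config$taxonAbundances
  if (!all(names(ab) %in% names(refs)))
    stop("abundance names must match reference names", call. = FALSE)
  withSeed(config$seed, {
    n <- config$nReads
    nodes <- sample(names(ab), n, replace = TRUE, prob = ab)
    refLen <- Biostrings::width(refs)[match(nodes, names(refs))]
    # lognormal lengths with the requested mean, truncated by rejection
    meanlog <- log(config$fragMean) - config$fragSdLog^2 / 2
    len <- round(rlnorm(n, meanlog, config$fragSdLog))
    bad <- len < config$fragRange[1] | len > config$fragRange[2]
    while (any(bad)) {
      len[bad] <- round(rlnorm(sum(bad), meanlog, config$fragSdLog))
      bad <- len < config$fragRange[1] | len > config$fragRange[2]
    }
    len <- pmin(len, refLen)
    start <- 1L + floor(runif(n) * (refLen - len + 1))
    damaged <- runif(n) >= config$contaminationFraction
    refSplit <- lapply(as.character(refs), function(r)
      strsplit(r, "")[[1]])
    seqs <- character(n)
    mmPacked <- character(n)
    for (i in seq_len(n)) {
      s <- refSplit[[nodes[i]]][start[i]:(start[i] + len[i] - 1L)]
      L <- length(s)
      x5 <- seq_len(L)               # distance from 5' end
      x3 <- rev(x5)                  # distance from 3' end
      if (damaged[i]) {
        pC <- damageCurve(x5, config$A, config$q, config$c)
        pG <- damageCurve(x3, config$A, config$q, config$c)
      } else {
        pC <- rep(config$c, L)
        pG <- rep(config$c, L)
      }
      u <- runif(L)
      hitC <- s == "C" & u < pC
      hitG <- s == "G" & u < pG
      obs <- s
      obs[hitC] <- "T"
      obs[hitG] <- "A"
      pos <- which(hitC | hitG)
      mmPacked[i] <- .packMismatches(pos, s[pos], obs[pos])
      seqs[i] <- paste(obs, collapse = "")
    }
    ids <- sprintf("read_%06d", seq_len(n))
    reads <- Biostrings::DNAStringSet(seqs)
    names(reads) <- ids
    truth <- data.frame(read_id = ids, node = as.integer(nodes),
                        damaged = damaged, length = len, start = start,
                        mismatches = mmPacked, stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Simulate a competitive hit table
#'
#' Aligns each simulated read back to its source reference and (optionally)
#' to every congeneric relative at the homologous coordinates, recording
#' the actual mismatch list and identity \eqn{1 - mismatches/length}.
#' Optional Gaussian noise perturbs the reported identities only, so the
#' mismatch lists remain exactly consistent with the emitted alignments.
#'
#' @param reads named \code{DNAStringSet} from [simulateReads()].
#' @param truth the matching truth table.
#' @param refs,taxonomy the reference set and [Taxonomy-class] the reads
#'   were simulated from.
#' @param identityNoise standard deviation of identity noise (default 0).
#' @param seed integer seed.
#' @param includeRelatives if \code{FALSE}, only the source-species hit is
#'   emitted (useful for damage-tally benchmarks).
#' @return a [HitTable-class].
#' @export
simulateHitTable <- function(reads, truth, refs, taxonomy,
                             identityNoise = 0, seed = 1L,
                             includeRelatives = TRUE) {
  if (!all(names(reads) %in% truth$read_id))
    stop("unknown read: truth table does not cover all reads",
         call. = FALSE)
  nd <- taxNodes(taxonomy)
  refSplit <- lapply(as.character(refs), function(r) strsplit(r, "")[[1]])
  # congeners share a parent genus
  parentOf <- nd$parent[match(as.integer(names(refs)), nd$id)]
  names(parentOf) <- names(refs)
  withSeed(seed, {
    readSplit <- strsplit(as.character(reads), "")
    tIdx <- match(names(reads), truth$read_id)
    trRead <- truth$read_id[tIdx]
    trNode <- as.character(truth$node[tIdx])
    trStart <- truth$start[tIdx]
    # accumulate columns in flat vectors; rbind of many small frames is slow
    hRead <- hNode <- hIdent <- hLen <- list()
    mRead <- mNode <- mPos <- mRef <- mObs <- list()
    k <- 0L
    for (i in seq_along(reads)) {
      targets <- if (includeRelatives)
        names(parentOf)[parentOf == parentOf[trNode[i]]] else trNode[i]
      rseq <- readSplit[[i]]
      L <- length(rseq)
      for (tg in targets) {
        ref <- refSplit[[tg]][trStart[i]:(trStart[i] + L - 1L)]
        mm <- which(ref != rseq)
        ident <- 1 - length(mm) / L
        if (identityNoise > 0)
          ident <- min(1, max(0, ident + rnorm(1, 0, identityNoise)))
        k <- k + 1L
        hRead[[k]] <- trRead[i]
        hNode[[k]] <- as.integer(tg)
        hIdent[[k]] <- ident
        hLen[[k]] <- L
        if (length(mm)) {
          mRead[[k]] <- rep(trRead[i], length(mm))
          mNode[[k]] <- rep(as.integer(tg), length(mm))
          mPos[[k]] <- mm
          mRef[[k]] <- ref[mm]
          mObs[[k]] <- rseq[mm]
        }
      }
    }
    hitsDf <- data.frame(read_id = unlist(hRead), node = unlist(hNode),
                         identity = unlist(hIdent), length = unlist(hLen),
                         strand = "+", stringsAsFactors = FALSE)
    mmDf <- if (length(mPos))
      data.frame(read_id = unlist(mRead), node = unlist(mNode),
                 pos = unlist(mPos), ref = unlist(mRef),
                 obs = unlist(mObs), stringsAsFactors = FALSE)
    else NULL
    HitTable(hitsDf, mmDf)
  })
}

# ---- geochronological inputs -----------------------------------------

#' Simulate cosmogenic isotope pairs and a temperature history
#'
#' Generates \code{nSamples} 26Al/10Be concentration pairs decayed from a
#' true burial age: \eqn{E[N26/N10] = R0 \exp(-t(\lambda26 - \lambda10))},
#' with lognormal-free multiplicative Gaussian measurement noise of
#' coefficient of variation \code{noiseCv} applied independently to each
#' concentration, and 1-sigma uncertainties set to \code{noiseCv} times the
#' true concentration.
#'
#' @param trueAge burial age in Myr (>= 0).
#' @param R0 surface production ratio (> 0).
#' @param noiseCv coefficient of variation of the measurement noise.
#' @param nSamples number of sample pairs.
#' @param seed integer seed.
#' @param config a [burialConfig()] supplying the decay constants.
#' @param N10surface pre-burial 10Be concentration of the shallowest
#'   sample (atoms/g); deeper samples decrease geometrically.
#' @return data.frame with columns \code{sample}, \code{depth}, \code{N10},
#'   \code{sN10}, \code{N26}, \code{sN26}.
#' @export
simulateIsotopePairs <- function(trueAge, R0, noiseCv = 0, nSamples = 3L,
                                 seed = 1L, config = burialConfig(R0 = R0),
                                 N10surface = 5e4) {
  if (trueAge < 0) stop("'trueAge' must be >= 0", call. = FALSE)
  .assertScalarNumber(R0, "R0", 1e-9, Inf)
  .assertScalarNumber(noiseCv, "noiseCv", 0, Inf)
  withSeed(seed, {
    depth <- seq(3, 21, length.out = nSamples)
    N10true <- N10surface * 0.9^seq_len(nSamples) *
      exp(-config$lambda10 * trueAge)
    ratio <- R0 * exp(-trueAge * (config$lambda26 - config$lambda10))
    N26true <- N10true * ratio
    noise <- function(x) x * (1 + noiseCv * rnorm(length(x)))
    data.frame(sample = sprintf("S%02d", seq_len(nSamples)),
               depth = depth,
               N10 = noise(N10true), sN10 = noiseCv * N10true,
               N26 = noise(N26true), sN26 = noiseCv * N26true,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a piecewise temperature history
#'
#' Emulates a glacial-interglacial climate record as a square wave around
#' the present-day mean annual temperature (MAT): glacial intervals sit
#' \code{glacialCooling} degrees below \code{matC}, interglacials at
#' \code{matC}.  With \code{glacialCooling = 0} the history is constant, so
#' the present-day MAT is reproduced exactly at every breakpoint.
#'
#' @param durationYr record span in years before present.
#' @param matC present-day mean annual air temperature, degrees C.
#' @param glacialCooling glacial temperature depression, degrees C.
#' @param periodYr glacial cycle length in years.
#' @param glacialFraction fraction of each cycle spent in glacial state.
#' @return a temperature history: data.frame with \code{time} (yr BP,
#'   strictly increasing from 0) and \code{tempK}, plus attribute
#'   \code{interpolation = "constant"} (left-continuous step function).
#' @export
simulateTemperatureHistory <- function(durationYr, matC,
                                       glacialCooling = 8,
                                       periodYr = 100000,
                                       glacialFraction = 0.8) {
  .assertScalarNumber(durationYr, "durationYr", 1, Inf)
  times <- 0
  temps <- matC
  t <- 0
  while (t < durationYr) {
    tIg <- t + (1 - glacialFraction) * periodYr   # interglacial ends
    tGl <- t + periodYr                           # glacial ends
    times <- c(times, tIg, tGl)
    temps <- c(temps, matC - glacialCooling, matC)
    t <- tGl
  }
  keep <- !duplicated(times)
  temperatureHistory(times[keep], temps[keep] + 273.15,
                     interpolation = "constant")
}

#' Construct a temperature history
#'
#' @param time years before present, strictly increasing, starting at 0.
#' @param tempK temperatures in kelvin (> 0).
#' @param interpolation \code{"linear"} or \code{"constant"} (step
#'   function, left-continuous).
#' @return data.frame with class \code{"TemperatureHistory"}.
#' @export
temperatureHistory <- function(time, tempK, interpolation = c("linear",
                                                              "constant")) {
  interpolation <- match.arg(interpolation)
  if (any(diff(time) <= 0))
    stop("'time' must be strictly increasing", call. = FALSE)
  if (any(tempK <= 0)) stop("temperatures must be > 0 K", call. = FALSE)
  structure(data.frame(time = time, tempK = tempK),
            interpolation = interpolation,
            class = c("TemperatureHistory", "data.frame"))
}
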