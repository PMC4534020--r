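## Synthetic-data generator: ground-truthed chromosome, BAC library, WGP tag
## fingerprints, RH / deletion panels and ortholog tables.  All functions are
## deterministic given `seed`; each draws from its own child stream (see
## .childSeed) so components can be regenerated independently.

#' Simulate a chromosome model
#'
#' Gene positions are sampled with intensity `1 + densityGradient * d(x)`,
#' where `d(x)` is the distance from the centromere normalised per arm (0 at
#' the centromere, 1 at either telomere).  A positive gradient therefore
#' reproduces the telomere-increasing gene density typical of large cereal
#' chromosomes; `densityGradient = 0` gives a uniform gene distribution.
#'
#' @param length chromosome length in bp.
#' @param armBoundary centromere midpoint in bp.
#' @param nGenes number of genes to place (may be 0).
#' @param densityGradient gradient coefficient (> -1); 0 = uniform.
#' @param norInterval optional length-2 bp interval of an NOR-like repeat
#'   block.
#' @param name chromosome label.
#' @param seed master RNG seed.
#' @return A [ChromosomeModel-class].
#' @examples
#' simulateChromosome(50e6, 22e6, nGenes = 500, densityGradient = 1, seed = 1)
#' @export
simulateChromosome <- function(length, armBoundary, nGenes,
                               densityGradient = 0, norInterval = NULL,
                               name = "chr6B", seed = 1) {
  if (!is.numeric(length) || length(length) != 1L || length <= 0)
    stop("'length' must be a single positive number")
  nGenes <- .assertCount(nGenes, "nGenes", positive = FALSE)
  if (armBoundary <= 0 || armBoundary >= length)
    stop("'armBoundary' must lie strictly inside (0, length)")
  if (densityGradient <= -1)
    stop("'densityGradient' must exceed -1")
  set.seed(.childSeed(seed, "chromosome"))
  pos <- numeric(0)
  if (nGenes > 0L) {
    fmax <- max(1, 1 + densityGradient)
    pos <- numeric(0)
    while (length(pos) < nGenes) {
      x <- runif(2L * (nGenes - length(pos)) + 10L, 0, length)
      d <- ifelse(x < armBoundary, (armBoundary - x) / armBoundary,
                  (x - armBoundary) / (length - armBoundary))
      keep <- runif(length(x)) < (1 + densityGradient * d) / fmax
      pos <- c(pos, x[keep])
    }
    pos <- sort(pos[seq_len(nGenes)])
  }
  win <- seq(0, length, by = 1e6)
  if (tail(win, 1L) < length) win <- c(win, length)
  rd <- data.frame(start = head(win, -1L), end = tail(win, -1L))
  rd$fraction <- 0.8
  nor <- if (is.null(norInterval)) numeric(0) else as.numeric(norInterval)
  if (length(nor))
    rd$fraction[rd$start < nor[2] & rd$end > nor[1]] <- 0.98
  new("ChromosomeModel", name = name, length = as.numeric(length),
      armBoundary = as.numeric(armBoundary), genePositions = pos,
      norInterval = nor, repeatDensity = rd)
}

#' Simulate an arm-sorted BAC library
#'
#' Clone count is `round(coverage * length / insertMean)`.  Each clone is a
#' contaminant (originating from a foreign chromosome, as happens when the
#' flow-sorted fraction is impure) with probability `1 - purity`.
#'
#' @param model a [ChromosomeModel-class].
#' @param coverage fold genome coverage of the library.
#' @param insertMean,insertSd insert length distribution (bp); defaults match
#'   a typical 130 kb HindIII BAC library.
#' @param purity fraction of clones from the target chromosome, in (0, 1].
#' @param foreignChromosomes labels available for contaminant origins.
#' @param seed master RNG seed.
#' @return data.frame with columns `bacID`, `origin`, `start`, `end`,
#'   `contaminant`.
#' @export
simulateBacLibrary <- function(model, coverage, insertMean = 130e3,
                               insertSd = 13e3, purity = 1,
                               foreignChromosomes = c("chrF1", "chrF2"),
                               seed = 1) {
  stopifnot(is(model, "ChromosomeModel"))
  if (coverage <= 0) stop("'coverage' must be positive")
  purity <- .assertFraction(purity, "purity", loOpen = TRUE)
  set.seed(.childSeed(seed, "library"))
  n <- round(coverage * model@length / insertMean)
  len <- pmax(2e4, rnorm(n, insertMean, insertSd))
  start <- runif(n, 0, pmax(1, model@length - len))
  contaminant <- runif(n) > purity
  origin <- rep(model@name, n)
  if (any(contaminant))
    origin[contaminant] <- sample(foreignChromosomes, sum(contaminant),
                                  replace = TRUE)
  data.frame(bacID = sprintf("BAC%06d", seq_len(n)), origin = origin,
             start = start, end = start + len, contaminant = contaminant,
             stringsAsFactors = FALSE)
}

#' Simulate WGP tag fingerprints for a BAC library
#'
#' Tags are identifiers of fixed genomic restriction-site positions, so that
#' overlapping clones share the tags of their overlap.  Sites are spaced
#' `meanInsert / meanTagsPerBac` bp apart, giving the target mean tag count
#' per clone.  Contaminant clones draw from a disjoint site universe per
#' foreign chromosome, except for a configurable fraction of "shared-repeat"
#' sites that collide with target-chromosome tag ids (making the
#' contamination screen non-trivial).
#'
#' @param model a [ChromosomeModel-class].
#' @param clones BAC table from [simulateBacLibrary()].
#' @param meanTagsPerBac target mean number of tags per clone.
#' @param dropout per-tag independent loss probability, in \[0, 1).
#' @param tagUniverse number of available tag ids per chromosome; defaults to
#'   the number of sites required.  Smaller values are an error.
#' @param sharedRepeatFraction fraction of foreign sites colliding with
#'   target-chromosome tag ids (default 0.02).
#' @param seed master RNG seed.
#' @return list with elements `fingerprints` ([FingerprintSet-class]),
#'   `sites` (data.frame tag/chrom/pos: the ground-truth site map) and
#'   `tagOrigin` (data.frame tag/group: plug-in tag-origin table for the
#'   contamination screen).
#' @export
simulateWgpTags <- function(model, clones, meanTagsPerBac = 20.6, dropout = 0,
                            tagUniverse = NULL, sharedRepeatFraction = 0.02,
                            seed = 1) {
  stopifnot(is(model, "ChromosomeModel"))
  if (meanTagsPerBac <= 0) stop("'meanTagsPerBac' must be positive")
  dropout <- .assertFraction(dropout, "dropout", hiOpen = TRUE)
  set.seed(.childSeed(seed, "tags"))
  insertMean <- mean(clones$end - clones$start)
  spacing <- insertMean / meanTagsPerBac
  sitePos <- seq(spacing / 2, model@length, by = spacing)
  nSites <- length(sitePos)
  if (is.null(tagUniverse)) tagUniverse <- nSites
  if (tagUniverse < nSites)
    stop("'tagUniverse' (", tagUniverse, ") smaller than required sites (",
         nSites, ")")
  chroms <- c(model@name, setdiff(unique(clones$origin), model@name))
  siteID <- vector("list", length(chroms))
  names(siteID) <- chroms
  siteID[[model@name]] <- seq_len(nSites)
  for (i in seq_along(chroms)[-1L]) {
    ids <- i * tagUniverse + seq_len(nSites)
    shared <- runif(nSites) < sharedRepeatFraction
    ids[shared] <- sample.int(nSites, sum(shared), replace = TRUE)
    siteID[[chroms[i]]] <- ids
  }
  tags <- vector("list", nrow(clones))
  names(tags) <- clones$bacID
  for (j in seq_len(nrow(clones))) {
    idx <- which(sitePos >= clones$start[j] & sitePos < clones$end[j])
    ids <- siteID[[clones$origin[j]]][idx]
    if (dropout > 0 && length(ids))
      ids <- ids[runif(length(ids)) >= dropout]
    tags[[j]] <- sort(unique(as.integer(ids)))
  }
  sites <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(tag = siteID[[ch]], chrom = ch, pos = sitePos,
               stringsAsFactors = FALSE)))
  origin <- sites[!duplicated(sites$tag), c("tag", "chrom")]
  names(origin) <- c("tag", "group")
  ## collided ids are genuinely target-chromosome sites
  origin$group[origin$tag <= nSites] <- model@name
  list(fingerprints = new("FingerprintSet", tags = tags), sites = sites,
       tagOrigin = origin)
}

#' Fold coverage of a clone library
#'
#' @param nClones number of clones (fingerprintable or assembled).
#' @param insertMeanBp mean insert size in bp.
#' @param targetSizeBp size of the chromosome or arm the library represents.
#' @return genome equivalents (fold redundancy).
#' @examples
#' libraryCoverage(28828, 132e3, 415e6)  # ~9.2x
#' @export
libraryCoverage <- function(nClones, insertMeanBp, targetSizeBp) {
  nClones * insertMeanBp / targetSizeBp
}

#' Simulate a radiation-hybrid panel
#'
#' Per line, break positions follow a Poisson process along the chromosome
#' (`nBreaks ~ Poisson(meanBreaks)`, positions uniform); each resulting
#' fragment is retained independently with probability `retention`.  The
#' per-line break-count distribution of real gamma-irradiated panels is not
#' standardised; Poisson is the modelling default and is exposed in the run
#' configuration.
#'
#' @param model a [ChromosomeModel-class].
#' @param nLines panel size (default 355, a typical arm-specific wheat
#'   panel).
#' @param meanBreaks mean breaks per line (default 3.6).
#' @param retention fragment retention probability, in (0, 1).
#' @param seed master RNG seed.
#' @return list of lines; each has `id`, `breaks`, `intervals` (2-column
#'   matrix of retained bp intervals, half-open) and `nBreaks` (interval
#'   boundaries interior to the chromosome).
#' @export
simulateRhPanel <- function(model, nLines = 355, meanBreaks = 3.6,
                            retention = 0.7, seed = 1) {
  stopifnot(is(model, "ChromosomeModel"))
  nLines <- .assertCount(nLines, "nLines")
  if (meanBreaks < 0) stop("'meanBreaks' must be non-negative")
  retention <- .assertFraction(retention, "retention", loOpen = TRUE,
                               hiOpen = TRUE)
  set.seed(.childSeed(seed, "panel"))
  L <- model@length
  lapply(seq_len(nLines), function(i) {
    nb <- rpois(1L, meanBreaks)
    br <- sort(runif(nb, 0, L))
    bounds <- c(0, br, L)
    keep <- runif(length(bounds) - 1L) < retention
    iv <- .mergeIntervals(cbind(head(bounds, -1L), tail(bounds, -1L))[keep, ,
                                                                      drop = FALSE])
    list(id = sprintf("RH%04d", i), breaks = br, intervals = iv,
         nBreaks = sum(iv > 0 & iv < L))
  })
}

.mergeIntervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1L]) {
    if (iv[k, 1L] <= out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- max(out[nrow(out), 2L], iv[k, 2L])
    } else out <- rbind(out, iv[k, ])
  }
  out
}

#' Simulate terminal-deletion lines
#'
#' Each line carries a single terminal deletion: short-arm lines lose the
#' distal short arm (retaining `[breakpoint, length)`), long-arm lines lose
#' the distal long arm (retaining `[0, breakpoint)`).
#'
#' @param model a [ChromosomeModel-class].
#' @param sBreaks bp breakpoints of short-arm deletion lines (must lie in the
#'   short arm).
#' @param lBreaks bp breakpoints of long-arm deletion lines.
#' @return list of lines in the same layout as [simulateRhPanel()].
#' @export
simulateDeletionLines <- function(model, sBreaks, lBreaks) {
  stopifnot(is(model, "ChromosomeModel"))
  if (any(sBreaks <= 0 | sBreaks >= model@armBoundary))
    stop("short-arm breakpoints must lie inside the short arm")
  if (any(lBreaks <= model@armBoundary | lBreaks >= model@length))
    stop("long-arm breakpoints must lie inside the long arm")
  L <- model@length
  c(lapply(seq_along(sBreaks), function(i)
      list(id = sprintf("delS%02d", i), breaks = sBreaks[i],
           intervals = matrix(c(sBreaks[i], L), 1L), nBreaks = 1L)),
    lapply(seq_along(lBreaks), function(i)
      list(id = sprintf("delL%02d", i), breaks = lBreaks[i],
           intervals = matrix(c(0, lBreaks[i]), 1L), nBreaks = 1L)))
}

#' Genotype markers on a panel of lines
#'
#' @param lines output of [simulateRhPanel()] or [simulateDeletionLines()].
#' @param markerPositions named numeric vector of marker bp positions.
#' @param errorRate probability of flipping a call (genotyping error).
#' @param missingRate probability of a missing call.
#' @param seed master RNG seed (used only when error/missing rates are
#'   positive).
#' @return An [RHGenotypeMatrix-class] (lines x markers).
#' @export
genotypeMarkers <- function(lines, markerPositions, errorRate = 0,
                            missingRate = 0, seed = 1) {
  if (is.null(names(markerPositions)))
    names(markerPositions) <- sprintf("M%04d", seq_along(markerPositions))
  calls <- t(vapply(lines, function(ln) {
    iv <- ln$intervals
    inAny <- rep(FALSE, length(markerPositions))
    for (k in seq_len(nrow(iv)))
      inAny <- inAny | (markerPositions >= iv[k, 1L] &
                        markerPositions < iv[k, 2L])
    as.integer(inAny)
  }, integer(length(markerPositions))))
  rownames(calls) <- vapply(lines, `[[`, character(1), "id")
  colnames(calls) <- names(markerPositions)
  if (errorRate > 0 || missingRate > 0) {
    set.seed(.childSeed(seed, "genotype"))
    if (errorRate > 0) {
      flip <- matrix(runif(length(calls)) < errorRate, nrow(calls))
      calls[flip] <- 1L - calls[flip]
    }
    if (missingRate > 0)
      calls[matrix(runif(length(calls)) < missingRate, nrow(calls))] <- NA
  }
  RHGenotypeMatrix(calls)
}

#' Simulate genic markers and ortholog links
#'
#' Syntenic genes receive reference-chromosome positions colinear with their
#' chromosome positions (scaled by `refScale`), except inside the specified
#' rearrangement blocks; nonsyntenic genes link to an off-chromosome
#' location.  Rearrangement blocks are lists with `kind` (one of
#' `"inversion"`, `"translocation"`, `"translocation+inversion"`), `start`,
#' `end` (bp on the simulated chromosome) and, for translocations, `offset`
#' (bp displacement applied before scaling).
#'
#' @param model a [ChromosomeModel-class] with genes.
#' @param nMarkers number of genes to expose as PCR-typable markers.
#' @param nonsyntenicFraction fraction of genes without a colinear ortholog.
#' @param rearrangements list of block specifications (may be empty); blocks
#'   must not overlap.
#' @param refChrom label of the homologous reference chromosome.
#' @param refOffChrom label used for nonsyntenic (off-chromosome) links.
#' @param refScale reference bp per simulated bp (grass genomes are several
#'   fold smaller than wheat; default 0.1).
#' @param seed master RNG seed.
#' @return list with `markers` (data.frame markerID/geneID/pos) and `links`
#'   (data.frame geneID/wheatPos/refChrom/refPos/syntenic).
#' @export
simulateMarkersAndOrthologs <- function(model, nMarkers,
                                        nonsyntenicFraction = 477 / 2015,
                                        rearrangements = list(),
                                        refChrom = "ref2", refOffChrom = "refX",
                                        refScale = 0.1, seed = 1) {
  stopifnot(is(model, "ChromosomeModel"))
  nonsyntenicFraction <- .assertFraction(nonsyntenicFraction,
                                         "nonsyntenicFraction")
  genes <- model@genePositions
  if (!length(genes)) stop("model carries no genes")
  nMarkers <- .assertCount(nMarkers, "nMarkers")
  if (nMarkers > length(genes))
    stop("more markers requested than genes available")
  if (length(rearrangements) > 1L) {
    iv <- t(vapply(rearrangements, function(b) c(b$start, b$end), numeric(2)))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(head(iv[, 2L], -1L) > tail(iv[, 1L], -1L)))
      stop("rearrangement blocks overlap")
  }
  set.seed(.childSeed(seed, "markers"))
  geneID <- sprintf("G%05d", seq_along(genes))
  syn <- runif(length(genes)) >= nonsyntenicFraction
  refPos <- genes * refScale
  for (b in rearrangements) {
    inb <- genes >= b$start & genes < b$end
    refPos[inb] <- switch(b$kind,
      inversion = (b$start + b$end - genes[inb]) * refScale,
      translocation = (genes[inb] + b$offset) * refScale,
      `translocation+inversion` =
        (b$start + b$end - genes[inb] + b$offset) * refScale,
      stop("unknown rearrangement kind: ", b$kind))
  }
  links <- data.frame(geneID = geneID, wheatPos = genes,
                      refChrom = ifelse(syn, refChrom, refOffChrom),
                      refPos = ifelse(syn, refPos,
                                      runif(length(genes), 0,
                                            model@length * refScale)),
                      syntenic = syn, stringsAsFactors = FALSE)
  sel <- sort(sample.int(length(genes), nMarkers))
  markers <- data.frame(markerID = sprintf("MK%05d", seq_len(nMarkers)),
                        geneID = geneID[sel], pos = genes[sel],
                        stringsAsFactors = FALSE)
  list(markers = markers, links = links)
}
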