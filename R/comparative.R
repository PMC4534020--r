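## Comparative gene-order analysis against reference chromosomes:
## marker de-duplication, tag-mediated gene transfer, density profiles and
## rearrangement (inversion / translocation) detection.

#' Remove redundant gene markers
#'
#' Greedy clustering at an identity threshold with one representative per
#' cluster (the longest sequence; ties break toward the lexicographically
#' smaller id).  Either a precomputed cluster table or a pairwise identity
#' matrix may be supplied.
#'
#' @param identity square numeric matrix of pairwise identities (dimnames =
#'   marker ids), or a data.frame with columns `id`, `cluster`.
#' @param lengths named numeric vector of sequence lengths (required with a
#'   matrix; optional with clusters, where missing lengths rank equal).
#' @param threshold identity at or above which two markers are redundant.
#' @return character vector of representative marker ids.
#' @export
dedupeGeneMarkers <- function(identity, lengths = NULL, threshold = 0.98) {
  if (is.data.frame(identity)) {
    reps <- vapply(split(identity$id, identity$cluster), function(ids) {
      len <- if (is.null(lengths)) rep(0, length(ids)) else lengths[ids]
      ids[.orderBy(len, ids, decreasing = TRUE)[1L]]
    }, character(1))
    return(sort(unname(reps)))
  }
  ids <- rownames(identity)
  if (is.null(lengths)) lengths <- setNames(rep(0, length(ids)), ids)
  left <- ids
  reps <- character(0)
  while (length(left)) {
    top <- left[.orderBy(lengths[left], left, decreasing = TRUE)[1L]]
    reps <- c(reps, top)
    drop <- left[identity[top, left] >= threshold]
    left <- setdiff(left, union(drop, top))
  }
  sort(reps)
}

#' Transfer genes to BAC contigs via shared WGP tags
#'
#' Only tags hitting exactly one sequence contig (unique, exact hits) are
#' used.  A sequence contig hit by tags belonging to more than one BAC
#' contig is discarded entirely unless the BAC contigs are co-located on
#' the map (within `coLocatedCR`); surviving sequence contigs transfer
#' their genes to the BAC contig with the most supporting tags.
#'
#' @param tagHits data.frame with columns `tag`, `seqContig` (unique exact
#'   tag-to-sequence-contig hits; tags occurring for several sequence
#'   contigs are dropped here).
#' @param seqContigGenes data.frame with columns `seqContig`, `geneID`.
#' @param contigs a [ContigSet-class] (tag ownership); tags occurring in
#'   several BAC contigs are ignored as ambiguous.
#' @param placements optional [placeContigs()] output used for the
#'   co-location test.
#' @param coLocatedCR centiray distance under which two BAC contigs count
#'   as co-located.
#' @return list with `assignments` (geneID/contig/seqContig), `discarded`
#'   (seqContig/reason) and `unassigned` (gene ids with no surviving hit).
#' @export
assignGenesViaTags <- function(tagHits, seqContigGenes, contigs,
                               placements = NULL, coLocatedCR = 50) {
  stopifnot(is(contigs, "ContigSet"))
  dupTags <- unique(tagHits$tag[duplicated(tagHits$tag)])
  tagHits <- tagHits[!tagHits$tag %in% dupTags, , drop = FALSE]
  tagMap <- data.frame(
    tag = unlist(contigs@contigTags, use.names = FALSE),
    contig = rep(names(contigs@contigTags), lengths(contigs@contigTags)),
    stringsAsFactors = FALSE)
  tagMap <- tagMap[!tagMap$tag %in% tagMap$tag[duplicated(tagMap$tag)], ,
                   drop = FALSE]
  tagHits$contig <- tagMap$contig[match(tagHits$tag, tagMap$tag)]
  tagHits <- tagHits[!is.na(tagHits$contig), , drop = FALSE]
  assign <- list(); disc <- list()
  for (sc in unique(tagHits$seqContig)) {
    hits <- tagHits[tagHits$seqContig == sc, ]
    tab <- sort(table(hits$contig), decreasing = TRUE)
    if (length(tab) > 1L) {
      distant <- TRUE
      if (!is.null(placements)) {
        pos <- placements$positionCR[match(names(tab), placements$contig)]
        distant <- anyNA(pos) || diff(range(pos)) > coLocatedCR
      }
      if (distant) {
        disc[[sc]] <- data.frame(seqContig = sc,
                                 reason = "tags from distant BAC contigs",
                                 stringsAsFactors = FALSE)
        next
      }
    }
    genes <- seqContigGenes$geneID[seqContigGenes$seqContig == sc]
    if (length(genes))
      assign[[sc]] <- data.frame(geneID = genes, contig = names(tab)[1L],
                                 seqContig = sc, stringsAsFactors = FALSE)
  }
  assignments <- if (length(assign)) do.call(rbind, assign)
    else data.frame(geneID = character(), contig = character(),
                    seqContig = character(), stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  discarded <- if (length(disc)) do.call(rbind, disc)
    else data.frame(seqContig = character(), reason = character(),
                    stringsAsFactors = FALSE)
  rownames(discarded) <- NULL
  list(assignments = assignments, discarded = discarded,
       unassigned = setdiff(seqContigGenes$geneID, assignments$geneID))
}

#' Gene-density profile along the map
#'
#' Per-contig gene density in genes/Mb, emitted in map order, with separate
#' syntenic and nonsyntenic sub-profiles when a `syntenic` flag is
#' available.
#'
#' @param placements output of [placeContigs()].
#' @param geneAssignments data.frame with columns `geneID`, `contig` and
#'   optionally `syntenic`.
#' @param contigs a [ContigSet-class] (or its `info` data.frame).
#' @return data.frame in map order with densities per contig.
#' @export
geneDensityProfile <- function(placements, geneAssignments, contigs) {
  info <- if (is(contigs, "ContigSet")) contigs@info else contigs
  pl <- placements[!is.na(placements$positionCR), , drop = FALSE]
  pl <- pl[order(pl$positionCR, pl$withinLocusRank, pl$contig), ,
           drop = FALSE]
  szMb <- info$sizeBp[match(pl$contig, info$contig)] / 1e6
  if (any(szMb <= 0 | is.na(szMb)))
    stop("zero-size contig in the profile")
  cnt <- function(sel) as.numeric(table(factor(geneAssignments$contig[sel],
                                               levels = pl$contig)))
  n <- cnt(rep(TRUE, nrow(geneAssignments)))
  out <- data.frame(contig = pl$contig, positionCR = pl$positionCR,
                    sizeMb = szMb, nGenes = n, density = n / szMb,
                    stringsAsFactors = FALSE)
  if ("syntenic" %in% names(geneAssignments)) {
    ns <- cnt(geneAssignments$syntenic)
    nn <- cnt(!geneAssignments$syntenic)
    out$nSyntenic <- ns
    out$densitySyntenic <- ns / szMb
    out$nNonsyntenic <- nn
    out$densityNonsyntenic <- nn / szMb
  }
  out
}

#' Detect inversion and translocation blocks from ortholog order
#'
#' The reference positions of syntenic genes, taken in map order, are
#' segmented into maximal monotone runs; up to one interrupting gene per
#' `outlierPer` consecutive genes may be skipped (real ortholog tables are
#' noisy).  The expected colinear orientation is ascending: a descending run
#' of at least `minBlockSize` genes is an inversion.  A run whose reference
#' positions are displaced by more than `translocOffset` from the linear
#' colinear expectation (fitted on the genes outside the run) is a
#' translocation; a displaced descending run is a translocation
#' (inversion).  When the whole gene order is reversed relative to the
#' reference and no internal blocks exist, a single inversion spanning all
#' genes is reported.
#'
#' @param links data.frame sorted by wheat map position with columns
#'   `geneID`, `wheatPos`, `refPos` (nonsyntenic links excluded upstream).
#' @param minBlockSize minimum genes per reported block.
#' @param outlierPer one skippable interrupting gene per this many genes.
#' @param translocOffset displacement threshold in reference bp.
#' @return data.frame of blocks: `kind`, `wheatStart`, `wheatEnd`,
#'   `refStartGene`, `refEndGene`, `nGenes`, `fromIndex`, `toIndex`.
#' @export
detectRearrangements <- function(links, minBlockSize = 3, outlierPer = 10,
                                 translocOffset = 5e6) {
  empty <- data.frame(kind = character(), wheatStart = numeric(),
                      wheatEnd = numeric(), refStartGene = character(),
                      refEndGene = character(), nGenes = integer(),
                      fromIndex = integer(), toIndex = integer(),
                      stringsAsFactors = FALSE)
  n <- nrow(links)
  if (n < minBlockSize) return(empty)
  links <- links[order(links$wheatPos), , drop = FALSE]
  y <- links$refPos
  rho <- suppressWarnings(cor(seq_len(n), y, method = "spearman"))
  flipped <- !is.na(rho) && rho < 0
  work <- if (flipped) rev(y) else y
  runs <- .monotoneRuns(work, outlierPer, jump = translocOffset)
  blocks <- list()
  for (rn in runs) {
    idx <- rn$idx
    if (length(idx) < minBlockSize) next
    orig <- if (flipped) rev(n + 1L - idx) else idx
    displaced <- .runDisplacement(seq_len(n), y, orig) > translocOffset
    kind <- if (rn$dir < 0 && displaced) "translocation (inversion)"
            else if (rn$dir < 0) "inversion"
            else if (displaced) "translocation"
            else next
    blocks[[length(blocks) + 1L]] <- .blockRow(links, orig, kind)
  }
  if (flipped && !length(blocks))
    blocks[[1L]] <- .blockRow(links, seq_len(n), "inversion")
  if (!length(blocks)) return(empty)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out[order(out$fromIndex), , drop = FALSE]
}

.blockRow <- function(links, idx, kind) {
  data.frame(kind = kind, wheatStart = min(links$wheatPos[idx]),
             wheatEnd = max(links$wheatPos[idx]),
             refStartGene = links$geneID[idx[which.min(links$refPos[idx])]],
             refEndGene = links$geneID[idx[which.max(links$refPos[idx])]],
             nGenes = length(idx), fromIndex = min(idx), toIndex = max(idx),
             stringsAsFactors = FALSE)
}

## Maximal monotone runs with a limited outlier skip: an interrupting value
## is skipped (left out of every run) when the run's direction resumes at
## the next value and the skip budget (one per `outlierPer` genes of the
## run so far, minimum one) is not exhausted.  A reference-position jump
## larger than `jump` always terminates the run (a displaced block should
## form its own run).  When a run ends by direction reversal, its last
## element also opens the next run (the turning point belongs to both).
.monotoneRuns <- function(y, outlierPer, jump = Inf) {
  n <- length(y)
  runs <- list()
  i <- 1L
  while (i <= n) {
    idx <- i
    dir <- 0
    skips <- 0L
    j <- i + 1L
    byJump <- FALSE
    while (j <= n) {
      step <- y[j] - y[idx[length(idx)]]
      if (abs(step) > jump) { byJump <- TRUE; break }
      d <- sign(step)
      if (dir == 0 && d != 0) { dir <- d; idx <- c(idx, j); j <- j + 1L; next }
      if (d == dir && d != 0) { idx <- c(idx, j); j <- j + 1L; next }
      ## candidate outlier: does the run resume just after?
      budget <- max(1L, length(idx) %/% outlierPer)
      if (skips < budget && j < n &&
          abs(y[j + 1L] - y[idx[length(idx)]]) <= jump &&
          sign(y[j + 1L] - y[idx[length(idx)]]) == dir) {
        skips <- skips + 1L
        j <- j + 1L
        next
      }
      break
    }
    runs[[length(runs) + 1L]] <- list(idx = idx, dir = dir)
    last <- idx[length(idx)]
    i <- if (!byJump && length(idx) > 1L && last < n) last else max(j, i + 1L)
  }
  runs
}

## Median absolute displacement of a run's reference positions from the
## colinear expectation fitted on the genes outside the run.  The fit is a
## resistant Theil-Sen line, so other rearranged blocks among the outside
## genes do not drag the expectation.
.runDisplacement <- function(xs, y, idx) {
  out <- setdiff(xs, idx)
  if (length(out) < 2L) return(0)
  xo <- out; yo <- y[out]
  if (length(xo) > 150L) {
    pick <- unique(round(seq(1L, length(xo), length.out = 150L)))
    xo <- xo[pick]; yo <- yo[pick]
  }
  dx <- outer(xo, xo, "-")
  dy <- outer(yo, yo, "-")
  ok <- upper.tri(dx) & dx != 0
  slope <- median(dy[ok] / dx[ok])
  inter <- median(y[out] - slope * out)
  median(abs(y[idx] - (inter + slope * idx)))
}

#' Export ortholog link records
#'
#' Writes tab-separated link records suitable for circular-plot tools and
#' reports link counts per reference chromosome.
#'
#' @param links data.frame with columns `wheatPos`, `refChrom`, `refPos`.
#' @param path optional output TSV path.
#' @return list with `table` (the link records) and `counts` (links per
#'   reference chromosome).
#' @export
syntenyLinkTable <- function(links, path = NULL) {
  tab <- links[, c("wheatPos", "refChrom", "refPos"), drop = FALSE]
  tab <- tab[order(tab$wheatPos), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  u <- sort(unique(tab$refChrom))
  counts <- data.frame(refChrom = u,
                       n = vapply(u, function(ch)
                         sum(tab$refChrom == ch), integer(1)),
                       row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, counts = counts)
}
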