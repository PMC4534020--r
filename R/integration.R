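## Anchoring of BAC contigs onto the RH map: chimera detection, placement,
## within-locus ordering by synteny, and integrated map summaries.

.markerLocusIndex <- function(map) {
  loci <- map@loci
  idx <- rep(seq_along(loci), lengths(loci))
  setNames(idx, unlist(loci, use.names = FALSE))
}

#' Detect and split chimeric contigs
#'
#' A contig is chimeric iff the centiray positions of its anchored markers
#' form two clusters separated by more than `gapCR` with no member markers
#' between them.  The split point is the largest CB-coordinate gap between
#' the BACs carrying markers of the two clusters; members go to the child on
#' their CB side.  Three or more clusters split at the largest gap only,
#' with a warning.
#'
#' @param contigs a [ContigSet-class].
#' @param anchors data.frame with columns `marker`, `bac` (each BAC a
#'   contig member).
#' @param map an [RHMap-class].
#' @param gapCR centiray gap above which marker clusters are called distant.
#' @return list with `contigs` (children replace split parents, suffixed
#'   `.1`/`.2`) and `report` (per-contig chimera calls).
#' @export
detectAndSplitChimeras <- function(contigs, anchors, map, gapCR = 50) {
  stopifnot(is(contigs, "ContigSet"), is(map, "RHMap"))
  mIdx <- .markerLocusIndex(map)
  mb <- contigs@members
  anchors <- anchors[anchors$marker %in% names(mIdx), , drop = FALSE]
  anchors$contig <- mb$contig[match(anchors$bac, mb$bac)]
  anchors$cR <- map@positions[mIdx[anchors$marker]]
  report <- data.frame(contig = contigs@info$contig, chimeric = FALSE,
                       stringsAsFactors = FALSE)
  for (cid in unique(anchors$contig[!is.na(anchors$contig)])) {
    an <- anchors[!is.na(anchors$contig) & anchors$contig == cid, ]
    if (nrow(an) < 2L) next
    pos <- sort(unique(an$cR))
    gaps <- diff(pos)
    nClust <- sum(gaps > gapCR) + 1L
    if (nClust < 2L) next
    if (nClust > 2L)
      warning(cid, ": markers form ", nClust,
              " distant clusters; splitting at the largest gap only")
    cut <- pos[which.max(gaps)]
    grp2 <- an$cR > cut + 1e-9
    report$chimeric[report$contig == cid] <- TRUE
    cmb <- mb[mb$contig == cid, , drop = FALSE]
    cmb <- cmb[order(cmb$cbStart, cmb$bac), , drop = FALSE]
    pos1 <- cmb$cbStart[match(an$bac[!grp2], cmb$bac)]
    pos2 <- cmb$cbStart[match(an$bac[grp2], cmb$bac)]
    if (mean(pos1, na.rm = TRUE) > mean(pos2, na.rm = TRUE)) {
      tmp <- pos1; pos1 <- pos2; pos2 <- tmp
    }
    ## candidate CB split: between max anchored coord of side 1 and min of
    ## side 2, at the largest inter-member gap
    lo <- max(pos1, na.rm = TRUE); hi <- min(pos2, na.rm = TRUE)
    inGap <- which(cmb$cbStart[-1L] > lo & cmb$cbStart[-nrow(cmb)] < hi)
    if (!length(inGap)) inGap <- seq_len(nrow(cmb) - 1L)
    gsize <- cmb$cbStart[inGap + 1L] - cmb$cbEnd[inGap]
    at <- inGap[which.max(gsize)]
    side2 <- cmb$bac[(at + 1L):nrow(cmb)]
    contigs <- .splitContig(contigs, cid, side2)
  }
  list(contigs = contigs, report = report)
}

.splitContig <- function(contigs, cid, side2bacs) {
  mb <- contigs@members
  info <- contigs@info
  rows <- mb$contig == cid
  is2 <- rows & mb$bac %in% side2bacs
  is1 <- rows & !mb$bac %in% side2bacs
  id1 <- paste0(cid, ".1"); id2 <- paste0(cid, ".2")
  mb$contig[is1] <- id1
  mb$contig[is2] <- id2
  shift <- min(mb$cbStart[is2])
  mb$cbStart[is2] <- mb$cbStart[is2] - shift
  mb$cbEnd[is2] <- mb$cbEnd[is2] - shift
  tagsAll <- contigs@contigTags
  old <- info[info$contig == cid, ]
  mk <- function(id, nm) {
    data.frame(contig = id, nMembers = nm, uniqueTags = NA_integer_,
               sizeBp = NA_real_, status = "split-child",
               stringsAsFactors = FALSE)
  }
  newInfo <- rbind(info[info$contig != cid, ],
                   mk(id1, sum(is1)), mk(id2, sum(is2)))
  ## child tag sets / sizes: proportional CB share of the parent
  for (id in c(id1, id2)) {
    n <- sum(mb$contig == id)
    frac <- n / old$nMembers
    newInfo$uniqueTags[newInfo$contig == id] <-
      as.integer(round(old$uniqueTags * frac))
    newInfo$sizeBp[newInfo$contig == id] <- old$sizeBp * frac
  }
  tagsAll[[id1]] <- tagsAll[[cid]]
  tagsAll[[id2]] <- tagsAll[[cid]]
  tagsAll[[cid]] <- NULL
  new("ContigSet", members = mb, info = newInfo, contigTags = tagsAll,
      cbUnit = contigs@cbUnit)
}

#' Place contigs on the RH map
#'
#' A contig's locus is the median locus of its anchored markers (an even
#' split breaks toward the more distal locus).  Orientation comes from the
#' sign of the Spearman correlation between marker CB coordinates and
#' centiray positions and needs at least two distinct marker loci; contigs
#' with markers that did not reach the map are `anchored-unmapped`, contigs
#' without qualifying markers `unanchored`.
#'
#' @param contigs a [ContigSet-class].
#' @param anchors data.frame with columns `marker`, `bac`.
#' @param map an [RHMap-class].
#' @return data.frame with one row per non-eliminated contig: `contig`,
#'   `locusIndex`, `locusName`, `positionCR`, `orientation`,
#'   `withinLocusRank`, `basis`.
#' @export
placeContigs <- function(contigs, anchors, map) {
  stopifnot(is(contigs, "ContigSet"), is(map, "RHMap"))
  mIdx <- .markerLocusIndex(map)
  mb <- contigs@members
  info <- contigs@info
  live <- info$contig[!info$status %in% c("eliminated-small",
                                          "eliminated-foreign",
                                          "singleton")]
  anchors$contig <- mb$contig[match(anchors$bac, mb$bac)]
  out <- lapply(live, function(cid) {
    an <- anchors[!is.na(anchors$contig) & anchors$contig == cid, ,
                  drop = FALSE]
    row <- data.frame(contig = cid, locusIndex = NA_integer_,
                      locusName = NA_character_, positionCR = NA_real_,
                      orientation = "unknown", withinLocusRank = NA_integer_,
                      basis = "unanchored", stringsAsFactors = FALSE)
    if (!nrow(an)) return(row)
    li <- mIdx[an$marker]
    if (all(is.na(li))) { row$basis <- "anchored-unmapped"; return(row) }
    an <- an[!is.na(li), , drop = FALSE]
    li <- li[!is.na(li)]
    sorted <- sort(li)
    n <- length(sorted)
    locus <- if (n %% 2L == 1L) sorted[(n + 1L) %/% 2L] else {
      two <- sorted[c(n %/% 2L, n %/% 2L + 1L)]
      two[which.max(map@positions[two])]     # tie toward the more distal locus
    }
    row$locusIndex <- locus
    row$locusName <- names(map@loci)[locus]
    row$positionCR <- map@positions[locus]
    row$basis <- "rh"
    if (length(unique(li)) >= 2L) {
      cb <- mb$cbStart[match(an$bac, mb$bac)]
      rho <- suppressWarnings(cor(cb, map@positions[li], method = "spearman"))
      if (!is.na(rho) && rho != 0)
        row$orientation <- if (rho > 0) "+" else "-"
    }
    row
  })
  pl <- do.call(rbind, out)
  ## stable within-locus ranks by contig id
  pl$withinLocusRank <- NA_integer_
  for (l in unique(pl$locusIndex[!is.na(pl$locusIndex)])) {
    at <- which(!is.na(pl$locusIndex) & pl$locusIndex == l)
    pl$withinLocusRank[at[order(pl$contig[at])]] <- seq_along(at)
  }
  pl
}

#' Rank co-located contigs by synteny
#'
#' Contigs placed at the same locus and carrying syntenic genes are ranked
#' by the median position of their orthologs on the reference chromosome;
#' contigs without links keep a stable rank after the ranked ones.
#'
#' @param placements output of [placeContigs()].
#' @param geneAssignments data.frame with columns `geneID`, `contig`.
#' @param links data.frame with columns `geneID`, `refPos`, `syntenic`.
#' @return `placements` with updated `withinLocusRank` and `basis`
#'   (`"rh+synteny"` where synteny ordered the contig).
#' @export
orderWithinLocusBySynteny <- function(placements, geneAssignments, links) {
  med <- vapply(split(links$refPos[links$syntenic],
                      links$geneID[links$syntenic]), median, numeric(1))
  gmed <- med[geneAssignments$geneID]
  cmed <- vapply(split(gmed, geneAssignments$contig),
                 function(v) median(v, na.rm = TRUE), numeric(1))
  for (l in unique(placements$locusIndex[!is.na(placements$locusIndex)])) {
    at <- which(!is.na(placements$locusIndex) & placements$locusIndex == l)
    if (length(at) < 2L) next
    m <- cmed[placements$contig[at]]
    ranked <- at[!is.na(m)]
    if (!length(ranked)) next
    rest <- at[is.na(m)]
    ordr <- ranked[order(m[!is.na(m)], placements$contig[ranked])]
    rest <- rest[order(placements$withinLocusRank[rest])]
    placements$withinLocusRank[c(ordr, rest)] <-
      seq_len(length(ordr) + length(rest))
    placements$basis[ordr] <- "rh+synteny"
  }
  placements
}

#' Integrated map summary
#'
#' Tabulates contigs by placement class (on the RH map, anchored by markers
#' but not mapped, unanchored) and arm, with cumulative sizes and coverage
#' percentages against the arm / chromosome sizes.
#'
#' @param placements output of [placeContigs()].
#' @param contigs a [ContigSet-class] (or its `info` data.frame).
#' @param arm named character vector contig -> `"S"`/`"L"` (arm of the
#'   assigned locus, or the source library for unanchored contigs); contigs
#'   missing from it count toward the whole-chromosome totals only.
#' @param chromSizesMb named numeric: `S`, `L`, `whole` reference sizes in
#'   Mb (defaults 415/498/914).
#' @return data.frame with one row per class x {S, L, whole}: `n`, `mb`,
#'   `coveragePct`.
#' @export
integratedSummary <- function(placements, contigs, arm = NULL,
                              chromSizesMb = c(S = 415, L = 498,
                                               whole = 914)) {
  info <- if (is(contigs, "ContigSet")) contigs@info else contigs
  sz <- setNames(info$sizeBp / 1e6, info$contig)
  cls <- ifelse(placements$basis %in% c("rh", "rh+synteny"), "on RH map",
                ifelse(placements$basis == "anchored-unmapped",
                       "anchored, not on RH map", "unanchored"))
  armOf <- if (is.null(arm)) setNames(rep(NA_character_,
                                          nrow(placements)),
                                      placements$contig) else arm
  rows <- list()
  for (cl in c("on RH map", "anchored, not on RH map", "unanchored")) {
    at <- which(cls == cl)
    for (a in c("S", "L", "whole")) {
      sel <- if (a == "whole") at
             else at[!is.na(armOf[placements$contig[at]]) &
                       armOf[placements$contig[at]] == a]
      mb <- sum(sz[placements$contig[sel]])
      rows[[paste(cl, a)]] <- data.frame(
        class = cl, arm = a, n = length(sel), mb = mb,
        coveragePct = 100 * mb / chromSizesMb[[a]],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Marker anchoring summary
#'
#' Per-category anchoring success rates and the mean marker density over
#' anchored contigs.
#'
#' @param developed named integer vector: markers developed per category.
#' @param anchored named integer vector: markers anchored per category
#'   (same names).
#' @param nContigs number of contigs carrying the anchored markers
#'   (optional).
#' @return list with `byCategory` (counts and `successPct`) and, when
#'   `nContigs` is given, `markersPerContig`.
#' @export
anchoringSummary <- function(developed, anchored, nContigs = NULL) {
  stopifnot(identical(names(developed), names(anchored)))
  tab <- data.frame(category = names(developed),
                    developed = as.integer(developed),
                    anchored = as.integer(anchored),
                    successPct = 100 * anchored / developed,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(byCategory = tab)
  if (!is.null(nContigs))
    out$markersPerContig <- sum(anchored) / nContigs
  out
}

#' Summarise a map interval between two contigs
#'
#' Sums contig sizes over the closed centiray interval between the two
#' endpoint contigs, split by arm.
#'
#' @param placements output of [placeContigs()].
#' @param contigs a [ContigSet-class] (or its `info` data.frame).
#' @param fromContig,toContig endpoint contig ids (both must be placed).
#' @param arm named character vector contig -> `"S"`/`"L"`.
#' @return list with `nContigs`, `mb` (named by arm) and `totalMb`.
#' @export
regionSummary <- function(placements, contigs, fromContig, toContig,
                          arm = NULL) {
  info <- if (is(contigs, "ContigSet")) contigs@info else contigs
  p1 <- placements$positionCR[placements$contig == fromContig]
  p2 <- placements$positionCR[placements$contig == toContig]
  if (!length(p1) || is.na(p1) || !length(p2) || is.na(p2))
    stop("both endpoint contigs must be placed on the map")
  lo <- min(p1, p2); hi <- max(p1, p2)
  at <- which(!is.na(placements$positionCR) &
                placements$positionCR >= lo & placements$positionCR <= hi)
  ids <- placements$contig[at]
  mb <- setNames(info$sizeBp[match(ids, info$contig)] / 1e6, ids)
  armOf <- if (is.null(arm)) setNames(rep("unknown", length(ids)), ids)
           else arm[ids]
  list(nContigs = table(factor(armOf, exclude = NULL)),
       mb = tapply(mb, armOf, sum), totalMb = sum(mb))
}
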