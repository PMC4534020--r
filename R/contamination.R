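## Screening of foreign-chromosome BACs and low-confidence contigs.
## The homology search that produces the tag-origin table is external; the
## table is a plug-in input (the simulator's ground truth in tests).

#' Flag a BAC as foreign by tag-origin votes
#'
#' Tags are voted to chromosome groups via the origin table.  The clone is
#' called foreign iff the best non-target group out-votes the target group
#' by strictly more than `margin` tags ("more than four" is read strictly:
#' a difference of 5 or more).  A clone whose tags are all unassigned is
#' `indeterminate`, not foreign.
#'
#' @param tags integer tag vector of one clone (or a [FingerprintSet-class]
#'   for vectorised screening).
#' @param origins data.frame with columns `tag`, `group` (one group per tag;
#'   absent tags count as unassigned).
#' @param targetGroup label of the target chromosome group.
#' @param margin strict vote-difference threshold (default 4).
#' @return for a single clone, a list with `call` (`"foreign"`,
#'   `"target"` or `"indeterminate"`) and `votes` (named counts); for a
#'   [FingerprintSet-class], a data.frame of calls per clone.
#' @export
flagForeignBac <- function(tags, origins, targetGroup, margin = 4) {
  if (is(tags, "FingerprintSet")) {
    calls <- vapply(tags@tags, function(tg)
      flagForeignBac(tg, origins, targetGroup, margin)$call, character(1))
    return(data.frame(bac = names(tags@tags), call = calls,
                      stringsAsFactors = FALSE))
  }
  grp <- origins$group[match(tags, origins$tag)]
  grp[is.na(grp)] <- "unassigned"
  votes <- table(grp)
  known <- votes[setdiff(names(votes), "unassigned")]
  if (!length(known))
    return(list(call = "indeterminate", votes = votes))
  tgt <- if (targetGroup %in% names(known)) known[[targetGroup]] else 0L
  other <- known[setdiff(names(known), targetGroup)]
  best <- if (length(other)) max(other) else 0L
  call <- if (best - tgt > margin) "foreign" else "target"
  list(call = call, votes = votes)
}

#' Eliminate contigs dominated by foreign clones
#'
#' A contig is eliminated iff its foreign members exceed `fraction` of all
#' members ("more than 66 %" is read strictly; indeterminate clones stay in
#' the denominator).  Eliminated contigs get status `eliminated-foreign`.
#'
#' @param contigs a [ContigSet-class].
#' @param foreignFlags data.frame from [flagForeignBac()] on a
#'   [FingerprintSet-class] (columns `bac`, `call`), covering every member.
#' @param fraction strict elimination threshold on the foreign fraction.
#' @return list with `contigs` (statuses updated) and `report` (per-contig
#'   vote tallies).
#' @export
eliminateLowConfidenceContigs <- function(contigs, foreignFlags,
                                          fraction = 0.66) {
  stopifnot(is(contigs, "ContigSet"))
  mb <- contigs@members
  call <- foreignFlags$call[match(mb$bac, foreignFlags$bac)]
  if (anyNA(call)) stop("foreign flags missing for some contig members")
  tab <- do.call(rbind, lapply(split(call, mb$contig), function(cl)
    data.frame(nMembers = length(cl), nForeign = sum(cl == "foreign"),
               nIndeterminate = sum(cl == "indeterminate"))))
  tab <- data.frame(contig = rownames(tab), tab, row.names = NULL,
                    stringsAsFactors = FALSE)
  tab$foreignFraction <- tab$nForeign / tab$nMembers
  tab$eliminated <- tab$foreignFraction > fraction
  info <- contigs@info
  hit <- info$contig %in% tab$contig[tab$eliminated] &
    !info$status %in% c("eliminated-small")
  info$status[hit] <- "eliminated-foreign"
  contigs@info <- info
  list(contigs = contigs, report = tab)
}

#' Eliminate redundant small contigs
#'
#' A contig with fewer than `minMembers` members is eliminated iff at least
#' `containment` of its unique tags also occur in some single larger
#' retained contig (such small contigs are fingerprint shadows of genomic
#' regions already represented).  Eliminated contigs get status
#' `eliminated-small`.
#'
#' @param contigs a [ContigSet-class].
#' @param minMembers contigs below this member count are candidates.
#' @param containment tag-containment fraction required for elimination.
#' @return list with `contigs` (statuses updated) and `report`.
#' @export
eliminateRedundantSmallContigs <- function(contigs, minMembers = 3,
                                           containment = 0.8) {
  stopifnot(is(contigs, "ContigSet"))
  info <- contigs@info
  live <- !info$status %in% c("eliminated-foreign", "eliminated-small")
  small <- live & info$nMembers < minMembers & info$nMembers >= 1L
  large <- live & info$nMembers >= minMembers
  largeTags <- contigs@contigTags[info$contig[large]]
  rep <- data.frame(contig = info$contig[small], bestContainment = 0,
                    containedIn = NA_character_, eliminated = FALSE,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(rep))) {
    tg <- contigs@contigTags[[rep$contig[r]]]
    if (!length(tg) || !length(largeTags)) next
    frac <- vapply(largeTags, function(big)
      length(intersect(tg, big)) / length(tg), numeric(1))
    b <- which.max(frac)
    rep$bestContainment[r] <- frac[b]
    rep$containedIn[r] <- names(largeTags)[b]
    rep$eliminated[r] <- frac[b] >= containment
  }
  info$status[info$contig %in% rep$contig[rep$eliminated]] <-
    "eliminated-small"
  contigs@info <- info
  list(contigs = contigs, report = rep)
}
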