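## FPC-style stepwise assembly of WGP fingerprints into BAC contigs.

#' Assembly parameter set
#'
#' Defaults follow common WGP practice on arm-sorted wheat libraries: a CB
#' unit (mean genomic distance between adjacent tags) near 5 kb, a FromEnd
#' window of half the mean tag count, exact tag matching (tolerance 0), an
#' initial cut-off of 1e-75 relaxed by 1e+5 per merge round, and DQer
#' splitting of contigs with more than 10 % Questionable clones at a cut-off
#' three rounds more stringent.
#'
#' @param gelLength number of distinct possible tags (G).
#' @param cbUnit bp per consensus-band (tag interval) unit.
#' @param tolerance tag-match window; only 0 (exact identity) is supported.
#' @param fromEnd end-region window in tag units used for merge eligibility.
#' @param initialCutoffExp,finalCutoffExp,stepExp cut-off schedule exponents:
#'   rounds run at `1e<exp>` from initial to final in steps of `stepExp`.
#' @param dqFraction Q-clone fraction above which a contig is split.
#' @param dqStep number of rounds more stringent at which DQer re-assembles.
#' @return validated list of class `AssemblyParams`.
#' @export
assemblyParams <- function(gelLength, cbUnit = 5220, tolerance = 0,
                           fromEnd = 12, initialCutoffExp = -75,
                           finalCutoffExp = -12, stepExp = 5,
                           dqFraction = 0.10, dqStep = 3) {
  if (gelLength <= 0) stop("'gelLength' must be positive")
  if (tolerance != 0) stop("only tolerance = 0 (exact tag identity) is supported")
  if (initialCutoffExp > finalCutoffExp)
    stop("initialCutoffExp must be <= finalCutoffExp")
  if (stepExp <= 0) stop("'stepExp' must be positive")
  dqFraction <- .assertFraction(dqFraction, "dqFraction", loOpen = TRUE,
                                hiOpen = TRUE)
  structure(list(gelLength = gelLength, cbUnit = cbUnit, tolerance = 0,
                 fromEnd = fromEnd, initialCutoffExp = initialCutoffExp,
                 finalCutoffExp = finalCutoffExp, stepExp = stepExp,
                 dqFraction = dqFraction, dqStep = as.integer(dqStep)),
            class = "AssemblyParams")
}

#' Filter BACs by tag count
#'
#' Excludes clones with fewer than `lowFactor` times or more than
#' `highFactor` times the mean tag count: a clone is kept iff
#' `ceiling(lowFactor * m) <= nTags <= floor(highFactor * m)` where `m` is
#' the mean over the input (a mean of 20.6 tags/BAC gives the window
#' 7..51).  Explicit `thresholds = c(lo, hi)` override the computed window.
#'
#' @param fp a [FingerprintSet-class].
#' @param lowFactor,highFactor multiples of the mean defining the window.
#' @param thresholds optional explicit `c(lo, hi)` tag-count window.
#' @return list with `kept` and `excluded` [FingerprintSet-class]s and the
#'   `thresholds` used.
#' @export
filterBacsByTagCount <- function(fp, lowFactor = 0.3, highFactor = 2.5,
                                 thresholds = NULL) {
  stopifnot(is(fp, "FingerprintSet"))
  if (length(fp) == 0L) stop("empty fingerprint input")
  n <- nTags(fp)
  if (is.null(thresholds)) {
    m <- mean(n)
    thresholds <- c(ceiling(lowFactor * m), floor(highFactor * m))
  }
  keep <- n >= thresholds[1L] & n <= thresholds[2L]
  message(sprintf("tag-count filter: kept %d/%d BACs (window %d..%d tags)",
                  sum(keep), length(keep), thresholds[1L], thresholds[2L]))
  list(kept = fp[keep], excluded = fp[!keep],
       thresholds = as.integer(thresholds))
}

## All clone pairs sharing >= 1 tag, with shared counts and log10 Sulston
## scores.  Pairs sharing nothing have score 1 and never cluster.
.pairScores <- function(fp, gelLength) {
  tagsL <- fp@tags
  nt <- lengths(tagsL)
  dt <- data.table(tag = unlist(tagsL, use.names = FALSE),
                   idx = rep(seq_along(tagsL), nt))
  pr <- merge(dt, dt, by = "tag", allow.cartesian = TRUE)
  pr <- pr[pr$idx.x < pr$idx.y, ]
  if (!nrow(pr))
    return(data.table(i = integer(), j = integer(), m = integer(),
                      log10s = numeric()))
  cnt <- pr[, list(m = .N), by = c("idx.x", "idx.y")]
  data.table(i = cnt$idx.x, j = cnt$idx.y, m = cnt$m,
             log10s = sulstonLog10(nt[cnt$idx.x], nt[cnt$idx.y], cnt$m,
                                   gelLength))
}

## Consensus-band map of one contig: greedy seriation seeded at the clone
## with the most tags, extended by the maximal-overlap neighbour (ties by
## BAC id).  Returns per-member CB intervals, per-tag consensus coordinates
## and Questionable flags (fewer than 50 % of a clone's tags inside its
## median-centred placement window).
.cbConsensus <- function(tagsL) {
  n <- length(tagsL)
  ids <- names(tagsL)
  nt <- lengths(tagsL)
  if (n == 1L) {
    co <- seq_len(nt[1L]) - 1
    names(co) <- as.character(tagsL[[1L]])
    return(list(members = data.frame(bac = ids, cbStart = 0,
                                     cbEnd = nt[1L], q = FALSE,
                                     stringsAsFactors = FALSE),
                tagCoord = co))
  }
  ## pairwise overlap counts among members
  dt <- data.table(tag = unlist(tagsL, use.names = FALSE),
                   idx = rep(seq_len(n), nt))
  pr <- merge(dt, dt, by = "tag", allow.cartesian = TRUE)
  pr <- pr[pr$idx.x != pr$idx.y, ]
  ov <- matrix(0L, n, n)
  if (nrow(pr)) {
    cnt <- pr[, list(m = .N), by = c("idx.x", "idx.y")]
    ov[cbind(cnt$idx.x, cnt$idx.y)] <- cnt$m
  }
  coords <- numeric(0)
  seed <- .orderBy(nt, ids, decreasing = TRUE)[1L]
  co <- seq_len(nt[seed]) - 1
  names(co) <- as.character(tagsL[[seed]])
  coords <- co
  placed <- rep(FALSE, n)
  placed[seed] <- TRUE
  while (!all(placed)) {
    cand <- which(!placed)
    gain <- vapply(cand, function(k) sum(ov[k, placed]), numeric(1))
    k <- cand[.orderBy(gain, ids[cand], decreasing = TRUE)[1L]]
    tg <- as.character(tagsL[[k]])
    anch <- coords[tg]
    anch <- anch[!is.na(anch)]
    novel <- setdiff(tg, names(coords))
    if (!length(anch)) {
      ## no direct overlap with placed tags yet: append to the right
      base <- max(coords) + 1
      nc <- base + seq_along(novel) - 1
    } else if (length(novel)) {
      gmin <- min(coords); gmax <- max(coords)
      s <- min(anch); e <- max(anch)
      if ((gmax - e) <= (s - gmin)) {
        nc <- e + seq_along(novel)                    # extend rightwards
      } else {
        nc <- s - rev(seq_along(novel))               # extend leftwards
      }
    } else nc <- numeric(0)
    if (length(novel)) {
      names(nc) <- novel
      coords <- c(coords, nc)
    }
    placed[k] <- TRUE
  }
  coords <- coords - min(coords)
  members <- do.call(rbind, lapply(seq_len(n), function(k) {
    tc <- coords[as.character(tagsL[[k]])]
    ctr <- median(tc)
    tol <- max(2, 0.1 * nt[k])
    inWin <- abs(tc - ctr) <= nt[k] / 2 + tol
    data.frame(bac = ids[k], cbStart = min(tc), cbEnd = max(tc) + 1,
               q = mean(inWin) < 0.5, stringsAsFactors = FALSE)
  }))
  list(members = members, tagCoord = coords)
}

## Assemble a ContigSet from a membership partition (list of index vectors).
.makeContigSet <- function(memberIdx, tagsL, cbUnit, status = NULL) {
  ids <- names(tagsL)
  ord <- order(vapply(memberIdx, function(ix) min(ids[ix]), character(1)))
  memberIdx <- memberIdx[ord]
  if (!is.null(status)) status <- status[ord]
  memb <- vector("list", length(memberIdx))
  info <- vector("list", length(memberIdx))
  ctags <- vector("list", length(memberIdx))
  for (k in seq_along(memberIdx)) {
    ix <- memberIdx[[k]]
    cid <- sprintf("CTG%04d", k)
    cb <- .cbConsensus(tagsL[ix])
    ut <- sort(unique(unlist(tagsL[ix], use.names = FALSE)))
    st <- if (!is.null(status)) status[k]
          else if (length(ix) > 1L) "retained" else "singleton"
    if (length(ix) == 1L) st <- "singleton"
    memb[[k]] <- cbind(contig = cid, cb$members)
    info[[k]] <- data.frame(contig = cid, nMembers = length(ix),
                            uniqueTags = length(ut),
                            sizeBp = length(ut) * cbUnit, status = st,
                            stringsAsFactors = FALSE)
    ctags[[k]] <- ut
  }
  info <- do.call(rbind, info)
  ctags <- setNames(ctags, info$contig)
  new("ContigSet", members = do.call(rbind, memb), info = info,
      contigTags = ctags, cbUnit = cbUnit)
}

#' Single-linkage contig building at one cut-off
#'
#' BACs i, j land in the same contig iff they are connected by a chain of
#' clone pairs whose Sulston score is at or below the cut-off.  Within-contig
#' CB coordinates come from a greedy consensus seriation; singletons are
#' reported with status `"singleton"`.
#'
#' @param fp a filtered [FingerprintSet-class].
#' @param cutoffExp cut-off exponent: pairs with score <= `1e<cutoffExp>`
#'   become edges.
#' @param params an [assemblyParams()] list.
#' @return A [ContigSet-class].
#' @export
buildContigs <- function(fp, cutoffExp, params) {
  stopifnot(is(fp, "FingerprintSet"), inherits(params, "AssemblyParams"))
  pairs <- .pairScores(fp, params$gelLength)
  .contigsFromPairs(fp, pairs, cutoffExp, params$cbUnit)
}

.contigsFromPairs <- function(fp, pairs, cutoffExp, cbUnit) {
  n <- length(fp)
  keep <- pairs$log10s <= cutoffExp
  g <- igraph::graph_from_edgelist(cbind(pairs$i[keep], pairs$j[keep]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_len(n)]
  .makeContigSet(split(seq_len(n), comp), fp@tags, cbUnit)
}

#' Stepwise assembly with merge rounds and DQer splitting
#'
#' The initial assembly is built by single-linkage clustering at the initial
#' cut-off.  Each subsequent round relaxes the cut-off by `stepExp` orders of
#' magnitude and performs only single-to-end and end-to-end merges: a merge
#' candidate must involve, on each side, either a singleton or a clone whose
#' CB placement lies within `fromEnd` tag units of its contig's CB extremes.
#' After every round, contigs whose Questionable-clone fraction exceeds
#' `dqFraction` are re-assembled at a cut-off `dqStep` rounds more stringent
#' (children are flagged `split-child`).  The returned ledger records, per
#' cut-off, the number of contigs, Q-contigs, singletons and the cumulative
#' assembly size.
#'
#' @param fp a filtered [FingerprintSet-class].
#' @param params an [assemblyParams()] list.
#' @return list of class `AssemblyResult`: `contigs` (final
#'   [ContigSet-class]), `ledger` (one row per round), `rounds` (per-round
#'   [ContigSet-class] snapshots) and `params`.
#' @export
stepwiseAssembly <- function(fp, params) {
  stopifnot(is(fp, "FingerprintSet"), inherits(params, "AssemblyParams"))
  exps <- seq(params$initialCutoffExp, params$finalCutoffExp,
              by = params$stepExp)
  pairs <- .pairScores(fp, params$gelLength)
  n <- length(fp)
  ids <- names(fp)
  ## initial partition
  keep <- pairs$log10s <= exps[1L]
  g <- igraph::graph_from_edgelist(cbind(pairs$i[keep], pairs$j[keep]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  part <- unname(split(seq_len(n), igraph::components(g)$membership[seq_len(n)]))
  origin <- rep("retained", length(part))
  cbs <- lapply(part, function(ix) .cbConsensus(fp@tags[ix]))
  ledger <- vector("list", length(exps))
  rounds <- vector("list", length(exps))
  for (ri in seq_along(exps)) {
    e <- exps[ri]
    if (ri > 1L) {
      upd <- .mergeRound(part, origin, cbs, pairs, e, params$fromEnd)
      if (length(upd$changed)) {
        part <- upd$part
        origin <- upd$origin
        cbs <- upd$cbs
        for (k in upd$changed) cbs[[k]] <- .cbConsensus(fp@tags[part[[k]]])
      }
    }
    dq <- .dqerRound(part, origin, cbs, fp, pairs, e, params)
    part <- dq$part; origin <- dq$origin; cbs <- dq$cbs
    qfrac <- vapply(seq_along(part), function(k)
      if (length(part[[k]]) > 1L) mean(cbs[[k]]$members$q) else 0, numeric(1))
    sizes <- vapply(part, function(ix)
      length(unique(unlist(fp@tags[ix], use.names = FALSE))) * params$cbUnit,
      numeric(1))
    multi <- lengths(part) > 1L
    ledger[[ri]] <- data.frame(exponent = e, nContigs = sum(multi),
                               nQContigs = sum(qfrac > params$dqFraction & multi),
                               nSingletons = sum(!multi),
                               cumulativeSizeBp = sum(sizes[multi]))
    rounds[[ri]] <- .snapshotContigSet(part, origin, cbs, fp, params$cbUnit)
  }
  structure(list(contigs = rounds[[length(rounds)]],
                 ledger = do.call(rbind, ledger), rounds = rounds,
                 params = params),
            class = "AssemblyResult")
}

## One merge round: union-find over contigs connected by a qualifying
## end/singleton clone pair at the current cut-off.
.mergeRound <- function(part, origin, cbs, pairs, e, fromEnd) {
  n <- max(unlist(part))
  cl <- integer(n)
  for (k in seq_along(part)) cl[part[[k]]] <- k
  isEnd <- logical(n)
  for (k in seq_along(part)) {
    ix <- part[[k]]
    if (length(ix) == 1L) { isEnd[ix] <- TRUE; next }
    mb <- cbs[[k]]$members
    lo <- min(mb$cbStart); hi <- max(mb$cbEnd)
    isEnd[ix] <- mb$cbStart <= lo + fromEnd | mb$cbEnd >= hi - fromEnd
  }
  ok <- pairs$log10s <= e & cl[pairs$i] != cl[pairs$j] &
    isEnd[pairs$i] & isEnd[pairs$j]
  if (!any(ok)) return(list(changed = integer(0)))
  g <- igraph::graph_from_edgelist(cbind(cl[pairs$i[ok]], cl[pairs$j[ok]]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(part) - igraph::vcount(g)))
  grp <- igraph::components(g)$membership[seq_along(part)]
  groups <- split(seq_along(part), grp)
  newPart <- lapply(groups, function(ks) sort(unlist(part[ks])))
  newOrigin <- vapply(groups, function(ks)
    if (length(ks) > 1L) "retained" else origin[ks], character(1))
  newCbs <- lapply(groups, function(ks)
    if (length(ks) == 1L) cbs[[ks]] else NULL)
  changed <- which(vapply(newCbs, is.null, logical(1)))
  list(part = unname(newPart), origin = unname(newOrigin),
       cbs = unname(newCbs), changed = changed)
}

## DQer: split contigs whose Q fraction exceeds dqFraction by re-clustering
## their members at a cut-off dqStep rounds more stringent.  Guarded by an
## iteration cap (a split child can itself be questionable).
.dqerRound <- function(part, origin, cbs, fp, pairs, e, params) {
  strict <- e - params$dqStep * params$stepExp
  for (iter in seq_len(5L)) {
    qfrac <- vapply(seq_along(part), function(k)
      if (length(part[[k]]) > 1L) mean(cbs[[k]]$members$q) else 0, numeric(1))
    bad <- which(qfrac > params$dqFraction)
    if (!length(bad)) return(list(part = part, origin = origin, cbs = cbs))
    for (k in bad) {
      ix <- part[[k]]
      sub <- pairs[pairs$i %in% ix & pairs$j %in% ix &
                     pairs$log10s <= strict, ]
      g <- igraph::graph_from_edgelist(
        cbind(match(sub$i, ix), match(sub$j, ix)), directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, length(ix) - igraph::vcount(g)))
      comp <- igraph::components(g)$membership[seq_along(ix)]
      kids <- unname(split(ix, comp))
      if (length(kids) == 1L) {        # unsplittable at the stricter cut-off
        origin[k] <- "retained"
        next
      }
      part[[k]] <- kids[[1L]]
      origin[k] <- "split-child"
      cbs[[k]] <- .cbConsensus(fp@tags[kids[[1L]]])
      for (kid in kids[-1L]) {
        part <- c(part, list(kid))
        origin <- c(origin, "split-child")
        cbs <- c(cbs, list(.cbConsensus(fp@tags[kid])))
      }
    }
    newQ <- vapply(seq_along(part), function(k)
      if (length(part[[k]]) > 1L) mean(cbs[[k]]$members$q) else 0, numeric(1))
    if (!any(newQ > params$dqFraction))
      return(list(part = part, origin = origin, cbs = cbs))
  }
  warning("DQer split loop hit its iteration cap; ",
          "some Q-contigs remain unsplit")
  list(part = part, origin = origin, cbs = cbs)
}

.snapshotContigSet <- function(part, origin, cbs, fp, cbUnit) {
  ids <- names(fp)
  ord <- order(vapply(part, function(ix) min(ids[ix]), character(1)))
  memb <- vector("list", length(part))
  info <- vector("list", length(part))
  ctags <- vector("list", length(part))
  for (r in seq_along(ord)) {
    k <- ord[r]
    cid <- sprintf("CTG%04d", r)
    ut <- sort(unique(unlist(fp@tags[part[[k]]], use.names = FALSE)))
    st <- if (length(part[[k]]) == 1L) "singleton" else origin[k]
    memb[[r]] <- cbind(contig = cid, cbs[[k]]$members)
    info[[r]] <- data.frame(contig = cid, nMembers = length(part[[k]]),
                            uniqueTags = length(ut),
                            sizeBp = length(ut) * cbUnit, status = st,
                            stringsAsFactors = FALSE)
    ctags[[r]] <- ut
  }
  info <- do.call(rbind, info)
  new("ContigSet", members = do.call(rbind, memb), info = info,
      contigTags = setNames(ctags, info$contig), cbUnit = cbUnit)
}

#' @export
print.AssemblyResult <- function(x, ...) {
  cat(sprintf("AssemblyResult: %d rounds (1e%d .. 1e%d)\n",
              nrow(x$ledger), x$ledger$exponent[1L],
              x$ledger$exponent[nrow(x$ledger)]))
  print(x$ledger, row.names = FALSE)
  invisible(x)
}

#' Choose the final cut-off from a round ledger
#'
#' Picks the round minimising the Q-contig count among rounds whose
#' cumulative size lies within `tolerance` of `coverageTarget`; ties break
#' toward the more stringent (smaller) exponent.  If no round falls inside
#' the band, the round with cumulative size closest to the target is chosen.
#'
#' @param ledger round ledger from [stepwiseAssembly()].
#' @param coverageTarget target cumulative size in bp (e.g. the arm size).
#' @param tolerance relative half-width of the acceptance band.
#' @return the selected cut-off exponent.
#' @export
selectFinalCutoff <- function(ledger, coverageTarget, tolerance = 0.15) {
  if (is.null(ledger) || !nrow(ledger)) stop("empty assembly ledger")
  rel <- abs(ledger$cumulativeSizeBp - coverageTarget) / coverageTarget
  cand <- which(rel <= tolerance)
  if (!length(cand)) cand <- which(rel == min(rel))
  cand <- cand[order(ledger$nQContigs[cand], ledger$exponent[cand])]
  ledger$exponent[cand[1L]]
}

#' Minimal tiling path of a contig
#'
#' Greedy furthest-reach interval cover over the members' CB intervals: the
#' selected clones span the contig's tag span with every consecutive pair
#' overlapping by at least one tag unit.  For interval inputs the greedy
#' cover is minimal.  A disconnected CB map yields per-component MTPs with a
#' warning.
#'
#' @param x a [ContigSet-class].
#' @param contig contig id; when missing, MTPs for all non-singleton contigs
#'   are returned as a named list.
#' @return ordered character vector of BAC ids (or a named list of them).
#' @export
selectMTP <- function(x, contig) {
  stopifnot(is(x, "ContigSet"))
  if (missing(contig)) {
    ids <- x@info$contig[x@info$status != "singleton"]
    return(setNames(lapply(ids, function(cc) selectMTP(x, cc)), ids))
  }
  mb <- x@members[x@members$contig == contig, , drop = FALSE]
  if (!nrow(mb)) stop("no such contig: ", contig)
  if (nrow(mb) == 1L) return(mb$bac)
  mb <- mb[.orderBy(mb$cbStart, mb$bac), , drop = FALSE]
  target <- max(mb$cbEnd)
  path <- character(0)
  curEnd <- -Inf
  disconnected <- FALSE
  repeat {
    if (is.infinite(curEnd)) {
      cand <- which(mb$cbStart == min(mb$cbStart))
    } else {
      cand <- which(mb$cbStart <= curEnd - 1 & mb$cbEnd > curEnd)
    }
    if (!length(cand)) {
      if (curEnd >= target) break
      nxt <- which(mb$cbStart > curEnd - 1 & mb$cbEnd > curEnd)
      if (!length(nxt)) break
      disconnected <- TRUE
      cand <- which(mb$cbStart == min(mb$cbStart[nxt]) & mb$cbEnd > curEnd)
    }
    k <- cand[.orderBy(mb$cbEnd[cand], mb$bac[cand], decreasing = TRUE)[1L]]
    path <- c(path, mb$bac[k])
    curEnd <- mb$cbEnd[k]
    if (curEnd >= target) break
  }
  if (disconnected)
    warning("disconnected CB map in ", contig,
            ": MTP covers each component separately")
  path
}

#' Assembly statistics
#'
#' N50 is the size of the contig at which the cumulative size (in descending
#' size order) first reaches half the total; L50 is its rank.
#'
#' @param x a [ContigSet-class] (non-eliminated contigs of >= 2 members are
#'   used) or a numeric vector of contig sizes in bp.
#' @param armSize optional reference size in bp for the coverage percentage.
#' @return list with `nContigs`, `cumulativeSizeBp`, `n50`, `l50` and (when
#'   `armSize` is given) `coveragePct`.
#' @export
assemblyStats <- function(x, armSize = NULL) {
  sizes <- if (is(x, "ContigSet")) {
    inf <- x@info
    inf$sizeBp[inf$nMembers >= 2L &
                 inf$status %in% c("retained", "split-child")]
  } else as.numeric(x)
  if (!length(sizes)) stop("no contigs to summarise")
  sizes <- sort(sizes, decreasing = TRUE)
  cum <- cumsum(sizes)
  l50 <- which(cum >= sum(sizes) / 2)[1L]
  out <- list(nContigs = length(sizes), cumulativeSizeBp = sum(sizes),
              n50 = sizes[l50], l50 = l50)
  if (!is.null(armSize))
    out$coveragePct <- 100 * sum(sizes) / armSize
  out
}
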