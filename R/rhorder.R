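## Maximum-likelihood locus ordering.  With complete calls and no
## observation error the chain likelihood decomposes over adjacent pairs:
##   loglik(order) = sum over edges of pair loglik - sum over internal loci
##                   of marginal loglik,
## so the search scores candidate orders through precomputed pairwise
## statistics; with missing calls the pairwise terms use pairwise-complete
## lines and the decomposition is the search surrogate, while the reported
## likelihood always comes from the exact forward algorithm.

.pathScore <- function(ord, pairll, margll) {
  k <- length(ord)
  if (k == 1L) return(margll[ord])
  sum(pairll[cbind(ord[-k], ord[-1L])]) - sum(margll[ord[-c(1L, k)]])
}

#' Order the loci of a linkage group by maximum likelihood
#'
#' Search: greedy chaining seeded at the strongest two-point pair, insertion
#' of the remaining loci at their best position, then full 2-opt (segment
#' reversal) and a sliding-window ripple (window 5) until no improvement.
#' Adjacent breakage probabilities are re-estimated by two-point fits on the
#' final order; centiray positions are the cumulative `-100 ln(1 - theta)`.
#' Orientation is canonical: the lexicographically smaller terminal locus
#' comes first.
#'
#' @param x lines-x-loci calls (an [RHGenotypeMatrix-class] or matrix),
#'   typically the consensus matrix from [collapseCoretained()] restricted
#'   to one linkage group.
#' @param lociMarkers optional named list giving the markers collapsed into
#'   each locus (defaults to the locus name itself).
#' @param rippleWindow ripple window size (default 5).
#' @return An [RHMap-class].
#' @export
orderLoci <- function(x, lociMarkers = NULL, rippleWindow = 5) {
  calls <- .callsOf(x)
  k <- ncol(calls)
  nm <- colnames(calls)
  if (is.null(lociMarkers)) lociMarkers <- setNames(as.list(nm), nm)
  if (k == 1L) {
    return(new("RHMap", loci = lociMarkers[nm], positions = 0,
               thetas = numeric(0), retention = mean(calls == 1, na.rm = TRUE),
               obligateBreaks = 0L, bins = data.frame()))
  }
  tp <- .twoPointAll(calls)
  r <- tp$r
  margll <- vapply(seq_len(k), function(i) {
    v <- calls[, i]; v <- v[!is.na(v)]
    sum(v) * log(r) + sum(1 - v) * log(1 - r)
  }, numeric(1))
  pairll <- tp$pairll
  pairll[is.na(pairll)] <- -1e9          # uninformative pairs never adjacent
  ## seed: strongest two-point pair
  lodv <- tp$lod
  lodv[is.na(lodv)] <- -Inf
  seedIdx <- which(lodv == max(lodv), arr.ind = TRUE)[1L, ]
  ord <- as.integer(seedIdx)
  remaining <- setdiff(seq_len(k), ord)
  ## insertion in order of decreasing linkage to the growing chain
  while (length(remaining)) {
    best <- remaining[which.max(vapply(remaining, function(i)
      max(lodv[i, ord]), numeric(1)))]
    scores <- vapply(0:length(ord), function(pos)
      .pathScore(append(ord, best, after = pos), pairll, margll), numeric(1))
    ord <- append(ord, best, after = which.max(scores) - 1L)
    remaining <- setdiff(remaining, best)
  }
  ## local search: 2-opt reversals + window ripple
  cur <- .pathScore(ord, pairll, margll)
  for (pass in seq_len(50L)) {
    improved <- FALSE
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      cand <- ord
      cand[i:j] <- rev(cand[i:j])
      sc <- .pathScore(cand, pairll, margll)
      if (sc > cur + 1e-9) { ord <- cand; cur <- sc; improved <- TRUE }
    }
    if (k > 2L) {
      w <- min(rippleWindow, k)
      perms <- .permutations(w)
      for (s in seq_len(k - w + 1L)) {
        win <- ord[s:(s + w - 1L)]
        for (pi in seq_len(nrow(perms))) {
          cand <- ord
          cand[s:(s + w - 1L)] <- win[perms[pi, ]]
          sc <- .pathScore(cand, pairll, margll)
          if (sc > cur + 1e-9) { ord <- cand; cur <- sc; improved <- TRUE }
        }
      }
    }
    if (!improved) break
  }
  if (nm[ord[1L]] > nm[ord[k]]) ord <- rev(ord)
  thetas <- tp$theta[cbind(ord[-k], ord[-1L])]
  thetas[is.na(thetas)] <- 1 - 1e-6
  pos <- c(0, cumsum(-100 * log(pmax(1e-12, 1 - thetas))))
  new("RHMap", loci = lociMarkers[nm[ord]], positions = pos,
      thetas = thetas, retention = r,
      obligateBreaks = as.integer(countObligateBreaks(nm[ord], calls)),
      bins = data.frame())
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Build an RH map from a genotype matrix
#'
#' Convenience wrapper: collapse co-retained markers into loci, group the
#' loci by two-point linkage, and order the largest group.
#'
#' @param x an [RHGenotypeMatrix-class].
#' @param lodMin,dMaxCR grouping thresholds (see [groupMarkers()]).
#' @return list with `map` (the [RHMap-class] of the largest group),
#'   `groups` (all locus groups) and `collapsed` (the locus partition).
#' @export
buildRHMap <- function(x, lodMin = 4.0, dMaxCR = 100) {
  col <- collapseCoretained(x)
  grps <- groupMarkers(col$calls, lodMin = lodMin, dMaxCR = dMaxCR)
  main <- grps[[1L]]
  map <- orderLoci(col$calls[, main, drop = FALSE],
                   lociMarkers = col$loci[main])
  list(map = map, groups = grps, collapsed = col)
}
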