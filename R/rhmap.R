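## Radiation-hybrid mapping under an equal-retention haploid breakage model.
##
## Cell probabilities for a marker pair at breakage probability theta and
## retention probability r (constant across loci and lines):
##   P(1,1) = r(1-theta) + r^2 theta
##   P(1,0) = P(0,1) = r theta (1-r)
##   P(0,0) = (1-r)(1-theta) + (1-r)^2 theta
## Distance in centirays: d = -100 ln(1 - theta).

.cellLoglik <- function(n11, n10, n01, n00, theta, r) {
  p11 <- r * (1 - theta) + r^2 * theta
  p10 <- r * theta * (1 - r)
  p00 <- (1 - r) * (1 - theta) + (1 - r)^2 * theta
  term <- function(n, p) if (n == 0) 0 else n * log(p)
  term(n11, p11) + term(n10 + n01, p10) + term(n00, p00)
}

.callsOf <- function(x) {
  m <- if (is(x, "RHGenotypeMatrix")) x@calls else as.matrix(x)
  storage.mode(m) <- "integer"
  m
}

#' Two-point estimate for a marker pair
#'
#' Lines with a missing call at either marker are dropped pairwise.  The
#' retention probability has the closed-form margin estimate
#' `(2 n11 + n10 + n01) / (2 n)`; the breakage probability maximises the
#' multinomial likelihood over the four cell counts by 1-D optimisation on
#' \[0, 1\].  The LOD compares the fit against independence (theta = 1, with
#' retention re-fitted).
#'
#' @param m1,m2 marker names or column indices.
#' @param x an [RHGenotypeMatrix-class] or a lines-x-markers matrix.
#' @return list with `theta`, `r`, `lod`, `dcR` and the cell `counts`.
#' @export
twoPoint <- function(m1, m2, x) {
  calls <- .callsOf(x)
  a <- calls[, m1]; b <- calls[, m2]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no informative lines for this marker pair")
  a <- a[ok]; b <- b[ok]
  cnt <- c(n11 = sum(a == 1 & b == 1), n10 = sum(a == 1 & b == 0),
           n01 = sum(a == 0 & b == 1), n00 = sum(a == 0 & b == 0))
  est <- .twoPointFromCounts(cnt)
  c(est, list(counts = cnt))
}

.twoPointFromCounts <- function(cnt) {
  n <- sum(cnt)
  r <- (2 * cnt[["n11"]] + cnt[["n10"]] + cnt[["n01"]]) / (2 * n)
  r <- min(max(r, 1e-9), 1 - 1e-9)
  f <- function(th) .cellLoglik(cnt[["n11"]], cnt[["n10"]], cnt[["n01"]],
                                cnt[["n00"]], th, r)
  theta <- if (cnt[["n10"]] + cnt[["n01"]] == 0) 0 else {
    opt <- optimize(f, c(1e-9, 1 - 1e-9), maximum = TRUE, tol = 1e-9)
    cand <- c(opt$maximum, 1e-9, 1 - 1e-9)
    cand[which.max(vapply(cand, f, numeric(1)))]
  }
  if (theta <= 2e-9) theta <- 0
  if (theta >= 1 - 2e-9) theta <- 1
  lod <- (f(theta) - f(1)) / log(10)
  list(theta = theta, r = r, lod = max(0, lod),
       dcR = if (theta < 1) -100 * log(1 - theta) else Inf)
}

## All-pairs two-point statistics: theta / lod / dcR / pair loglik matrices.
## The pair loglik (at the fitted theta and the global retention estimate)
## is the edge weight used by the order search.
.twoPointAll <- function(calls, r = NULL) {
  p <- ncol(calls)
  if (is.null(r)) r <- mean(calls == 1, na.rm = TRUE)
  r <- min(max(r, 1e-9), 1 - 1e-9)
  theta <- lod <- dcR <- pll <- matrix(NA_real_, p, p)
  A1 <- !is.na(calls) & calls == 1
  A0 <- !is.na(calls) & calls == 0
  N11 <- crossprod(A1)
  N00 <- crossprod(A0)
  N10 <- crossprod(A1, A0)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    cnt <- c(n11 = N11[i, j], n10 = N10[i, j], n01 = N10[j, i],
             n00 = N00[i, j])
    if (sum(cnt) == 0) next
    est <- .twoPointFromCounts(cnt)
    theta[i, j] <- theta[j, i] <- est$theta
    lod[i, j] <- lod[j, i] <- est$lod
    dcR[i, j] <- dcR[j, i] <- est$dcR
    th <- min(max(est$theta, 1e-9), 1 - 1e-9)
    pll[i, j] <- pll[j, i] <- .cellLoglik(cnt[["n11"]], cnt[["n10"]],
                                          cnt[["n01"]], cnt[["n00"]], th, r)
  }
  list(theta = theta, lod = lod, dcR = dcR, pairll = pll, r = r)
}

#' Group markers into linkage groups
#'
#' Connected components of the graph with an edge iff the two-point LOD is
#' at least `lodMin` AND the two-point distance is at most `dMaxCR`.
#'
#' @param x an [RHGenotypeMatrix-class] or calls matrix.
#' @param lodMin two-point LOD threshold (default 4.0).
#' @param dMaxCR maximum two-point distance in centirays (default 100).
#' @return list of character vectors (marker groups), largest first.
#' @export
groupMarkers <- function(x, lodMin = 4.0, dMaxCR = 100) {
  calls <- .callsOf(x)
  tp <- .twoPointAll(calls)
  adj <- !is.na(tp$lod) & tp$lod >= lodMin & tp$dcR <= dMaxCR
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  grps <- split(colnames(calls), comp)
  unname(grps[order(-lengths(grps), vapply(grps, min, character(1)))])
}

#' Collapse co-retained markers into loci
#'
#' Markers whose calls agree on every line where both are non-missing, and
#' which share at least one informative line, merge into one locus
#' (transitive closure).
#'
#' @param x an [RHGenotypeMatrix-class] or calls matrix.
#' @return list with `loci` (named list of marker vectors) and `calls`
#'   (lines x loci consensus matrix; locus named after its lexicographically
#'   first marker).
#' @export
collapseCoretained <- function(x) {
  calls <- .callsOf(x)
  A1 <- !is.na(calls) & calls == 1
  A0 <- !is.na(calls) & calls == 0
  disagree <- crossprod(A1, A0) + crossprod(A0, A1)
  shared <- crossprod(A1 + A0)
  adj <- disagree == 0 & shared >= 1
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  loci <- lapply(unname(split(colnames(calls), comp)), sort)
  loci <- loci[order(vapply(loci, `[`, character(1), 1L))]
  names(loci) <- vapply(loci, `[`, character(1), 1L)
  cons <- vapply(loci, function(mk) {
    sub <- calls[, mk, drop = FALSE]
    apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) v[1L] else NA_integer_
    })
  }, integer(nrow(calls)))
  rownames(cons) <- rownames(calls)
  list(loci = loci, calls = cons)
}

#' Multipoint log-likelihood of a locus order
#'
#' Per line, a two-state Markov chain runs along the order: the first locus
#' is retained with probability `r`; between adjacent loci the state is kept
#' with probability `1 - theta_i`, otherwise re-drawn (retained with
#' probability `r`).  An observation error `epsilon` flips a call; missing
#' calls are marginalised by the forward algorithm.
#'
#' @param order locus names or column indices, in map order.
#' @param x an [RHGenotypeMatrix-class] or calls matrix (lines x loci).
#' @param thetas adjacent breakage probabilities, length `length(order) - 1`.
#' @param r retention probability.
#' @param epsilon per-call error probability (default 0).
#' @return total log-likelihood over lines.
#' @export
multipointLoglik <- function(order, x, thetas, r, epsilon = 0) {
  calls <- .callsOf(x)[, order, drop = FALSE]
  k <- ncol(calls)
  if (k > 1L && length(thetas) != k - 1L)
    stop("'thetas' must have length length(order) - 1")
  if (length(thetas) && any(thetas < 0 | thetas > 1))
    stop("breakage probabilities must lie in [0, 1]")
  emit <- function(obs, state) {
    e <- ifelse(is.na(obs), 1,
                ifelse(obs == state, 1 - epsilon, epsilon))
    e
  }
  a1 <- r * emit(calls[, 1L], 1L)
  a0 <- (1 - r) * emit(calls[, 1L], 0L)
  ll <- 0
  if (k > 1L) for (i in 2L:k) {
    th <- thetas[i - 1L]
    s <- a1 + a0
    ll <- ll + sum(log(s))
    a1 <- a1 / s; a0 <- a0 / s
    n1 <- (a1 * ((1 - th) + th * r) + a0 * (th * r)) * emit(calls[, i], 1L)
    n0 <- (a1 * (th * (1 - r)) + a0 * ((1 - th) + th * (1 - r))) *
      emit(calls[, i], 0L)
    a1 <- n1; a0 <- n0
  }
  ll + sum(log(a1 + a0))
}

#' Count obligate breaks for a locus order
#'
#' Per line, the number of adjacent 1/0 transitions in the ordered call
#' vector after dropping missing calls, summed over lines.
#'
#' @param order locus names or column indices in map order (use a subset for
#'   bin scope: the map region between a bin's distal and proximal markers).
#' @param x an [RHGenotypeMatrix-class] or calls matrix.
#' @return integer break count.
#' @export
countObligateBreaks <- function(order, x) {
  calls <- .callsOf(x)[, order, drop = FALSE]
  sum(apply(calls, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) 0L else sum(diff(v) != 0L)
  }))
}

#' Assign ordered loci to deletion bins
#'
#' Loci sharing an identical presence pattern across the terminal-deletion
#' lines form one bin; bins are ordered along the map.  Each bin is named by
#' the deletion line whose breakpoint defines its proximal end (the boundary
#' toward the centromere), falling back to a positional name for terminal
#' bins.  Supplying `armBoundaryAfter` (the index of the last short-arm
#' locus) splits the bin spanning the centromere into a short-arm and a
#' long-arm bin, prefixed `C-`.
#'
#' @param map an [RHMap-class] (or character vector of locus names in map
#'   order).
#' @param deletionCalls deletion-line genotypes: an [RHGenotypeMatrix-class]
#'   or matrix (lines x loci, column names matching the locus names).
#' @param armBoundaryAfter optional index of the last locus on the short arm.
#' @return data.frame with one row per bin: `bin`, `fromLocus`, `toLocus`
#'   (indices along the map), `nLoci` and `pattern`.
#' @export
assignDeletionBins <- function(map, deletionCalls, armBoundaryAfter = NULL) {
  ord <- if (is(map, "RHMap")) names(map@loci) else map
  calls <- .callsOf(deletionCalls)[, ord, drop = FALSE]
  pat <- apply(calls, 2L, paste, collapse = "/")
  runs <- rle(pat)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (anyDuplicated(runs$values)) {
    dup <- runs$values[duplicated(runs$values)]
    off <- ord[starts[runs$values %in% dup]]
    warning("non-contiguous deletion pattern along the order; ",
            "offending loci: ", paste(head(off, 5L), collapse = ", "))
  }
  bins <- data.frame(fromLocus = starts, toLocus = ends,
                     nLoci = runs$lengths, pattern = runs$values,
                     stringsAsFactors = FALSE)
  if (!is.null(armBoundaryAfter)) {
    k <- which(bins$fromLocus <= armBoundaryAfter &
                 bins$toLocus > armBoundaryAfter)
    if (length(k) == 1L) {
      left <- bins[k, ]; right <- bins[k, ]
      left$toLocus <- armBoundaryAfter
      left$nLoci <- armBoundaryAfter - left$fromLocus + 1L
      right$fromLocus <- armBoundaryAfter + 1L
      right$nLoci <- right$toLocus - right$fromLocus + 1L
      bins <- rbind(bins[seq_len(k - 1L), ], left, right,
                    bins[seq_len(nrow(bins))[-seq_len(k)], ])
      rownames(bins) <- NULL
      attr(bins, "centromereSplit") <- c(k, k + 1L)
    }
  }
  ## name each bin by the line flipping at its proximal boundary
  lines <- rownames(calls)
  nameOf <- function(k) {
    boundary <- if (!is.null(armBoundaryAfter) &&
                    bins$toLocus[k] <= armBoundaryAfter) {
      if (k < nrow(bins)) c(k, k + 1L) else NULL      # short arm: proximal is rightwards
    } else if (k > 1L) c(k - 1L, k) else NULL
    if (is.null(boundary)) return(sprintf("bin%02d", k))
    p1 <- strsplit(bins$pattern[boundary[1L]], "/")[[1L]]
    p2 <- strsplit(bins$pattern[boundary[2L]], "/")[[1L]]
    flip <- which(p1 != p2)
    if (!length(flip)) sprintf("bin%02d", k) else lines[flip[1L]]
  }
  bins$bin <- vapply(seq_len(nrow(bins)), nameOf, character(1))
  cs <- attr(bins, "centromereSplit")
  if (!is.null(cs)) bins$bin[cs] <- paste0("C-", bins$bin[cs])
  bins$bin <- make.unique(bins$bin)
  bins[, c("bin", "fromLocus", "toLocus", "nLoci", "pattern")]
}

#' Map summary statistics
#'
#' Computes the standard resolution summaries of an integrated physical/RH
#' map: average locus spacing in centirays, physical distance per centiray,
#' and physical resolution per obligate break (overall and per deletion
#' bin).  A scope with zero breaks has undefined resolution (`NA`, not
#' infinity).
#'
#' @param totalCR total map length in centirays (or an [RHMap-class], from
#'   which `totalCR`, `nLoci` and `obligateBreaks` are taken).
#' @param nLoci number of loci.
#' @param mappedMb cumulative size of the mapped contigs in Mb.
#' @param obligateBreaks total obligate breaks.
#' @param bins optional data.frame with columns `bin`, `sizeMb`, `breaks`
#'   for per-bin resolution.
#' @return list with `crPerLocus`, `kbPerCR`, `mbPerBreak` and, when bins
#'   are given, `binResolution` (bins with an `mbPerBreak` column).
#' @examples
#' mapSummaries(1560.7, nLoci = 448, mappedMb = 794.8,
#'              obligateBreaks = 1277)
#' @export
mapSummaries <- function(totalCR, nLoci = NULL, mappedMb,
                         obligateBreaks = NULL, bins = NULL) {
  if (is(totalCR, "RHMap")) {
    map <- totalCR
    totalCR <- max(map@positions)
    if (is.null(nLoci)) nLoci <- length(map@loci)
    if (is.null(obligateBreaks)) obligateBreaks <- map@obligateBreaks
  }
  out <- list(crPerLocus = totalCR / nLoci,
              kbPerCR = mappedMb * 1000 / totalCR,
              mbPerBreak = if (obligateBreaks > 0)
                mappedMb / obligateBreaks else NA_real_)
  if (!is.null(bins)) {
    bins$mbPerBreak <- ifelse(bins$breaks > 0, bins$sizeMb / bins$breaks,
                              NA_real_)
    out$binResolution <- bins
  }
  out
}
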