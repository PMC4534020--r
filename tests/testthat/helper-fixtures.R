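# Shared fixtures, all built in code.

# A ContigSet with prescribed membership and CB intervals, for tests that
# exercise downstream stages without re-running the assembler.
makeContigSet <- function(memberTags, membership, cbUnit = 5000,
                          cbStarts = NULL) {
  contigIDs <- unique(membership)
  memb <- list(); info <- list(); ctags <- list()
  for (cid in contigIDs) {
    bacs <- names(membership)[membership == cid]
    starts <- if (is.null(cbStarts)) {
      s <- seq(0, by = 10, length.out = length(bacs))
      setNames(s, bacs)
    } else cbStarts[bacs]
    memb[[cid]] <- data.frame(
      contig = cid, bac = bacs, cbStart = unname(starts),
      cbEnd = unname(starts) + lengths(memberTags[bacs]),
      q = FALSE, stringsAsFactors = FALSE)
    ut <- sort(unique(unlist(memberTags[bacs], use.names = FALSE)))
    info[[cid]] <- data.frame(
      contig = cid, nMembers = length(bacs), uniqueTags = length(ut),
      sizeBp = length(ut) * cbUnit,
      status = if (length(bacs) > 1L) "retained" else "singleton",
      stringsAsFactors = FALSE)
    ctags[[cid]] <- ut
  }
  new("ContigSet", members = do.call(rbind, memb),
      info = do.call(rbind, info),
      contigTags = ctags, cbUnit = cbUnit)
}

# Fingerprints of clones tiled across an interval: clone i covers sites
# [starts[i], ends[i]) of an integer site grid.
tiledFingerprints <- function(starts, ends, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("B%02d", seq_along(starts))
  FingerprintSet(setNames(
    mapply(function(s, e) seq.int(s, e - 1L), starts, ends,
           SIMPLIFY = FALSE), ids))
}

# An RHMap at explicit centiray positions with one marker per locus.
makeRHMap <- function(positions, lociNames = NULL) {
  if (is.null(lociNames)) lociNames <- sprintf("L%03d", seq_along(positions))
  new("RHMap", loci = setNames(as.list(lociNames), lociNames),
      positions = positions - positions[1L],
      thetas = rep(0.1, max(0L, length(positions) - 1L)),
      retention = 0.7, obligateBreaks = 0L, bins = data.frame())
}

# Exhaustive minimal interval cover (oracle for selectMTP): smallest subset
# spanning [min start, max end) with consecutive overlap >= 1 unit.
exhaustiveMTPSize <- function(starts, ends) {
  n <- length(starts)
  lo <- min(starts); hi <- max(ends)
  covers <- function(sel) {
    s <- starts[sel]; e <- ends[sel]
    o <- order(s); s <- s[o]; e <- e[o]
    if (s[1L] > lo) return(FALSE)
    reach <- e[1L]
    for (k in seq_along(s)[-1L]) {
      if (s[k] > reach - 1) return(FALSE)
      reach <- max(reach, e[k])
    }
    reach >= hi
  }
  for (size in 1:n) {
    sets <- utils::combn(n, size, simplify = FALSE)
    if (any(vapply(sets, covers, logical(1)))) return(size)
  }
  n
}

# All permutations of a character vector (factorial oracle helper).
combinat_perms <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in combinat_perms(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], p)
  out
}

# Exhaustive maximal-monotone-run oracle (no outlier skipping): returns
# descending runs of length >= minLen as index ranges.
descendingRunsOracle <- function(y, minLen = 3) {
  n <- length(y)
  runs <- list()
  i <- 1L
  while (i < n) {
    j <- i
    while (j < n && y[j + 1L] < y[j]) j <- j + 1L
    if (j - i + 1L >= minLen) runs[[length(runs) + 1L]] <- c(i, j)
    i <- if (j > i) j else i + 1L
  }
  runs
}
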