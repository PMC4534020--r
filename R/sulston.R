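## Clone-overlap significance for WGP fingerprints (tolerance fixed at 0:
## tags either match exactly or not at all).

#' Sulston score: probability of sharing at least m tags by chance
#'
#' With exact tag matching, a random tag of the larger fingerprint (`nH`
#' tags) hits any given one of `gelLength` possible tags with probability
#' `q = 1 - (1 - 1/gelLength)^nH`.  The score is the binomial upper tail
#' `P(X >= m)` for `X ~ Binomial(nL, q)`, where `nL <= nH` are the two tag
#' counts and `m` the number of shared tags.  Low scores indicate overlaps
#' unlikely to arise by chance.
#'
#' The computation is carried out in log space, so [sulstonLog10()] stays
#' finite far below the smallest normal double; `sulstonScore()` itself
#' underflows to 0 below ~1e-308.
#'
#' @param f1,f2 integer tag vectors (one fingerprint each).
#' @param gelLength number of distinct possible tags (G); must be at least
#'   the larger tag count.
#' @return `sulstonScore()`: the probability in \[0, 1\].
#' @examples
#' sulstonScore(1:20, 1:20, gelLength = 120913)   # ~1e-76: clear overlap
#' sulstonScore(1:20, 21:40, gelLength = 120913)  # 1: nothing shared
#' @export
sulstonScore <- function(f1, f2, gelLength) {
  m <- length(intersect(f1, f2))
  10^sulstonLog10(length(unique(f1)), length(unique(f2)), m, gelLength)
}

#' @rdname sulstonScore
#' @param n1,n2 tag counts of the two fingerprints (vectorised).
#' @param m shared tag count (vectorised).
#' @return `sulstonLog10()`: log10 of the score (vectorised over
#'   `n1`, `n2`, `m`).
#' @export
sulstonLog10 <- function(n1, n2, m, gelLength) {
  if (length(gelLength) != 1L || is.na(gelLength) || gelLength <= 0)
    stop("'gelLength' must be a single positive count")
  if (any(n1 <= 0 | n2 <= 0))
    stop("fingerprints must carry at least one tag")
  nL <- pmin(n1, n2)
  nH <- pmax(n1, n2)
  if (gelLength < max(nH))
    stop("'gelLength' must be >= the larger tag count")
  if (any(m > nL)) stop("shared count exceeds the smaller fingerprint")
  q <- 1 - (1 - 1 / gelLength)^nH
  ## P(X >= m) = upper tail at m - 1; exactly 1 when m = 0
  out <- pbinom(m - 1, nL, q, lower.tail = FALSE, log.p = TRUE) / log(10)
  out[m == 0] <- 0
  out
}
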