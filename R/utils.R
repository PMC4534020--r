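## Internal helpers.

## Per-component child seeds derived from one master seed, so that each
## simulation component consumes an independent, reproducible stream.
## Scheme: child = (seed mod 2000003) * 1000 + component offset (< 2^31).
.childSeed <- function(seed, component) {
  offs <- c(chromosome = 1L, library = 2L, tags = 3L, panel = 4L,
            deletion = 5L, markers = 6L, genotype = 7L, noise = 8L)
  if (!component %in% names(offs))
    stop("unknown seed component: ", component)
  (as.integer(seed) %% 2000003L) * 1000L + offs[[component]]
}

.assertCount <- function(x, name, positive = TRUE) {
  if (length(x) != 1L || is.na(x) || x != round(x) || (positive && x <= 0) ||
      (!positive && x < 0))
    stop("'", name, "' must be a single ",
         if (positive) "positive" else "non-negative", " integer")
  as.integer(x)
}

.assertFraction <- function(x, name, lo = 0, hi = 1,
                            loOpen = FALSE, hiOpen = FALSE) {
  bad <- length(x) != 1L || is.na(x) ||
    (if (loOpen) x <= lo else x < lo) ||
    (if (hiOpen) x >= hi else x > hi)
  if (bad)
    stop("'", name, "' must lie in ", if (loOpen) "(" else "[", lo, ", ", hi,
         if (hiOpen) ")" else "]")
  as.numeric(x)
}

## Stable lexicographic tie-break: order by key, then id.
.orderBy <- function(key, id, decreasing = FALSE) {
  order(if (decreasing) -xtfrm(key) else xtfrm(key), id)
}
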