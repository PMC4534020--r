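test_that("two-point: identical columns give zero breakage and zero distance", {
  calls <- cbind(a = c(1, 1, 0, 0, 1, 0), b = c(1, 1, 0, 0, 1, 0))
  rownames(calls) <- paste0("l", 1:6)
  est <- twoPoint("a", "b", calls)
  expect_equal(est$theta, 0)
  expect_equal(est$dcR, 0)
  expect_error(twoPoint("a", "b", matrix(NA_integer_, 2, 2,
                                         dimnames = list(c("x", "y"),
                                                         c("a", "b")))),
               "informative")
})

test_that("two-point estimates match a brute-force grid oracle", {
  cnt <- c(n11 = 40, n10 = 5, n01 = 5, n00 = 50)
  calls <- rbind(
    matrix(rep(c(1, 1), cnt["n11"]), ncol = 2, byrow = TRUE),
    matrix(rep(c(1, 0), cnt["n10"]), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 1), cnt["n01"]), ncol = 2, byrow = TRUE),
    matrix(rep(c(0, 0), cnt["n00"]), ncol = 2, byrow = TRUE))
  dimnames(calls) <- list(sprintf("l%03d", 1:100), c("a", "b"))
  est <- twoPoint("a", "b", calls)
  ## grid oracle over (theta, r): coarse scan then 1e-4 refinement
  ll <- function(th, r) {
    p11 <- r * (1 - th) + r^2 * th
    p10 <- r * th * (1 - r)
    p00 <- (1 - r) * (1 - th) + (1 - r)^2 * th
    40 * log(p11) + 10 * log(p10) + 50 * log(p00)
  }
  coarse <- expand.grid(th = seq(0.01, 0.99, by = 0.01),
                        r = seq(0.01, 0.99, by = 0.01))
  v <- mapply(ll, coarse$th, coarse$r)
  top <- coarse[which.max(v), ]
  fine <- expand.grid(th = seq(max(1e-4, top$th - 0.01),
                               min(1 - 1e-4, top$th + 0.01), by = 1e-4),
                      r = seq(max(1e-4, top$r - 0.01),
                              min(1 - 1e-4, top$r + 0.01), by = 1e-4))
  vf <- mapply(ll, fine$th, fine$r)
  best <- fine[which.max(vf), ]
  expect_equal(est$theta, best$th, tolerance = 1e-3)
  expect_equal(est$r, best$r, tolerance = 1e-3)
  lodOracle <- (max(vf) - ll(1 - 1e-12, est$r)) / log(10)
  expect_equal(est$lod, lodOracle, tolerance = 1e-2)
})

test_that("independent markers rarely clear the LOD 4 linkage threshold", {
  set.seed(101)
  below <- vapply(1:200, function(i) {
    calls <- cbind(a = rbinom(355, 1, 0.7), b = rbinom(355, 1, 0.7))
    rownames(calls) <- paste0("l", 1:355)
    twoPoint("a", "b", calls)$lod < 4.0
  }, logical(1))
  expect_gte(mean(below), 0.99)
})

test_that("linkage grouping takes connected components under LOD and distance limits", {
  model <- simulateChromosome(60e6, 27e6, 0, seed = 23)
  panel <- simulateRhPanel(model, 300, meanBreaks = 6, retention = 0.5,
                           seed = 23)
  posA <- setNames(seq(2e6, 12e6, by = 2e6), sprintf("A%d", 1:6))
  gA <- genotypeCalls(genotypeMarkers(panel, posA))
  ## all mutually linked markers form one group
  expect_length(groupMarkers(gA), 1L)
  ## a second, unlinked chromosome: markers genotyped on an independent panel
  panel2 <- simulateRhPanel(model, 300, meanBreaks = 6, retention = 0.5,
                            seed = 24)
  gB <- genotypeCalls(genotypeMarkers(panel2, setNames(posA,
                                                       sprintf("B%d", 1:6))))
  grps <- groupMarkers(cbind(gA, gB))
  expect_length(grps, 2L)
  expect_setequal(grps[[which(vapply(grps, function(g) "A1" %in% g,
                                     logical(1)))]], names(posA))
  ## an all-missing-information marker is its own group
  gC <- cbind(gA, C1 = rep(c(0L, 1L), length.out = 300))
  set.seed(1); gC[, "C1"] <- sample(gC[, "C1"])
  expect_true(any(lengths(groupMarkers(gC)) == 1L))
})

test_that("co-retained markers collapse into loci by transitive agreement", {
  calls <- cbind(a = c(1, 0, 1, NA), b = c(1, 0, 1, 0), c = c(1, 0, 0, 0))
  rownames(calls) <- paste0("l", 1:4)
  col <- collapseCoretained(calls)
  expect_length(col$loci, 2L)
  expect_setequal(col$loci[["a"]], c("a", "b"))   # differ nowhere observed
  expect_setequal(col$loci[["c"]], "c")           # differs from b on line 3
  ## duplicate columns collapse to one locus
  dup <- cbind(x = c(1, 0, 1), y = c(1, 0, 1))
  rownames(dup) <- paste0("l", 1:3)
  expect_length(collapseCoretained(dup)$loci, 1L)
})

test_that("653 markers on 448 distinct fragment patterns collapse to 448 loci", {
  model <- simulateChromosome(914e6, 415e6, 0, seed = 29)
  ## a dense panel makes all 448 position patterns distinct
  panel <- simulateRhPanel(model, 355, meanBreaks = 20, retention = 0.7,
                           seed = 29)
  basePos <- seq(1e6, 913e6, length.out = 448)   # well-separated positions
  idx <- sort(c(seq_len(448), sample.int(448, 653 - 448, replace = TRUE)))
  pos <- setNames(basePos[idx], sprintf("M%03d", seq_along(idx)))
  g <- genotypeMarkers(panel, pos)
  truePatterns <- length(unique(apply(
    genotypeCalls(g)[, !duplicated(idx), drop = FALSE], 2L, paste,
    collapse = "")))
  expect_equal(truePatterns, 448L)
  expect_length(collapseCoretained(g)$loci, 448L)
})

test_that("multipoint likelihood reduces correctly and matches path enumeration", {
  r <- 0.6
  calls <- matrix(c(1, 0, 1, 1, 0), ncol = 1,
                  dimnames = list(paste0("l", 1:5), "a"))
  expect_equal(multipointLoglik("a", calls, numeric(0), r),
               3 * log(r) + 2 * log(1 - r))
  set.seed(33)
  toy <- matrix(rbinom(24, 1, 0.6), 6, 4,
                dimnames = list(paste0("l", 1:6), paste0("m", 1:4)))
  thetas <- c(0.2, 0.35, 0.1)
  brute <- function(ord, thetas) {
    tot <- 0
    states <- as.matrix(expand.grid(rep(list(0:1), length(ord))))
    for (i in seq_len(nrow(toy))) {
      obs <- toy[i, ord]
      pLine <- 0
      for (s in seq_len(nrow(states))) {
        st <- states[s, ]
        if (!all(st == obs)) next
        p <- if (st[1] == 1) r else 1 - r
        for (k in seq_along(ord)[-1]) {
          th <- thetas[k - 1]
          p <- p * ((1 - th) * (st[k] == st[k - 1]) +
                      th * (if (st[k] == 1) r else 1 - r))
        }
        pLine <- pLine + p
      }
      tot <- tot + log(pLine)
    }
    as.numeric(tot)
  }
  expect_equal(multipointLoglik(1:4, toy, thetas, r), brute(1:4, thetas))
  ## reversal with the same (symmetric) thetas leaves the likelihood fixed
  expect_equal(multipointLoglik(4:1, toy, rev(thetas), r),
               multipointLoglik(1:4, toy, thetas, r))
  expect_error(multipointLoglik(1:4, toy, c(0.2, 1.3, 0.1), r), "\\[0, 1\\]")
})

test_that("obligate break counting is an exact transition count", {
  calls <- rbind(l1 = c(1, 1, 1, 1), l2 = c(1, 0, 1, 0))
  colnames(calls) <- paste0("m", 1:4)
  expect_equal(countObligateBreaks(1:4, calls["l1", , drop = FALSE]), 0L)
  expect_equal(countObligateBreaks(1:4, calls["l2", , drop = FALSE]), 3L)
  set.seed(3)
  toy <- matrix(rbinom(36, 1, 0.5), 6, 6,
                dimnames = list(paste0("l", 1:6), paste0("m", 1:6)))
  toy[2, 3] <- NA
  direct <- sum(apply(toy, 1, function(v) {
    v <- v[!is.na(v)]
    sum(abs(diff(v)))
  }))
  expect_equal(countObligateBreaks(1:6, toy), direct)
})

test_that("the true order has no more obligate breaks than random permutations", {
  model <- simulateChromosome(50e6, 22e6, 0, seed = 41)
  panel <- simulateRhPanel(model, 200, meanBreaks = 6, retention = 0.6,
                           seed = 41)
  pos <- sort(runif(15, 0, 50e6))
  names(pos) <- sprintf("L%02d", order(order(pos)))
  g <- genotypeMarkers(panel, pos)
  truth <- names(sort(pos))
  b0 <- countObligateBreaks(truth, g)
  set.seed(41)
  for (k in 1:100)
    expect_gte(countObligateBreaks(sample(truth), g), b0)
})

test_that("centiray distance is zero at theta 0, increasing, and diverges at 1", {
  th <- seq(0, 0.99, by = 0.01)
  d <- -100 * log(1 - th)
  expect_equal(d[1], 0)
  expect_true(all(diff(d) > 0))
  calls <- cbind(a = rep(c(1, 0), 25), b = rep(c(0, 1), 25))
  rownames(calls) <- paste0("l", 1:50)
  expect_equal(twoPoint("a", "b", calls)$dcR, Inf)
})

test_that("locus ordering finds the maximum-likelihood order for small groups", {
  set.seed(51)
  model <- simulateChromosome(30e6, 14e6, 0, seed = 51)
  for (k in c(3, 5, 6)) {
    panel <- simulateRhPanel(model, 150, meanBreaks = 5, retention = 0.6,
                             seed = 50 + k)
    pos <- sort(runif(k, 0, 30e6))
    names(pos) <- sprintf("L%d", seq_len(k))
    g <- genotypeCalls(genotypeMarkers(panel, pos))
    map <- orderLoci(g)
    ord <- names(rhLoci(map))
    ## oracle: exhaustive search over all orders, scored by the multipoint
    ## likelihood with two-point adjacent breakage estimates
    score <- function(o) {
      th <- vapply(seq_len(k - 1), function(i)
        min(max(twoPoint(o[i], o[i + 1], g)$theta, 1e-9), 1 - 1e-9),
        numeric(1))
      multipointLoglik(o, g, th, mean(g == 1))
    }
    perms <- combinat_perms(colnames(g))
    best <- max(vapply(perms, score, numeric(1)))
    expect_equal(score(ord), best, tolerance = 1e-6)
  }
})

test_that("deletion bins form from presence patterns, split at the centromere", {
  model <- simulateChromosome(914e6, 415e6, 0, seed = 61)
  sBr <- seq(40e6, 390e6, length.out = 8)
  lBr <- seq(440e6, 890e6, length.out = 10)
  del <- simulateDeletionLines(model, sBr, lBr)
  pos <- sort(c(seq(5e6, 910e6, by = 12e6), 410e6))
  names(pos) <- sprintf("P%03d", seq_along(pos))
  g <- genotypeMarkers(del, pos)
  ord <- names(pos)
  armLast <- max(which(pos < model@armBoundary))
  bins <- assignDeletionBins(ord, g, armBoundaryAfter = armLast)
  expect_equal(nrow(bins), 20L)     # 18 breakpoints + centromere split
  expect_equal(sum(bins$nLoci), length(ord))
  ## one deletion line alone defines at most two bins
  one <- simulateDeletionLines(model, sBr[1], numeric(0))
  bins1 <- assignDeletionBins(ord, genotypeMarkers(one, pos))
  expect_lte(nrow(bins1), 2L)
  ## all lines retaining everything: a single bin
  allRet <- lapply(del, function(ln) {
    ln$intervals <- matrix(c(0, model@length), 1L); ln
  })
  expect_equal(nrow(assignDeletionBins(ord, genotypeMarkers(allRet, pos))),
               1L)
})

test_that("map summary arithmetic reproduces the standard resolution measures", {
  s <- mapSummaries(1560.7, nLoci = 448, mappedMb = 794.8,
                    obligateBreaks = 1277)
  expect_equal(round(s$crPerLocus, 1), 3.5)
  expect_equal(round(s$kbPerCR), 509)
  expect_equal(round(s$mbPerBreak, 2), 0.62)
  bins <- data.frame(bin = c("6BS7", "zero"), sizeMb = c(84.3, 10),
                     breaks = c(180, 0))
  sb <- mapSummaries(100, 10, 100, 50, bins = bins)
  expect_equal(round(sb$binResolution$mbPerBreak[1], 2), 0.47)
  expect_true(is.na(sb$binResolution$mbPerBreak[2]))   # undefined, not Inf
})

test_that("retention probability is recovered within 0.03 at 355 lines", {
  model <- simulateChromosome(100e6, 45e6, 0, seed = 71)
  panel <- simulateRhPanel(model, 355, meanBreaks = 8, retention = 0.7,
                           seed = 71)
  pos <- sort(runif(30, 0, 100e6))
  names(pos) <- sprintf("L%02d", seq_along(pos))
  g <- genotypeCalls(genotypeMarkers(panel, pos))
  map <- orderLoci(g)
  expect_lt(abs(map@retention - 0.7), 0.03)
})
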