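test_that("marker de-duplication keeps one representative per cluster", {
  ## identical duplicates collapse to one representative
  idm <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(dedupeGeneMarkers(idm, c(a = 100, b = 90)), "a")
  ## an all-distinct set is unchanged
  d <- diag(3); dimnames(d) <- list(letters[1:3], letters[1:3])
  expect_equal(dedupeGeneMarkers(d, setNames(c(10, 20, 30), letters[1:3])),
               letters[1:3])
  ## three clusters by construction: three representatives, longest first
  ids <- c("x1", "x2", "y1", "y2", "y3", "z1")
  cluster <- c(1, 1, 2, 2, 2, 3)
  lens <- setNames(c(50, 80, 70, 70, 60, 40), ids)
  idm3 <- outer(cluster, cluster, function(a, b) ifelse(a == b, 0.99, 0.1))
  dimnames(idm3) <- list(ids, ids)
  reps <- dedupeGeneMarkers(idm3, lens)
  expect_setequal(reps, c("x2", "y1", "z1"))   # longest per cluster, tie by id
  expect_equal(reps,
               dedupeGeneMarkers(data.frame(id = ids, cluster = cluster),
                                 lens))
})

test_that("gene transfer uses unique tag hits and discards conflicted sequence contigs", {
  tags <- list(A1 = 1:20, A2 = 15:35, B1 = 500:520, B2 = 515:535)
  cs <- makeContigSet(tags, setNames(c("CTGA", "CTGA", "CTGB", "CTGB"),
                                     names(tags)))
  genes <- data.frame(seqContig = c("sc1", "sc1", "sc2"),
                      geneID = c("g1", "g2", "g3"), stringsAsFactors = FALSE)
  ## sc1 hit only by CTGA tags; sc2 hit by tags of both distant contigs
  hits <- data.frame(tag = c(2L, 16L, 18L, 510L),
                     seqContig = c("sc1", "sc1", "sc2", "sc2"))
  out <- assignGenesViaTags(hits, genes, cs)
  expect_setequal(out$assignments$geneID, c("g1", "g2"))
  expect_true(all(out$assignments$contig == "CTGA"))
  expect_equal(out$discarded$seqContig, "sc2")
  expect_equal(out$unassigned, "g3")
  ## conservation: assigned + unassigned = input genes
  expect_setequal(c(out$assignments$geneID, out$unassigned), genes$geneID)
  ## co-located contigs are allowed to share a sequence contig
  pl <- data.frame(contig = c("CTGA", "CTGB"), locusIndex = 1L,
                   locusName = "L1", positionCR = c(10, 20),
                   orientation = "unknown", withinLocusRank = 1:2,
                   basis = "rh", stringsAsFactors = FALSE)
  out2 <- assignGenesViaTags(hits, genes, cs, placements = pl)
  expect_true("g3" %in% out2$assignments$geneID)
})

test_that("a simulated pipeline transfers most genes to their true contig", {
  model <- simulateChromosome(6e6, 2.5e6, nGenes = 60, seed = 83)
  clones <- simulateBacLibrary(model, 8, purity = 1, seed = 83)
  w <- simulateWgpTags(model, clones, dropout = 0, seed = 83)
  p <- assemblyParams(gelLength = 120913, cbUnit = 130e3 / 20.6,
                      initialCutoffExp = -30, finalCutoffExp = -15)
  cs <- buildContigs(w$fingerprints, -15, p)
  mb <- contigMembers(cs)
  sites <- w$sites[w$sites$chrom == model@name, ]
  ## survey sequence contigs: 50 kb windows carrying genes; hit by the tags
  ## inside them
  genes <- data.frame(seqContig = sprintf("sc%03d", seq_along(model@genePositions)),
                      geneID = sprintf("G%03d", seq_along(model@genePositions)),
                      stringsAsFactors = FALSE)
  hits <- do.call(rbind, lapply(seq_along(model@genePositions), function(i) {
    gpos <- model@genePositions[i]
    tg <- sites$tag[sites$pos >= gpos - 25e3 & sites$pos < gpos + 25e3]
    if (!length(tg)) return(NULL)
    data.frame(tag = tg, seqContig = sprintf("sc%03d", i))
  }))
  out <- assignGenesViaTags(hits, genes, cs)
  ## truth: the contig of the clones spanning the gene position
  mid <- setNames((clones$start + clones$end) / 2, clones$bacID)
  trueContig <- vapply(out$assignments$geneID, function(g) {
    gpos <- model@genePositions[match(g, genes$geneID)]
    hit <- which(clones$start <= gpos & clones$end > gpos)
    names(sort(table(mb$contig[match(clones$bacID[hit], mb$bac)]),
               decreasing = TRUE))[1L]
  }, character(1))
  acc <- mean(out$assignments$contig == trueContig)
  expect_gte(acc, 0.95)
})

test_that("gene density is genes per Mb in map order, split by synteny class", {
  info <- data.frame(contig = c("C1", "C2"), nMembers = 3, uniqueTags = 1,
                     sizeBp = c(1e6, 2e6), status = "retained",
                     stringsAsFactors = FALSE)
  pl <- data.frame(contig = c("C2", "C1"), locusIndex = c(2L, 1L),
                   locusName = c("L2", "L1"), positionCR = c(10, 0),
                   orientation = "unknown", withinLocusRank = 1L,
                   basis = "rh", stringsAsFactors = FALSE)
  ga <- data.frame(geneID = c("g1", "g2", "g3"),
                   contig = c("C1", "C2", "C2"),
                   syntenic = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  prof <- geneDensityProfile(pl, ga, info)
  expect_equal(prof$contig, c("C1", "C2"))    # map order
  expect_equal(prof$density, c(1.0, 1.0))
  expect_equal(prof$densitySyntenic, c(1.0, 0.5))
  ## zero genes give density zero; zero sizes error
  prof0 <- geneDensityProfile(pl, ga[0, ], info)
  expect_equal(prof0$density, c(0, 0))
  info$sizeBp[1] <- 0
  expect_error(geneDensityProfile(pl, ga, info), "zero-size")
})

test_that("a telomere gradient carried by nonsyntenic genes shows only in their sub-profile", {
  model <- simulateChromosome(100e6, 50e6, nGenes = 0, seed = 91)
  set.seed(91)
  nC <- 40
  bounds <- seq(0, 100e6, length.out = nC + 1)
  info <- data.frame(contig = sprintf("C%02d", 1:nC), nMembers = 3,
                     uniqueTags = 1, sizeBp = diff(bounds),
                     status = "retained", stringsAsFactors = FALSE)
  pl <- data.frame(contig = info$contig, locusIndex = seq_len(nC),
                   locusName = sprintf("L%02d", 1:nC),
                   positionCR = seq(0, 390, by = 10),
                   orientation = "unknown", withinLocusRank = 1L,
                   basis = "rh", stringsAsFactors = FALSE)
  mid <- (head(bounds, -1) + tail(bounds, -1)) / 2
  dist <- abs(mid - 50e6) / 50e6           # distance from the centromere
  nSyn <- rpois(nC, 6)                     # flat syntenic density
  nNon <- rpois(nC, 1 + 8 * dist)          # telomere-increasing nonsyntenic
  ga <- do.call(rbind, lapply(1:nC, function(i) {
    k <- nSyn[i] + nNon[i]
    if (!k) return(NULL)
    data.frame(geneID = sprintf("G%02d_%02d", i, seq_len(k)),
               contig = info$contig[i],
               syntenic = rep(c(TRUE, FALSE), c(nSyn[i], nNon[i])))
  }))
  prof <- geneDensityProfile(pl, ga, info)
  rNon <- cor(dist, prof$densityNonsyntenic, method = "spearman")
  rSyn <- cor(dist, prof$densitySyntenic, method = "spearman")
  expect_gt(rNon, 0.5)
  expect_lt(abs(rSyn), 0.4)
})

test_that("rearrangement detection matches the monotone-run oracle", {
  ## perfectly colinear: no blocks
  lin <- data.frame(geneID = sprintf("g%02d", 1:20),
                    wheatPos = (1:20) * 1e6, refPos = (1:20) * 1e5)
  expect_equal(nrow(detectRearrangements(lin)), 0L)
  ## globally reversed: one inversion spanning all genes
  rev1 <- transform(lin, refPos = rev(refPos))
  out <- detectRearrangements(rev1)
  expect_equal(nrow(out), 1L)
  expect_equal(out$kind, "inversion")
  expect_equal(c(out$fromIndex, out$toIndex), c(1L, 20L))
  ## genes 8..12 reversed: exactly one inversion covering 8..12
  y <- (1:20) * 1e5
  y[8:12] <- rev(y[8:12])
  inv <- transform(lin, refPos = y)
  out2 <- detectRearrangements(inv)
  expect_equal(nrow(out2), 1L)
  expect_equal(out2$kind, "inversion")
  expect_equal(c(out2$fromIndex, out2$toIndex), c(8L, 12L))
  oracle <- descendingRunsOracle(y, minLen = 3)
  expect_equal(list(c(out2$fromIndex, out2$toIndex)), oracle)
})

test_that("rearrangement detection is invariant to shifts and scalings of reference coordinates", {
  y <- (1:20) * 1e5
  y[5:9] <- rev(y[5:9])
  base <- data.frame(geneID = sprintf("g%02d", 1:20),
                     wheatPos = (1:20) * 1e6, refPos = y)
  a <- detectRearrangements(base)
  b <- detectRearrangements(transform(base, refPos = refPos * 3 + 7e6),
                            translocOffset = 5e6 * 3)
  expect_equal(a[, c("kind", "fromIndex", "toIndex", "nGenes")],
               b[, c("kind", "fromIndex", "toIndex", "nGenes")])
  ## reversing the whole wheat order maps the inversion onto itself
  revd <- base[rev(seq_len(nrow(base))), ]
  revd$wheatPos <- sort(revd$wheatPos)
  cc <- detectRearrangements(revd)
  expect_equal(cc$nGenes, a$nGenes)
  expect_equal(sort(21L - c(cc$toIndex, cc$fromIndex)),
               sort(c(a$fromIndex, a$toIndex)))
})

test_that("displaced blocks are called translocations", {
  y <- (1:30) * 1e5
  y[10:15] <- y[10:15] + 20e6          # displaced ascending block
  tr <- data.frame(geneID = sprintf("g%02d", 1:30),
                   wheatPos = (1:30) * 1e6, refPos = y)
  out <- detectRearrangements(tr)
  expect_true("translocation" %in% out$kind)
  hit <- out[out$kind == "translocation", ][1, ]
  expect_lte(abs(hit$fromIndex - 10L), 1L)
  expect_lte(abs(hit$toIndex - 15L), 1L)
  ## displaced and reversed: translocation (inversion)
  y2 <- (1:30) * 1e5
  y2[10:15] <- rev(y2[10:15]) + 20e6
  out2 <- detectRearrangements(transform(tr, refPos = y2))
  expect_true("translocation (inversion)" %in% out2$kind)
})

test_that("synteny link export conserves counts per reference chromosome", {
  links <- data.frame(wheatPos = runif(1000, 0, 900e6),
                      refChrom = sample(c("Os02", "Bradi3", "Sb04"), 1000,
                                        replace = TRUE),
                      refPos = runif(1000, 0, 40e6))
  path <- tempfile(fileext = ".tsv")
  out <- syntenyLinkTable(links, path)
  expect_equal(sum(out$counts$n), 1000L)
  expect_equal(nrow(out$counts), 3L)
  reread <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(reread), 1000L)
  ## empty input: header-only file
  p2 <- tempfile(fileext = ".tsv")
  out0 <- syntenyLinkTable(links[0, ], p2)
  expect_equal(nrow(out0$table), 0L)
  expect_equal(readLines(p2), "wheatPos\trefChrom\trefPos")
})
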