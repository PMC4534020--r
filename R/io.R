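## Readers and writers.  All writers are deterministic given identical
## inputs (stable orders, fixed float formatting).  BED is 0-based
## half-open; AGP and GFF3 are 1-based inclusive; each file says so in a
## header comment.

#' Read / write WGP fingerprints
#'
#' TSV with columns `bac_id` and `tags` (comma-separated integer tag ids).
#' Reading collapses duplicate tags per clone with a warning; a duplicated
#' BAC id is an error naming the clone.  `writeFingerprints()` followed by
#' `readFingerprints()` is the identity.
#'
#' @param path file path.
#' @return A [FingerprintSet-class].
#' @export
readFingerprints <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = "character", comment.char = "#")
  if (!all(c("bac_id", "tags") %in% names(df)))
    stop("fingerprint TSV needs 'bac_id' and 'tags' columns")
  dup <- df$bac_id[duplicated(df$bac_id)]
  if (length(dup))
    stop("duplicate BAC id in fingerprint file: ", dup[1L])
  tags <- lapply(strsplit(df$tags, ","), function(v)
    as.integer(v[nzchar(v)]))
  names(tags) <- df$bac_id
  FingerprintSet(tags)
}

#' @rdname readFingerprints
#' @param fp a [FingerprintSet-class].
#' @export
writeFingerprints <- function(fp, path) {
  stopifnot(is(fp, "FingerprintSet"))
  df <- data.frame(bac_id = names(fp),
                   tags = vapply(fp@tags, paste, character(1),
                                 collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write RH genotype matrices
#'
#' CSV, lines in rows and markers in columns, values 1/0/NA.
#'
#' @param path file path.
#' @return An [RHGenotypeMatrix-class].
#' @export
readGenotypes <- function(path) {
  m <- as.matrix(read.csv(path, row.names = 1L, check.names = FALSE))
  RHGenotypeMatrix(m)
}

#' @rdname readGenotypes
#' @param x an [RHGenotypeMatrix-class].
#' @export
writeGenotypes <- function(x, path) {
  stopifnot(is(x, "RHGenotypeMatrix"))
  write.csv(x@calls, path, quote = FALSE)
  invisible(path)
}

#' Write the contig table
#'
#' @param contigs a [ContigSet-class].
#' @param path output TSV path.
#' @export
writeContigTable <- function(contigs, path) {
  stopifnot(is(contigs, "ContigSet"))
  info <- contigs@info
  mb <- contigs@members
  info$members <- vapply(info$contig, function(cid)
    paste(mb$bac[mb$contig == cid], collapse = ","), character(1))
  info$cbStarts <- vapply(info$contig, function(cid)
    paste(mb$cbStart[mb$contig == cid], collapse = ","), character(1))
  write.table(info, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write placements as AGP 2.1
#'
#' One object (the chromosome map); components are contigs in map order with
#' orientation `+`/`-`/`?`; inter-contig gaps are `U 100 contig no`
#' (unknown-size gaps).  Coordinates are 1-based inclusive.
#'
#' @param placements output of [placeContigs()] (placed rows are used, in
#'   map order).
#' @param contigs a [ContigSet-class] (component lengths).
#' @param path output path.
#' @param object object (chromosome) name.
#' @return the path, invisibly.
#' @export
writeAgp <- function(placements, contigs, path, object = "chr") {
  info <- if (is(contigs, "ContigSet")) contigs@info else contigs
  pl <- placements[!is.na(placements$positionCR), , drop = FALSE]
  pl <- pl[order(pl$positionCR, pl$withinLocusRank, pl$contig), ,
           drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##agp-version\t2.1",
               "# coordinates: 1-based inclusive"), con)
  pos <- 0L
  part <- 0L
  for (k in seq_len(nrow(pl))) {
    if (k > 1L) {
      part <- part + 1L
      writeLines(paste(object, pos + 1L, pos + 100L, part, "U", 100L,
                       "contig", "no", "na", sep = "\t"), con)
      pos <- pos + 100L
    }
    len <- as.integer(round(info$sizeBp[info$contig == pl$contig[k]]))
    ori <- pl$orientation[k]
    if (ori == "unknown") ori <- "?"
    part <- part + 1L
    writeLines(paste(object, pos + 1L, pos + len, part, "W",
                     pl$contig[k], 1L, len, ori, sep = "\t"), con)
    pos <- pos + len
  }
  invisible(path)
}

#' Read an AGP file back into a component table
#'
#' @param path AGP path written by [writeAgp()].
#' @return data.frame of component (`W`) lines.
#' @export
readAgp <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  f <- strsplit(ln, "\t")
  rows <- Filter(function(v) v[5L] == "W", f)
  data.frame(object = vapply(rows, `[`, character(1), 1L),
             objectStart = as.integer(vapply(rows, `[`, character(1), 2L)),
             objectEnd = as.integer(vapply(rows, `[`, character(1), 3L)),
             component = vapply(rows, `[`, character(1), 6L),
             orientation = vapply(rows, `[`, character(1), 9L),
             stringsAsFactors = FALSE)
}

#' Write placements as BED
#'
#' 0-based half-open cumulative map coordinates, mirroring the AGP layout.
#'
#' @inheritParams writeAgp
#' @export
writeBed <- function(placements, contigs, path, object = "chr") {
  info <- if (is(contigs, "ContigSet")) contigs@info else contigs
  pl <- placements[!is.na(placements$positionCR), , drop = FALSE]
  pl <- pl[order(pl$positionCR, pl$withinLocusRank, pl$contig), ,
           drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 0-based half-open", con)
  pos <- 0L
  for (k in seq_len(nrow(pl))) {
    if (k > 1L) pos <- pos + 100L
    len <- as.integer(round(info$sizeBp[info$contig == pl$contig[k]]))
    ori <- pl$orientation[k]
    if (ori == "unknown") ori <- "."
    writeLines(paste(object, pos, pos + len, pl$contig[k], 0L, ori,
                     sep = "\t"), con)
    pos <- pos + len
  }
  invisible(path)
}

#' Write simulated genes as GFF3
#'
#' @param model a [ChromosomeModel-class].
#' @param path output path.
#' @export
writeGff3 <- function(model, path) {
  stopifnot(is(model, "ChromosomeModel"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", model@name,
                       as.integer(model@length))), con)
  gp <- model@genePositions
  for (i in seq_along(gp)) {
    s <- as.integer(floor(gp[i])) + 1L          # to 1-based inclusive
    writeLines(paste(model@name, "wgpmap", "gene", s, s + 999L, ".", "+",
                     ".", sprintf("ID=G%05d", i), sep = "\t"), con)
  }
  invisible(path)
}
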