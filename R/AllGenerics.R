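#' Accessors for wgpmap containers
#'
#' @param x a wgpmap S4 object.
#' @name accessors
NULL

#' @describeIn accessors genotype call matrix of an [RHGenotypeMatrix-class].
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
setMethod("genotypeCalls", "RHGenotypeMatrix", function(x) x@calls)

#' @describeIn accessors number of tags per fingerprint.
#' @export
setGeneric("nTags", function(x) standardGeneric("nTags"))
setMethod("nTags", "FingerprintSet",
          function(x) vapply(x@tags, length, integer(1)))

#' @describeIn accessors fingerprint tag list.
#' @export
setGeneric("fingerprintTags", function(x) standardGeneric("fingerprintTags"))
setMethod("fingerprintTags", "FingerprintSet", function(x) x@tags)

#' @describeIn accessors per-contig summary table of a [ContigSet-class].
#' @export
setGeneric("contigInfo", function(x) standardGeneric("contigInfo"))
setMethod("contigInfo", "ContigSet", function(x) x@info)

#' @describeIn accessors member table (BAC placements) of a [ContigSet-class].
#' @export
setGeneric("contigMembers", function(x) standardGeneric("contigMembers"))
setMethod("contigMembers", "ContigSet", function(x) x@members)

#' @describeIn accessors unique tag sets per contig.
#' @export
setGeneric("contigTags", function(x) standardGeneric("contigTags"))
setMethod("contigTags", "ContigSet", function(x) x@contigTags)

#' @describeIn accessors consensus-band unit (bp per tag interval).
#' @export
setGeneric("cbUnit", function(x) standardGeneric("cbUnit"))
setMethod("cbUnit", "ContigSet", function(x) x@cbUnit)

#' @describeIn accessors ordered loci (lists of co-retained markers).
#' @export
setGeneric("rhLoci", function(x) standardGeneric("rhLoci"))
setMethod("rhLoci", "RHMap", function(x) x@loci)

#' @describeIn accessors cumulative centiray positions.
#' @export
setGeneric("rhPositions", function(x) standardGeneric("rhPositions"))
setMethod("rhPositions", "RHMap", function(x) x@positions)

#' @describeIn accessors deletion-bin table of an [RHMap-class].
#' @export
setGeneric("rhBins", function(x) standardGeneric("rhBins"))
setMethod("rhBins", "RHMap", function(x) x@bins)

#' @export
setMethod("length", "FingerprintSet", function(x) length(x@tags))

#' @export
setMethod("names", "FingerprintSet", function(x) names(x@tags))

#' @export
setMethod("[", "FingerprintSet", function(x, i, j, ..., drop = TRUE) {
  new("FingerprintSet", tags = x@tags[i])
})

#' @export
setMethod("length", "RHMap", function(x) length(x@loci))

setMethod("show", "ChromosomeModel", function(object) {
  cat(sprintf("ChromosomeModel '%s': %.1f Mb (arm boundary %.1f Mb), %d genes",
              object@name, object@length / 1e6, object@armBoundary / 1e6,
              length(object@genePositions)))
  if (length(object@norInterval))
    cat(sprintf(", NOR %.1f-%.1f Mb", object@norInterval[1] / 1e6,
                object@norInterval[2] / 1e6))
  cat("\n")
})

setMethod("show", "FingerprintSet", function(object) {
  n <- length(object@tags)
  cat(sprintf("FingerprintSet: %d BAC clones, mean %.1f tags/BAC\n", n,
              if (n) mean(vapply(object@tags, length, integer(1))) else 0))
})

setMethod("show", "ContigSet", function(object) {
  inf <- object@info
  ret <- inf[inf$status %in% c("retained", "split-child"), , drop = FALSE]
  cat(sprintf(paste0("ContigSet: %d contigs (%d retained, %d singletons), ",
                     "%.1f Mb cumulative, cbUnit %g bp\n"),
              nrow(inf), nrow(ret), sum(inf$status == "singleton"),
              sum(ret$sizeBp) / 1e6, object@cbUnit))
})

setMethod("show", "RHMap", function(object) {
  k <- length(object@loci)
  cat(sprintf("RHMap: %d loci (%d markers), %.1f cR, r = %.3f, %d obligate breaks\n",
              k, length(unlist(object@loci)),
              if (k) max(object@positions) else 0,
              object@retention, object@obligateBreaks))
  if (nrow(object@bins))
    cat(sprintf("  %d deletion bins\n", nrow(object@bins)))
})
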