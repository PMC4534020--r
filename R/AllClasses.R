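## Central S4 containers.  Coordinates are 0-based half-open internally;
## exporters convert to 1-based closed where a format requires it.

#' ChromosomeModel: a simulated chromosome with arms and gene positions
#'
#' @slot name single chromosome label.
#' @slot length chromosome length in bp.
#' @slot armBoundary centromere midpoint in bp (separates short and long arm).
#' @slot genePositions strictly increasing gene start positions in bp.
#' @slot norInterval length-2 numeric (bp interval of an NOR-like repeat
#'   block) or `numeric(0)` when absent.
#' @slot repeatDensity data.frame with columns `start`, `end`, `fraction`
#'   giving a piecewise repeat-fraction profile.
#' @exportClass ChromosomeModel
setClass("ChromosomeModel",
  representation(name = "character", length = "numeric",
                 armBoundary = "numeric", genePositions = "numeric",
                 norInterval = "numeric", repeatDensity = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@length) != 1L || object@length <= 0)
      msg <- c(msg, "length must be a single positive number")
    if (length(object@armBoundary) != 1L || object@armBoundary <= 0 ||
        object@armBoundary >= object@length)
      msg <- c(msg, "armBoundary must lie strictly inside (0, length)")
    gp <- object@genePositions
    if (length(gp) && (any(gp < 0) || any(gp >= object@length)))
      msg <- c(msg, "gene positions must lie in [0, length)")
    if (length(gp) > 1L && any(diff(gp) <= 0))
      msg <- c(msg, "gene positions must be strictly increasing")
    if (length(object@norInterval) %in% c(0L, 2L) == FALSE)
      msg <- c(msg, "norInterval must be empty or a length-2 interval")
    rf <- object@repeatDensity$fraction
    if (length(rf) && (any(rf < 0) || any(rf > 1)))
      msg <- c(msg, "repeat fractions must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' FingerprintSet: WGP tag fingerprints of a set of BAC clones
#'
#' One fingerprint per clone: the set of integer tag identifiers observed on
#' that BAC.  Tags are abstract site IDs; real WGP sequence tags map onto this
#' representation through any exact-match dictionary.
#'
#' @slot tags named list of sorted integer vectors; names are BAC ids.
#' @exportClass FingerprintSet
setClass("FingerprintSet",
  representation(tags = "list"),
  validity = function(object) {
    nm <- names(object@tags)
    if (is.null(nm) || anyDuplicated(nm))
      return("fingerprints must be uniquely named by BAC id")
    if (!all(vapply(object@tags, is.numeric, logical(1))))
      return("each fingerprint must be a numeric/integer tag vector")
    TRUE
  })

#' ContigSet: assembled BAC contigs with a consensus tag-coordinate map
#'
#' @slot members data.frame with columns `contig`, `bac`, `cbStart`, `cbEnd`
#'   (consensus-band coordinates, 0-based half-open) and `q` (Questionable
#'   clone flag).
#' @slot info data.frame with one row per contig: `contig`, `nMembers`,
#'   `uniqueTags`, `sizeBp` (= uniqueTags x cbUnit) and `status` (one of
#'   `retained`, `singleton`, `eliminated-small`, `eliminated-foreign`,
#'   `split-child`).
#' @slot contigTags named list of integer vectors: unique tags per contig.
#' @slot cbUnit bp represented by one consensus-band (tag interval) unit.
#' @exportClass ContigSet
setClass("ContigSet",
  representation(members = "data.frame", info = "data.frame",
                 contigTags = "list", cbUnit = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("contig", "bac", "cbStart", "cbEnd", "q")
    if (!all(need %in% names(object@members)))
      msg <- c(msg, "members must have contig/bac/cbStart/cbEnd/q columns")
    needi <- c("contig", "nMembers", "uniqueTags", "sizeBp", "status")
    if (!all(needi %in% names(object@info)))
      msg <- c(msg, "info must have contig/nMembers/uniqueTags/sizeBp/status")
    if (anyDuplicated(object@info$contig))
      msg <- c(msg, "duplicated contig ids in info")
    if (length(object@cbUnit) != 1L || object@cbUnit <= 0)
      msg <- c(msg, "cbUnit must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' RHGenotypeMatrix: marker presence/absence calls across RH lines
#'
#' @slot calls integer matrix, lines x markers, values 1 (present), 0
#'   (absent) or NA (missing); dimnames give line and marker ids.
#' @exportClass RHGenotypeMatrix
setClass("RHGenotypeMatrix",
  representation(calls = "matrix"),
  validity = function(object) {
    m <- object@calls
    if (is.null(rownames(m)) || is.null(colnames(m)))
      return("calls must carry line rownames and marker colnames")
    v <- m[!is.na(m)]
    if (length(v) && !all(v %in% c(0L, 1L)))
      return("calls must be 1, 0 or NA")
    TRUE
  })

#' RHMap: an ordered radiation-hybrid map
#'
#' @slot loci named list; each element is the character vector of co-retained
#'   markers collapsed into that locus, in map order.
#' @slot positions cumulative centiray positions (first is 0, non-decreasing).
#' @slot thetas adjacent-interval breakage probabilities (length = loci - 1).
#' @slot retention estimated fragment-retention probability.
#' @slot obligateBreaks total obligate breaks over all lines for this order.
#' @slot bins data.frame of deletion bins (may have zero rows).
#' @exportClass RHMap
setClass("RHMap",
  representation(loci = "list", positions = "numeric", thetas = "numeric",
                 retention = "numeric", obligateBreaks = "integer",
                 bins = "data.frame"),
  validity = function(object) {
    k <- length(object@loci)
    msg <- character()
    if (length(object@positions) != k)
      msg <- c(msg, "one position per locus required")
    if (k && object@positions[1L] != 0)
      msg <- c(msg, "first position must be 0")
    if (k > 1L && any(diff(object@positions) < 0))
      msg <- c(msg, "positions must be non-decreasing")
    if (k > 1L && length(object@thetas) != k - 1L)
      msg <- c(msg, "thetas must have length loci - 1")
    mk <- unlist(object@loci, use.names = FALSE)
    if (anyDuplicated(mk))
      msg <- c(msg, "each marker may appear in exactly one locus")
    if (length(msg)) msg else TRUE
  })

## ---- constructors ----------------------------------------------------------

#' Create a FingerprintSet
#'
#' @param tags named list of integer tag vectors (names are BAC ids).
#'   Duplicate tags within a clone are collapsed with a warning.
#' @return A [FingerprintSet-class] object.
#' @export
FingerprintSet <- function(tags) {
  dup <- vapply(tags, anyDuplicated, integer(1)) > 0L
  if (any(dup)) {
    warning("duplicate tags collapsed for: ",
            paste(head(names(tags)[dup], 5L), collapse = ", "))
  }
  tags <- lapply(tags, function(x) sort(unique(as.integer(x))))
  new("FingerprintSet", tags = tags)
}

#' Create an RHGenotypeMatrix
#'
#' @param calls lines x markers matrix of 1/0/NA calls.
#' @return An [RHGenotypeMatrix-class] object.
#' @export
RHGenotypeMatrix <- function(calls) {
  storage.mode(calls) <- "integer"
  new("RHGenotypeMatrix", calls = calls)
}
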