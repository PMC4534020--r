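## Run configuration, the end-to-end driver and the run manifest.

.configDefaults <- function() {
  list(
    seed = 1L,
    simulate = list(length = 60e6, armBoundary = 27e6, nGenes = 400,
                    densityGradient = 1, coverage = 10,
                    insertMean = 130e3, insertSd = 13e3, purity = 0.92,
                    meanTagsPerBac = 20.6, dropout = 0.02,
                    nLines = 355, meanBreaks = 3.6, retention = 0.7,
                    nMarkers = 120, nonsyntenicFraction = 477 / 2015),
    assemble = list(cbUnit = NULL, fromEnd = 12, initialCutoffExp = -75,
                    finalCutoffExp = -15, stepExp = 5, dqFraction = 0.10,
                    dqStep = 3),
    screen = list(margin = 4, fraction = 0.66, minMembers = 3,
                  containment = 0.8),
    rhmap = list(lodMin = 4.0, dMaxCR = 100, epsilon = 0),
    integrate = list(gapCR = 50),
    compare = list(minBlockSize = 3, outlierPer = 10, translocOffset = 5e6))
}

#' Read a run configuration
#'
#' YAML with one block per pipeline stage; every key has a default and
#' unknown keys are rejected.
#'
#' @param path YAML path, or `NULL` for the defaults.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .configDefaults()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  for (sec in names(user)) {
    if (sec == "seed") { cfg$seed <- as.integer(user$seed); next }
    unknown <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(unknown))
      stop("unknown key(s) in '", sec, "': ",
           paste(unknown, collapse = ", "))
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg
}

#' Run the full pipeline on simulated data
#'
#' Simulates a chromosome, BAC library, fingerprints, RH and deletion
#' panels and ortholog links, then runs assembly, contamination screening,
#' RH mapping, integration and the comparative analysis.  When `outDir` is
#' given, the standard exports (fingerprints TSV, genotype CSV, contig
#' table, AGP, BED, GFF3, link TSV) and a JSON run manifest are written.
#'
#' @param config configuration list from [readRunConfig()].
#' @param outDir optional output directory.
#' @return list with the intermediate objects of every stage.
#' @export
runPipeline <- function(config = readRunConfig(), outDir = NULL) {
  t0 <- Sys.time()
  sd <- config$seed
  sim <- config$simulate
  model <- simulateChromosome(sim$length, sim$armBoundary, sim$nGenes,
                              sim$densityGradient, seed = sd)
  clones <- simulateBacLibrary(model, sim$coverage, sim$insertMean,
                               sim$insertSd, sim$purity, seed = sd)
  wgp <- simulateWgpTags(model, clones, sim$meanTagsPerBac, sim$dropout,
                         seed = sd)
  flt <- filterBacsByTagCount(wgp$fingerprints)
  cbU <- config$assemble$cbUnit
  if (is.null(cbU)) cbU <- sim$insertMean / sim$meanTagsPerBac
  params <- assemblyParams(
    gelLength = max(2L * nrow(wgp$sites),
                    max(unlist(wgp$fingerprints@tags))),
    cbUnit = cbU, fromEnd = config$assemble$fromEnd,
    initialCutoffExp = config$assemble$initialCutoffExp,
    finalCutoffExp = config$assemble$finalCutoffExp,
    stepExp = config$assemble$stepExp,
    dqFraction = config$assemble$dqFraction,
    dqStep = config$assemble$dqStep)
  asm <- stepwiseAssembly(flt$kept, params)
  cut <- selectFinalCutoff(asm$ledger, coverageTarget = model@length)
  contigs <- asm$rounds[[which(asm$ledger$exponent == cut)]]
  flags <- flagForeignBac(flt$kept, wgp$tagOrigin, model@name,
                          config$screen$margin)
  scr1 <- eliminateLowConfidenceContigs(contigs, flags,
                                        config$screen$fraction)
  scr2 <- eliminateRedundantSmallContigs(scr1$contigs,
                                         config$screen$minMembers,
                                         config$screen$containment)
  contigs <- scr2$contigs
  mo <- simulateMarkersAndOrthologs(model, sim$nMarkers,
                                    sim$nonsyntenicFraction, seed = sd)
  panel <- simulateRhPanel(model, sim$nLines, sim$meanBreaks,
                           sim$retention, seed = sd)
  mpos <- setNames(mo$markers$pos, mo$markers$markerID)
  geno <- genotypeMarkers(panel, mpos)
  rh <- buildRHMap(geno, config$rhmap$lodMin, config$rhmap$dMaxCR)
  anchors <- .truthAnchors(mo$markers, clones, contigs)
  split <- detectAndSplitChimeras(contigs, anchors, rh$map,
                                  config$integrate$gapCR)
  contigs <- split$contigs
  placements <- placeContigs(contigs, anchors, rh$map)
  geneAssign <- .truthGeneAssignments(mo$links, model, clones, contigs)
  placements <- orderWithinLocusBySynteny(placements, geneAssign, mo$links)
  arm <- .truthArms(clones, contigs, model)
  summary <- integratedSummary(placements, contigs, arm = arm,
                               chromSizesMb = c(S = model@armBoundary / 1e6,
                                                L = (model@length -
                                                       model@armBoundary) / 1e6,
                                                whole = model@length / 1e6))
  syn <- mo$links[mo$links$syntenic, , drop = FALSE]
  rearr <- detectRearrangements(syn, config$compare$minBlockSize,
                                config$compare$outlierPer,
                                config$compare$translocOffset)
  out <- list(model = model, clones = clones, wgp = wgp,
              fingerprints = flt$kept, assembly = asm, finalCutoff = cut,
              contigs = contigs, screenReport = list(foreign = scr1$report,
                                                     small = scr2$report),
              markers = mo$markers, links = mo$links, genotypes = geno,
              rh = rh, anchors = anchors, placements = placements,
              geneAssignments = geneAssign, summary = summary,
              rearrangements = rearr)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeFingerprints(flt$kept, file.path(outDir, "fingerprints.tsv"))
    writeGenotypes(geno, file.path(outDir, "genotypes.csv"))
    writeContigTable(contigs, file.path(outDir, "contigs.tsv"))
    writeAgp(placements, contigs, file.path(outDir, "map.agp"),
             object = model@name)
    writeBed(placements, contigs, file.path(outDir, "map.bed"),
             object = model@name)
    writeGff3(model, file.path(outDir, "genes.gff3"))
    syntenyLinkTable(mo$links, file.path(outDir, "links.tsv"))
    write.csv(summary, file.path(outDir, "integrated_summary.csv"),
              row.names = FALSE)
    write.csv(asm$ledger, file.path(outDir, "assembly_ledger.csv"),
              row.names = FALSE)
    .writeManifest(file.path(outDir, "manifest.json"), config, outDir, t0)
  }
  invisible(out)
}

## Arm membership per contig from the simulated clone coordinates (an
## arm-specific library knows its arm; majority vote of member midpoints).
.truthArms <- function(clones, contigs, model) {
  mb <- contigs@members
  mid <- (clones$start + clones$end) / 2
  midOf <- setNames(mid, clones$bacID)
  vapply(split(mb$bac, mb$contig), function(bacs) {
    m <- midOf[bacs]
    if (mean(m < model@armBoundary, na.rm = TRUE) >= 0.5) "S" else "L"
  }, character(1))
}

## Ground-truth marker anchors, emulating PCR screening of the library:
## a marker anchors every non-contaminant clone spanning its position that
## sits in a live multi-clone contig.
.truthAnchors <- function(markers, clones, contigs) {
  mb <- contigs@members
  live <- contigs@info$contig[!contigs@info$status %in%
                                c("eliminated-small", "eliminated-foreign",
                                  "singleton")]
  inContig <- clones$bacID %in% mb$bac[mb$contig %in% live] &
    !clones$contaminant
  rows <- lapply(seq_len(nrow(markers)), function(i) {
    hit <- which(inContig & clones$start <= markers$pos[i] &
                   clones$end > markers$pos[i])
    if (!length(hit)) return(NULL)
    data.frame(marker = markers$markerID[i], bac = clones$bacID[hit],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(data.frame(marker = character(),
                                         bac = character(),
                                         stringsAsFactors = FALSE))))
}

## Ground-truth gene-to-contig transfer (the simulator's stand-in for the
## survey-sequence tag mapping): each gene assigned to the contig of a
## clone spanning it.
.truthGeneAssignments <- function(links, model, clones, contigs) {
  mb <- contigs@members
  own <- clones$bacID %in% mb$bac & !clones$contaminant
  rows <- lapply(seq_len(nrow(links)), function(i) {
    hit <- which(own & clones$start <= links$wheatPos[i] &
                   clones$end > links$wheatPos[i])
    if (!length(hit)) return(NULL)
    data.frame(geneID = links$geneID[i],
               contig = mb$contig[match(clones$bacID[hit[1L]], mb$bac)],
               syntenic = links$syntenic[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(data.frame(geneID = character(),
                                         contig = character(),
                                         syntenic = logical(),
                                         stringsAsFactors = FALSE))))
}

.writeManifest <- function(path, config, outDir, t0) {
  files <- setdiff(list.files(outDir), basename(path))
  manifest <- list(
    package = "wgpmap",
    version = as.character(packageVersion("wgpmap")),
    seed = config$seed,
    config = config,
    outputs = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(outDir, f)))),
    wallTimeSec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
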