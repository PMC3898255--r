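# End-to-end discovery pipeline: collapse -> classify -> call peaks ->
# miRNA filter -> top-k -> 50-nt windows -> anchored motif discovery ->
# motif filtering/merging -> MORPH per retained motif.

#' Pipeline configuration
#'
#' @param genome,gff,reads input file paths (FASTA, GFF3, BED6)
#' @param outDir run directory (created)
#' @param mirnaSites optional BED of known miRNA cleavage sites
#' @param params a [peakParams()] list
#' @param regions region classes to process (default all five)
#' @param motif list: `widths`, `minSites`, `eMax`, `dominanceMin`,
#'   `similarityMin`
#' @param morph list: `halfwidth`, `minTotal`, `filterOn`, `render`
#' @param bedScore,dropMulti BED dialect (see [readEndBed()])
#' @param seed seed for any seeded sub-step
#' @return list of class `PipelineConfig`
#' @export
pipelineConfig <- function(genome, gff, reads, outDir,
                           mirnaSites = NULL, params = peakParams(),
                           regions = REGION_LEVELS,
                           motif = list(widths = 6:8, minSites = 5L,
                                        eMax = 1, dominanceMin = 0.5,
                                        similarityMin = 0.75),
                           morph = list(halfwidth = 10L, minTotal = 5,
                                        filterOn = TRUE, render = TRUE),
                           bedScore = "hits", dropMulti = TRUE,
                           seed = 1L) {
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Run the full discovery pipeline
#'
#' Executes every stage in order and writes `peaks.tsv`,
#' `windows_<region>.fa`, `motifs.tsv`, `groups.tsv`, per-motif MORPH
#' matrices/summaries/heat maps, and `run_log.txt` into the run
#' directory.  Every TSV carries the configuration hash and package
#' version; a rerun on the same inputs is bit-identical for TSVs.
#'
#' @param config a [pipelineConfig()]
#' @return invisible list: `peaks` (full report), `models` (retained
#'   [MotifModel-class]s), `groups`, `morphs` (named list of clustered
#'   [MorphMatrix-class]s), `stageCounts`, `paths`
#' @export
runDiscovery <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  for (p in c(config$genome, config$gff, config$reads, config$mirnaSites))
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  stamp <- c(paste0("degmorph ", packageVersion("degmorph")),
             paste0("config ", configHash(config[setdiff(names(config),
                                                         "outDir")])))
  logLines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    logLines <<- c(logLines, line)
    message("[degmorph] ", line)
  }

  note("stage collapse: reading %s", config$reads)
  genome <- readGenome(config$genome)
  ann <- readAnnotation(config$gff)
  ect <- readEndBed(config$reads, bedScore = config$bedScore,
                    dropMulti = config$dropMulti, genome = genome)
  note("collapsed to %d positions / %d reads", length(ect),
       if (length(ect)) sum(endCountsOf(ect)) else 0L)

  note("stage callpeaks")
  peaks <- callPeaks(ect, ann, config$params)
  sc <- attr(peaks, "stageCounts")
  note("candidates %d; dominance-pass %d; P-pass %d; retained %d",
       sc["candidates"], sc["dominance_pass"], sc["p_pass"],
       sc["retained"])

  if (!is.null(config$mirnaSites)) {
    peaks <- filterMirnaSites(peaks, config$mirnaSites,
                              config$params$mirnaTolerance)
    note("miRNA-excluded %d", sum(peaks$excluded_mirna))
  }
  writePeaks(peaks, file.path(config$outDir, "peaks.tsv"), stamp)

  models <- list(); windowsByRegion <- list()
  for (region in config$regions) {
    sub <- peaks[!is.na(peaks$region) & peaks$region == region &
                   !peaks$excluded_mirna, , drop = FALSE]
    top <- selectTop(sub, config$params$topK)
    note("region %s: %d peaks, %d after top-%d cap", region, nrow(sub),
         nrow(top), config$params$topK)
    wins <- extractWindows(top, genome)
    windowsByRegion[[region]] <- wins
    if (length(wins))
      writeXStringSet(wins, file.path(config$outDir,
                                      sprintf("windows_%s.fa", region)))
    if (length(wins) < config$motif$minSites) next
    found <- discoverAnchored(wins, widths = config$motif$widths,
                              minSites = config$motif$minSites,
                              provenance = region)
    kept <- filterMotifs(found, eMax = config$motif$eMax,
                         dominanceMin = config$motif$dominanceMin)
    note("region %s: %d motifs found, %d pass E<%g & dominance>=%g",
         region, length(found), length(kept), config$motif$eMax,
         config$motif$dominanceMin)
    models <- c(models, kept)
  }
  writeMotifs(models, file.path(config$outDir, "motifs.tsv"), stamp)

  groups <- if (length(models))
    mergeMotifs(models, config$motif$similarityMin) else list()
  if (length(models)) {
    gdf <- do.call(rbind, lapply(seq_along(groups), function(gi) {
      g <- groups[[gi]]
      data.frame(group = gi, representative = g@representative,
                 member = vapply(g@members, consensusOf, character(1)),
                 provenance = vapply(g@members, function(m) m@provenance,
                                     character(1)))
    }))
    con <- file(file.path(config$outDir, "groups.tsv"), "w")
    for (h in stamp) writeLines(paste0("# ", h), con)
    write.table(gdf, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }

  morphs <- list()
  for (m in models) {
    region <- m@provenance
    if (!(region %in% REGION_LEVELS)) next
    anchors <- anchorsFromMotif(ann, genome, m@consensus, region)
    mm <- buildMorphMatrix(anchors, ect,
                           halfwidth = config$morph$halfwidth,
                           minTotal = config$morph$minTotal,
                           filterOn = config$morph$filterOn)
    tag <- sprintf("%s_%s", region, m@consensus)
    note("morph %s: %d/%d loci retained", tag, nrow(morphMat(mm)),
         length(anchors))
    if (nrow(morphMat(mm)) >= 1) {
      mm <- wardCluster(mm)
      writeMorphTree(mm, file.path(config$outDir,
                                   sprintf("morph_%s.nwk", tag)))
      if (isTRUE(config$morph$render))
        renderHeatmap(mm, file.path(config$outDir,
                                    sprintf("morph_%s.png", tag)),
                      motifWidth = nchar(m@consensus), main = m@consensus)
    }
    writeMorphMatrix(mm, file.path(config$outDir,
                                   sprintf("morph_%s.tsv", tag)), stamp)
    sm <- summarizeMorph(mm)
    con <- file(file.path(config$outDir,
                          sprintf("morph_%s_summary.tsv", tag)), "w")
    for (h in stamp) writeLines(paste0("# ", h), con)
    write.table(sm, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    morphs[[tag]] <- mm
  }

  writeLines(c(paste0("# ", stamp), logLines),
             file.path(config$outDir, "run_log.txt"))
  invisible(list(peaks = peaks, models = models, groups = groups,
                 morphs = morphs, windows = windowsByRegion,
                 stageCounts = sc,
                 paths = list(outDir = config$outDir)))
}
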