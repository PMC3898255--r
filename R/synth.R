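# Seeded synthetic degradome generator.  Emulates every signal class the
# pipeline detects -- per-transcript background decay, position-fixed
# truncation peaks downstream/upstream of embedded motif instances,
# miRNA-guided cleavage, snoRNA-like 5'-end peaks, and adaptor-mispriming
# artifacts -- and records the ground truth of every planted element.

#' Configuration for the synthetic degradome generator
#'
#' Defaults are the package's reference study conditions: 200
#' protein-coding genes over 2 chromosomes, a PUF-type element
#' (`TGTACATA`, an instance of the TGTAHAKA family) embedded in 60 of the
#' 3' UTRs with a truncation peak 3 nt upstream of the motif (motif-frame
#' offset -3), negative-binomial peak heights (mean 20, dispersion 5),
#' uniform Poisson background decay of 0.02 reads per transcript nt,
#' C/D-box-like ncRNAs carrying an `RTGATGA` box at bases 5-11 with
#' 5'-end peaks, 12 miRNA-guided cleavage targets (cut opposite guide
#' bases 10-11), and 30 adaptor-mispriming loci (`GTCCGAC`) in the CDS.
#'
#' @param seed mandatory RNG seed (the whole bundle is a pure function of
#'   the configuration)
#' @param nChroms,chromLength genome shape
#' @param nGenes protein-coding gene count
#' @param geneStructure element lengths in nt plus `intronProb` (fraction
#'   of genes with one intron splitting the CDS) and intergenic gap range
#' @param ncrna C/D-box and other ncRNA counts, length, box start
#' @param plantings list of motif plantings: `word`, `region`,
#'   `peakOffset` (motif frame, no zero), `nLoci`, `mean`, `dispersion`
#' @param backgroundRate Poisson rate per transcript nt
#' @param mirna guide sequence (21 nt), target count, peak height
#' @param mispriming adaptor 3' word, locus count, read count, `enabled`
#' @param multiHitFraction fraction of background reads marked as 2-hit
#'   multi-mappers in the BED score column
#' @param gcBias force the last two read bases to "GC" in `reads.fa`
#'   (terminal-ligation bias toggle for composition QC)
#' @return a list of class `SynthConfig`
#' @export
synthConfig <- function(seed,
                        nChroms = 2L, chromLength = 180000L,
                        nGenes = 200L,
                        geneStructure = list(utr5 = 60L, cdsExon1 = 300L,
                                             intronLen = 150L,
                                             cdsExon2 = 150L, utr3 = 180L,
                                             intronProb = 0.5,
                                             gapMin = 250L, gapMax = 550L),
                        ncrna = list(nCdBox = 40L, nOther = 15L,
                                     len = 90L, boxStart = 5L),
                        plantings = list(list(word = "TGTACATA",
                                              region = "THREE_UTR",
                                              peakOffset = -3L,
                                              nLoci = 60L, mean = 20,
                                              dispersion = 5)),
                        backgroundRate = 0.02,
                        mirna = list(seq = "TTGACAGAAGAGAGTGAGCAC",
                                     nTargets = 12L, mean = 15,
                                     dispersion = 5),
                        mispriming = list(adaptor = "GTCCGAC",
                                          nLoci = 30L, count = 12L,
                                          enabled = TRUE),
                        multiHitFraction = 0,
                        gcBias = FALSE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  for (p in plantings) stopifnot(p$peakOffset != 0L, p$nLoci >= 0)
  stopifnot(nGenes >= 0, backgroundRate >= 0,
            multiHitFraction >= 0, multiHitFraction <= 1)
  structure(as.list(environment()), class = "SynthConfig")
}

expectedModalOffset <- function(peakOffset) {
  # end-frame offset of motif base 1, given the peak's motif-frame offset
  if (peakOffset < 0) 1L - peakOffset
  else if (peakOffset == 1L) 1L
  else -(peakOffset - 1L)
}

# negative binomial peak height (size = dispersion, mu = mean)
nbDraw <- function(n, mean, dispersion) {
  rnbinom(n, size = dispersion, mu = mean)
}

#' Simulate a degradome bundle with ground truth
#'
#' Deterministic for a given configuration: writes `genome.fa`,
#' `annotation.gff3`, `ends.bed` (one BED6 line per read, score = genome
#' hit count), `reads.fa` (the 20 nt starting at each 5' end, strand
#' oriented), `mirna_sites.bed` (known cleavage sites for the exclusion
#' filter), and `truth.tsv`.
#'
#' @param config a [synthConfig()]
#' @param outDir output directory (created; default a fresh tempdir)
#' @return invisible list with the in-memory objects (`genome`,
#'   `annotation`, `ends` ([EndCounts-class]), `reads`, `truth`) and the
#'   file `paths`
#' @export
simulateDegradome <- function(config, outDir = tempfile("synth")) {
  stopifnot(inherits(config, "SynthConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  res <- withr::with_seed(as.integer(config$seed), simulateImpl(config))
  paths <- writeBundle(res, config, outDir)
  invisible(c(res, list(paths = paths)))
}

simulateImpl <- function(config) {
  gs <- config$geneStructure
  chromNames <- sprintf("chr%d", seq_len(config$nChroms))
  genomeChars <- lapply(seq_len(config$nChroms), function(i)
    sample(c("A", "C", "G", "T"), config$chromLength, replace = TRUE))
  names(genomeChars) <- chromNames

  # ---- gene and ncRNA placement -------------------------------------------
  genes <- list(); ncs <- list()
  ncQuota <- c(CD_box = config$ncrna$nCdBox, other = config$ncrna$nOther)
  ncClassSeq <- rep(c("CD_box", "other"),
                    times = c(ncQuota[1], ncQuota[2]))
  if (length(ncClassSeq)) ncClassSeq <- sample(ncClassSeq)
  ncNext <- 1L
  geneIdx <- 0L
  for (ci in seq_len(config$nChroms)) {
    cursor <- 1000L
    while (geneIdx < config$nGenes) {
      hasIntron <- stats::runif(1) < gs$intronProb
      cdsLens <- if (hasIntron) c(gs$cdsExon1, gs$cdsExon2)
                 else gs$cdsExon1 + gs$cdsExon2
      footprint <- gs$utr5 + sum(cdsLens) + gs$utr3 +
        if (hasIntron) gs$intronLen else 0L
      gap <- as.integer(round(stats::runif(1, gs$gapMin, gs$gapMax)))
      if (cursor + footprint + gap + 1000L > config$chromLength) break
      geneIdx <- geneIdx + 1L
      st <- sample(c("+", "-"), 1)
      g <- makeGene(sprintf("g%03d", geneIdx), chromNames[ci], cursor, st,
                    gs, hasIntron)
      genes[[geneIdx]] <- g
      cursor <- cursor + footprint

      # drop an ncRNA into the following intergenic gap when room allows
      if (ncNext <= length(ncClassSeq) &&
          gap >= config$ncrna$len + 80L) {
        s <- cursor + 40L
        e <- s + config$ncrna$len - 1L
        ncSt <- sample(c("+", "-"), 1)
        cls <- ncClassSeq[ncNext]
        ncs[[ncNext]] <- list(id = sprintf("nc%03d", ncNext),
                              chrom = chromNames[ci], start = s, end = e,
                              strand = ncSt, class = cls)
        ncNext <- ncNext + 1L
      }
      cursor <- cursor + gap
    }
  }
  if (geneIdx < config$nGenes)
    stop("genome too small for the requested gene count", call. = FALSE)

  embed <- function(chrom, left, word) {
    genomeChars[[chrom]][left:(left + nchar(word) - 1L)] <<-
      strsplit(word, "")[[1]]
  }

  # C/D boxes of snoRNA-like features
  for (nc in ncs) {
    if (nc$class != "CD_box") next
    boxWord <- paste0(sample(c("A", "G"), 1), "TGATGA")
    b0 <- config$ncrna$boxStart
    if (nc$strand == "+") embed(nc$chrom, nc$start + b0 - 1L, boxWord)
    else embed(nc$chrom, nc$end - b0 - nchar(boxWord) + 2L,
               revcompChar(boxWord))
  }

  truth <- list()
  addTruth <- function(class, chrom, strand, anchor, endPos, count,
                       word = "") {
    truth[[length(truth) + 1L]] <<- data.frame(
      id = sprintf("%s%03d", substr(class, 1, 2), length(truth) + 1L),
      class = class, chrom = chrom, strand = strand,
      anchor_pos = as.integer(anchor), end_pos = as.integer(endPos),
      count = as.integer(count), word = word)
  }

  usedGenes <- logical(length(genes))
  pickGenes <- function(n, need) {
    ok <- which(!usedGenes & vapply(genes, need, logical(1)))
    if (length(ok) < n)
      stop("plantings exceed available loci of the requested region class",
           call. = FALSE)
    sel <- if (length(ok) == n) ok else sample(ok, n)
    usedGenes[sel] <<- TRUE
    sel
  }

  regionIv <- function(g, region) {
    switch(region,
           THREE_UTR = g$utr3, FIVE_UTR = g$utr5, CDS = g$cds1,
           INTRON = g$intron,
           stop("unsupported planting region: ", region, call. = FALSE))
  }

  # ---- motif plantings -----------------------------------------------------
  for (p in config$plantings) {
    if (p$nLoci == 0) next
    w <- nchar(p$word)
    margin <- 13L
    sel <- pickGenes(p$nLoci, function(g) {
      iv <- regionIv(g, p$region)
      !is.null(iv) && (iv[2] - iv[1] + 1L) >= w + 2L * margin
    })
    heights <- nbDraw(length(sel), p$mean, p$dispersion)
    for (i in seq_along(sel)) {
      g <- genes[[sel[i]]]
      iv <- regionIv(g, p$region)
      left <- as.integer(round(stats::runif(
        1, iv[1] + margin, iv[2] - margin - w + 1L)))
      if (g$strand == "+") {
        embed(g$chrom, left, p$word); anchor <- left
      } else {
        embed(g$chrom, left, revcompChar(p$word)); anchor <- left + w - 1L
      }
      endPos <- frameToGenomic(anchor, g$strand, p$peakOffset)
      addTruth("motif_peak", g$chrom, g$strand, anchor, endPos,
               heights[i], p$word)
    }
  }

  # ---- miRNA-guided cleavage ----------------------------------------------
  if (config$mirna$nTargets > 0) {
    m <- config$mirna$seq
    site <- revcompChar(m)
    sel <- pickGenes(config$mirna$nTargets, function(g)
      (g$cds1[2] - g$cds1[1] + 1L) >= nchar(site) + 26L)
    heights <- nbDraw(length(sel), config$mirna$mean,
                      config$mirna$dispersion)
    for (i in seq_along(sel)) {
      g <- genes[[sel[i]]]
      left <- g$cds1[1] + 13L
      if (g$strand == "+") {
        embed(g$chrom, left, site)
        endPos <- left + 11L          # target base 12, opposite guide 10/11
      } else {
        embed(g$chrom, left, revcompChar(site))
        endPos <- left + nchar(site) - 12L
      }
      addTruth("mirna_cleavage", g$chrom, g$strand, left, endPos,
               heights[i], m)
    }
  }

  # ---- adaptor mispriming --------------------------------------------------
  if (isTRUE(config$mispriming$enabled) && config$mispriming$nLoci > 0) {
    ad <- config$mispriming$adaptor
    w <- nchar(ad)
    sel <- pickGenes(config$mispriming$nLoci, function(g)
      (g$cds1[2] - g$cds1[1] + 1L) >= w + 40L)
    for (i in seq_along(sel)) {
      g <- genes[[sel[i]]]
      left <- g$cds1[1] + 20L
      if (g$strand == "+") {
        embed(g$chrom, left, ad)
        anchor <- left; endPos <- anchor + w
      } else {
        embed(g$chrom, left, revcompChar(ad))
        anchor <- left + w - 1L; endPos <- anchor - w
      }
      addTruth("artifact", g$chrom, g$strand, anchor, endPos,
               config$mispriming$count, ad)
    }
  }

  # ---- snoRNA-like 5'-end peaks -------------------------------------------
  for (nc in ncs) {
    if (nc$class != "CD_box") next
    endPos <- if (nc$strand == "+") nc$start else nc$end
    addTruth("sno_5p", nc$chrom, nc$strand, endPos, endPos,
             nbDraw(1, 20, 5))
  }

  # ---- background decay ----------------------------------------------------
  bg <- list()
  for (g in genes) {
    pos <- unlist(lapply(g$exons, function(iv) iv[1]:iv[2]),
                  use.names = FALSE)
    cnt <- rpois(length(pos), config$backgroundRate)
    hit <- cnt > 0
    if (any(hit))
      bg[[length(bg) + 1L]] <- data.frame(chrom = g$chrom,
                                          strand = g$strand,
                                          pos = pos[hit],
                                          count = cnt[hit])
  }
  bg <- if (length(bg)) do.call(rbind, bg)
        else data.frame(chrom = character(), strand = character(),
                        pos = integer(), count = integer())
  truthDf <- if (length(truth)) do.call(rbind, truth)
             else data.frame(id = character(), class = character(),
                             chrom = character(), strand = character(),
                             anchor_pos = integer(), end_pos = integer(),
                             count = integer(), word = character())
  truthDf <- rbind(truthDf, data.frame(
    id = "background", class = "background", chrom = "*", strand = "*",
    anchor_pos = NA_integer_, end_pos = NA_integer_,
    count = sum(bg$count), word = ""))

  # ---- assemble per-read table --------------------------------------------
  planted <- truthDf[truthDf$class != "background" & truthDf$count > 0, ]
  allEnds <- rbind(
    if (nrow(planted)) data.frame(chrom = planted$chrom,
                                  strand = planted$strand,
                                  pos = planted$end_pos,
                                  count = planted$count,
                                  source = "planted") else NULL,
    if (nrow(bg)) cbind(bg, source = "background") else NULL)
  if (is.null(allEnds))
    allEnds <- data.frame(chrom = character(), strand = character(),
                          pos = integer(), count = integer(),
                          source = character())
  genome <- DNAStringSet(vapply(genomeChars, paste, character(1),
                                collapse = ""))
  names(genome) <- chromNames

  reads <- expandReads(allEnds, genome, config)
  ends <- if (nrow(allEnds))
    endCounts(allEnds$chrom, allEnds$strand, allEnds$pos, allEnds$count,
              seqlengths = genomeSeqlengths(genome))
  else new("EndCounts", gr = GRanges(count = integer()))

  list(genome = genome, genes = genes, ncs = ncs, truth = truthDf,
       ends = ends, reads = reads)
}

# one gene's genomic structure; all intervals are 1-based [start, end]
makeGene <- function(id, chrom, start, strand, gs, hasIntron) {
  segLens <- if (strand == "+") {
    if (hasIntron) c(utr5 = gs$utr5, cds1 = gs$cdsExon1,
                     intron = gs$intronLen, cds2 = gs$cdsExon2,
                     utr3 = gs$utr3)
    else c(utr5 = gs$utr5, cds1 = gs$cdsExon1 + gs$cdsExon2,
           utr3 = gs$utr3)
  } else {
    if (hasIntron) c(utr3 = gs$utr3, cds2 = gs$cdsExon2,
                     intron = gs$intronLen, cds1 = gs$cdsExon1,
                     utr5 = gs$utr5)
    else c(utr3 = gs$utr3, cds1 = gs$cdsExon1 + gs$cdsExon2,
           utr5 = gs$utr5)
  }
  ends <- start + cumsum(segLens) - 1L
  starts <- c(start, head(ends, -1) + 1L)
  iv <- Map(function(s, e) c(s, e), starts, ends)
  names(iv) <- names(segLens)
  span <- c(start, ends[length(ends)])
  exons <- if (hasIntron) {
    if (strand == "+") list(c(iv$utr5[1], iv$cds1[2]),
                            c(iv$cds2[1], iv$utr3[2]))
    else list(c(iv$utr3[1], iv$cds2[2]), c(iv$cds1[1], iv$utr5[2]))
  } else list(span)
  list(id = id, chrom = chrom, strand = strand, span = span,
       utr5 = iv$utr5, utr3 = iv$utr3, cds1 = iv$cds1,
       cds2 = if (hasIntron) iv$cds2 else NULL,
       intron = if (hasIntron) iv$intron else NULL,
       exons = exons)
}

expandReads <- function(allEnds, genome, config) {
  if (!nrow(allEnds))
    return(data.frame(id = character(), chrom = character(),
                      strand = character(), pos = integer(),
                      hits = integer(), seq = character()))
  o <- order(allEnds$chrom, allEnds$pos, allEnds$strand)
  allEnds <- allEnds[o, ]
  idx <- rep(seq_len(nrow(allEnds)), allEnds$count)
  df <- data.frame(chrom = allEnds$chrom[idx],
                   strand = allEnds$strand[idx],
                   pos = allEnds$pos[idx],
                   source = allEnds$source[idx])
  df$id <- sprintf("r%06d", seq_len(nrow(df)))
  df$hits <- 1L
  if (config$multiHitFraction > 0) {
    bgIdx <- which(df$source == "background")
    nMulti <- as.integer(round(length(bgIdx) * config$multiHitFraction))
    if (nMulti > 0) df$hits[sample(bgIdx, nMulti)] <- 2L
  }
  sl <- genomeSeqlengths(genome)
  df$seq <- vapply(seq_len(nrow(df)), function(i) {
    p <- df$pos[i]; chrom <- df$chrom[i]
    if (df$strand[i] == "+") {
      to <- min(p + 19L, sl[[chrom]])
      as.character(subseq(genome[[chrom]], p, to))
    } else {
      from <- max(1L, p - 19L)
      revcompChar(as.character(subseq(genome[[chrom]], from, p)))
    }
  }, character(1))
  if (isTRUE(config$gcBias))
    df$seq <- paste0(substr(df$seq, 1, nchar(df$seq) - 2L), "GC")
  df
}

writeBundle <- function(res, config, outDir) {
  paths <- list(genome = file.path(outDir, "genome.fa"),
                gff = file.path(outDir, "annotation.gff3"),
                bed = file.path(outDir, "ends.bed"),
                reads = file.path(outDir, "reads.fa"),
                mirna = file.path(outDir, "mirna_sites.bed"),
                truth = file.path(outDir, "truth.tsv"))
  writeXStringSet(res$genome, paths$genome, width = 70L)

  lines <- c("##gff-version 3")
  for (g in res$genes) {
    a <- function(s, e, type, attrs, phase = ".")
      sprintf("%s\tdegmorph\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$chrom, type, s, e, g$strand, phase, attrs)
    tx <- paste0(g$id, ".t1")
    lines <- c(lines,
               a(g$span[1], g$span[2], "gene", paste0("ID=", g$id)),
               a(g$span[1], g$span[2], "mRNA",
                 paste0("ID=", tx, ";Parent=", g$id)))
    for (ex in g$exons)
      lines <- c(lines, a(ex[1], ex[2], "exon", paste0("Parent=", tx)))
    cdsPieces <- if (is.null(g$cds2)) list(g$cds1)
                 else if (g$strand == "+") list(g$cds1, g$cds2)
                 else list(g$cds2, g$cds1)   # genomic order
    # phase follows translation order (strand-aware)
    transOrder <- if (is.null(g$cds2)) list(g$cds1)
                  else list(g$cds1, g$cds2)
    phases <- c(0L, (3L - (vapply(transOrder, function(iv)
      iv[2] - iv[1] + 1L, integer(1)) %% 3L)) %% 3L)[seq_along(transOrder)]
    names(phases) <- vapply(transOrder, function(iv)
      paste(iv, collapse = "-"), character(1))
    for (iv in cdsPieces)
      lines <- c(lines, a(iv[1], iv[2], "CDS", paste0("Parent=", tx),
                          phases[[paste(iv, collapse = "-")]]))
  }
  for (nc in res$ncs)
    lines <- c(lines, sprintf(
      "%s\tdegmorph\tncRNA\t%d\t%d\t.\t%s\t.\tID=%s;ncrna_class=%s",
      nc$chrom, nc$start, nc$end, nc$strand, nc$id, nc$class))
  writeLines(lines, paths$gff)

  rd <- res$reads
  bed <- if (nrow(rd)) sprintf("%s\t%d\t%d\t%s\t%d\t%s", rd$chrom,
                               ifelse(rd$strand == "+", rd$pos - 1L,
                                      pmax(0L, rd$pos - 20L)),
                               ifelse(rd$strand == "+", rd$pos + 19L,
                                      rd$pos),
                               rd$id, rd$hits, rd$strand)
         else character()
  writeLines(bed, paths$bed)
  writeLines(if (nrow(rd)) paste0(">", rd$id, "\n", rd$seq)
             else character(), paths$reads)

  mir <- res$truth[res$truth$class == "mirna_cleavage", , drop = FALSE]
  writeLines(if (nrow(mir)) sprintf("%s\t%d\t%d\t%s\t0\t%s", mir$chrom,
                                    mir$end_pos - 1L, mir$end_pos,
                                    mir$id, mir$strand)
             else character(), paths$mirna)
  write.table(res$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

#' Compare pipeline output against simulation ground truth
#'
#' A called peak matches a truth record iff it sits at the same
#' (chrom, strand, position).  A planted motif is recovered iff some
#' reported model's consensus expansion contains the planted word and its
#' modal offset equals the offset implied by the planted peak geometry.
#'
#' @param peaks [callPeaks()] output
#' @param truth the `truth` data.frame from [simulateDegradome()]
#' @param motifs optional list of [MotifModel-class]
#' @param plantedWord,plantedPeakOffset optional planted word and its
#'   motif-frame peak offset for motif-recovery checking
#' @return list with overall and per-class `sensitivity`, `precision`,
#'   counts, and (when requested) `motifRecovered` plus
#'   `expectedModalOffset`
#' @export
truthCompare <- function(peaks, truth, motifs = NULL, plantedWord = NULL,
                         plantedPeakOffset = NULL) {
  tr <- truth[truth$class != "background" & truth$count > 0, , drop = FALSE]
  tKey <- paste(tr$chrom, tr$strand, tr$end_pos)
  cKey <- paste(peaks$chrom, peaks$strand, peaks$pos)
  found <- tKey %in% cKey
  out <- list(
    sensitivity = if (nrow(tr)) mean(found) else NA_real_,
    sensitivityByClass = if (nrow(tr))
      vapply(split(found, tr$class), mean, numeric(1)) else numeric(),
    precision = if (nrow(peaks)) mean(cKey %in% tKey) else NA_real_,
    nTruth = nrow(tr), nCalled = nrow(peaks))
  if (!is.null(motifs) && !is.null(plantedWord)) {
    expOff <- expectedModalOffset(as.integer(plantedPeakOffset))
    hit <- vapply(motifs, function(m)
      nchar(m@consensus) == nchar(plantedWord) &&
        iupacMatch(m@consensus, plantedWord) &&
        m@modalOffset == expOff, logical(1))
    out$motifRecovered <- any(hit)
    out$expectedModalOffset <- expOff
  }
  out
}
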