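# Input parsing, coordinate conventions, end-count collapsing, and the
# five-way region classification.

#' Read a genome FASTA
#'
#' Sequences are uppercased and U is converted to T.  Only A/C/G/T/N are
#' accepted after normalization; sequence names must be unique (the name is
#' the first whitespace-delimited word of the header).
#'
#' @param path FASTA file
#' @return a [Biostrings::DNAStringSet] with `seqlengths`-compatible names
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBStringSet(path)
  if (length(raw) == 0) stop("empty FASTA: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm))
    stop("duplicate sequence name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  s <- toupper(as.character(raw))
  s <- chartr("U", "T", s)
  ok <- grepl("^[ACGTN]*$", s)
  if (!all(ok))
    stop("non-IUPAC characters in record(s): ",
         paste(nm[!ok], collapse = ", "), call. = FALSE)
  out <- DNAStringSet(s)
  names(out) <- nm
  out
}

genomeSeqlengths <- function(genome) {
  structure(Biostrings::width(genome), names = names(genome))
}

#' Read a GFF3 annotation
#'
#' Parses gene/mRNA/exon features plus optional CDS, `five_prime_UTR`,
#' `three_prime_UTR` and ncRNA-class features.  Transcripts with a CDS but
#' without explicit UTR features get UTRs derived as exon set-minus CDS,
#' split by the strand-aware side of the CDS.  Features whose type is not
#' part of the protein-coding hierarchy are kept as ncRNAs; their class is
#' taken from an `ncrna_class` attribute when present, else the type.
#'
#' @param path GFF3 file
#' @return a [DegAnnotation-class]
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gff <- rtracklayer::import(path)
  type <- as.character(gff$type)
  firstParent <- function(x) {
    p <- gff$Parent[x]
    vapply(p, function(z) if (length(z)) z[[1]] else NA_character_,
           character(1))
  }

  gi <- type == "gene"
  genes <- gff[gi]
  mcols(genes) <- DataFrame(gene_id = gff$ID[gi])

  ti <- type %in% c("mRNA", "transcript")
  txs <- gff[ti]
  txParent <- firstParent(ti)
  if (any(is.na(txParent)) || !all(txParent %in% genes$gene_id))
    stop("transcript references a missing parent gene", call. = FALSE)
  mcols(txs) <- DataFrame(tx_id = gff$ID[ti], gene_id = txParent)

  pullChildren <- function(sel) {
    par <- firstParent(sel)
    if (any(is.na(par)) || !all(par %in% txs$tx_id))
      stop("feature references a missing parent transcript", call. = FALSE)
    g <- gff[sel]
    mcols(g) <- NULL
    gl <- GenomicRanges::split(g, factor(par, levels = txs$tx_id))
    endoapply_sort(gl)
  }
  endoapply_sort <- function(gl) S4Vectors::endoapply(gl, GenomicRanges::sort)

  exons <- pullChildren(type == "exon")
  cds <- pullChildren(type == "CDS")
  utr5 <- pullChildren(type == "five_prime_UTR")
  utr3 <- pullChildren(type == "three_prime_UTR")

  # exons must lie within the parent gene span
  gspan <- genes[match(txs$gene_id, genes$gene_id)]
  for (i in seq_along(txs)) {
    ex <- exons[[txs$tx_id[i]]]
    if (length(ex) &&
        (min(start(ex)) < start(gspan)[i] || max(end(ex)) > end(gspan)[i]))
      stop("exon outside gene span for transcript ", txs$tx_id[i],
           call. = FALSE)
  }

  # derive UTRs from exon \ CDS where a CDS exists but no explicit UTRs
  for (i in seq_along(txs)) {
    id <- txs$tx_id[i]
    cdsI <- cds[[id]]
    if (!length(cdsI)) next
    if (length(utr5[[id]]) || length(utr3[[id]])) next
    rest <- GenomicRanges::setdiff(exons[[id]], cdsI)
    if (!length(rest)) next
    left <- rest[end(rest) < min(start(cdsI))]
    right <- rest[start(rest) > max(end(cdsI))]
    if (as.character(strand(txs)[i]) == "+") {
      utr5[[id]] <- left; utr3[[id]] <- right
    } else {
      utr5[[id]] <- right; utr3[[id]] <- left
    }
  }

  ncSel <- !(type %in% c("gene", "mRNA", "transcript", "exon", "CDS",
                         "five_prime_UTR", "three_prime_UTR",
                         "chromosome", "region"))
  ncrna <- gff[ncSel]
  ncClass <- if (!is.null(gff$ncrna_class)) gff$ncrna_class[ncSel]
             else rep(NA_character_, sum(ncSel))
  ncClass[is.na(ncClass)] <- type[ncSel][is.na(ncClass)]
  ncId <- if (!is.null(gff$ID)) gff$ID[ncSel] else NULL
  if (is.null(ncId)) ncId <- paste0("nc", seq_len(sum(ncSel)))
  ncId[is.na(ncId)] <- paste0("nc", which(is.na(ncId)))
  mcols(ncrna) <- DataFrame(nc_id = ncId, nc_class = ncClass)

  new("DegAnnotation", genes = genes, transcripts = txs, exons = exons,
      cds = cds, utr5 = utr5, utr3 = utr3, ncrna = ncrna)
}

#' Read mapped degradome 5'-end reads from BED6
#'
#' Each record is reduced to its biological 5'-terminus position
#' (`chromStart` on `+`, `chromEnd - 1` on `-`, BED half-open) and records
#' are collapsed into per-position counts.  The role of the BED score
#' column is selected by `bedScore`: `"ignore"` (every line is one read),
#' `"count"` (pre-collapsed read count), or `"hits"` (genome hit count of
#' the read; reads with more than one hit are dropped when
#' `dropMulti = TRUE`).
#'
#' @param path BED6 file
#' @param bedScore score-column dialect, see Details
#' @param dropMulti drop multi-hit reads (only meaningful with
#'   `bedScore = "hits"`)
#' @param genome optional [Biostrings::DNAStringSet] for bounds checking
#' @return an [EndCounts-class]
#' @export
readEndBed <- function(path, bedScore = c("ignore", "count", "hits"),
                       dropMulti = FALSE, genome = NULL) {
  bedScore <- match.arg(bedScore)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  sl <- if (is.null(genome)) NULL else genomeSeqlengths(genome)
  if (length(gr) == 0) {
    out <- new("EndCounts", gr = GRanges(count = integer()))
    return(out)
  }
  st <- as.character(strand(gr))
  if (any(st == "*")) stop("strand missing in BED record(s)", call. = FALSE)
  score <- gr$score
  if (bedScore != "ignore" && (is.null(score) || anyNA(score)))
    stop("score column required for bedScore='", bedScore, "'",
         call. = FALSE)
  keep <- rep(TRUE, length(gr))
  if (bedScore == "hits" && dropMulti) keep <- score <= 1
  cnt <- if (bedScore == "count") as.numeric(score) else 1
  pos <- ifelse(st == "+", start(gr), end(gr))
  if (!is.null(sl)) {
    lim <- sl[as.character(seqnames(gr))]
    if (anyNA(lim))
      stop("BED chromosome absent from genome", call. = FALSE)
    if (any(start(gr) < 1 | end(gr) > lim))
      stop("read coordinates outside chromosome bounds", call. = FALSE)
  }
  if (!any(keep)) return(new("EndCounts", gr = GRanges(count = integer())))
  endCounts(as.character(seqnames(gr))[keep], st[keep], pos[keep],
            rep(cnt, length.out = length(gr))[keep], seqlengths = sl)
}

#' Write an EndCounts object as BED6
#'
#' One width-1 record per position with the count in the score column;
#' re-reading with `readEndBed(bedScore = "count")` round-trips exactly.
#'
#' @param x an [EndCounts-class]
#' @param path output file
#' @export
writeEndBed <- function(x, path) {
  gr <- endPositions(x)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = start(gr),
                   name = paste0("e", seq_along(gr)),
                   score = mcols(gr)$count,
                   strand = as.character(strand(gr)))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# strand-aware reduced interval sets per region class, with the priority
# CDS > 3'UTR > 5'UTR > intron applied at query time
regionIndex <- function(ann) {
  ul <- function(gl) unlist(gl, use.names = FALSE)
  cdsAll <- ul(ann@cds)
  # exons of CDS-less transcripts count as CDS unless covered by explicit UTRs
  noCds <- vapply(seq_along(ann@transcripts), function(i) {
    length(ann@cds[[ann@transcripts$tx_id[i]]]) == 0
  }, logical(1))
  if (any(noCds)) {
    for (id in ann@transcripts$tx_id[noCds]) {
      ex <- ann@exons[[id]]
      if (!length(ex)) next
      expl <- c(ann@utr5[[id]], ann@utr3[[id]])
      if (length(expl)) ex <- GenomicRanges::setdiff(ex, expl)
      if (length(ex)) cdsAll <- c(cdsAll, ex)
    }
  }
  list(cds = reduce(cdsAll), utr3 = reduce(ul(ann@utr3)),
       utr5 = reduce(ul(ann@utr5)), gene = reduce(ann@genes))
}

#' Classify strand-aware genomic positions into the five region classes
#'
#' Each (chrom, strand, pos) is assigned exactly one of `FIVE_UTR`, `CDS`,
#' `THREE_UTR`, `INTRON`, `IGR` against transcripts on the same strand,
#' with the deterministic priority CDS > 3'UTR > 5'UTR > intron; IGR only
#' if no same-strand gene overlaps (an antisense gene does not change the
#' label).
#'
#' @param ann a [DegAnnotation-class]
#' @param chrom,strand,pos parallel vectors (`pos` 1-based)
#' @return character vector of labels from [REGION_LEVELS]
#' @export
classifyPositions <- function(ann, chrom, strand, pos) {
  checkStrand(strand)
  q <- GRanges(chrom, IRanges(as.integer(pos), width = 1L), strand = strand)
  idx <- regionIndex(ann)
  hit <- function(subject) IRanges::overlapsAny(q, subject)
  lab <- rep("IGR", length(q))
  lab[hit(idx$gene)] <- "INTRON"
  lab[hit(idx$utr5)] <- "FIVE_UTR"
  lab[hit(idx$utr3)] <- "THREE_UTR"
  lab[hit(idx$cds)] <- "CDS"
  lab
}

# per-transcript intervals for one region class, named by transcript
regionIntervalsByTx <- function(ann, region) {
  region <- match.arg(region, REGION_LEVELS)
  switch(region,
    FIVE_UTR = ann@utr5,
    THREE_UTR = ann@utr3,
    CDS = ann@cds,
    INTRON = {
      gl <- lapply(ann@transcripts$tx_id, function(id) {
        ex <- ann@exons[[id]]
        if (length(ex) < 2) return(GRanges())
        GenomicRanges::setdiff(range(ex), ex)
      })
      names(gl) <- ann@transcripts$tx_id
      GRangesList(gl)
    },
    IGR = stop("IGR has no per-transcript intervals", call. = FALSE))
}
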