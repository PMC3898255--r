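# S4 classes for the central data objects.

#' Strand-aware per-position counts of uncapped 5' termini
#'
#' Wraps a width-1 [GenomicRanges::GRanges] whose `count` metadata column
#' holds the number of degradome reads whose biological 5' end maps to that
#' genomic base on that strand (leftmost base on `+`, rightmost on `-`).
#' One record per (chromosome, strand, position); counts are >= 1.
#'
#' @slot gr width-1 `GRanges` with integer metadata column `count`
#' @seealso [endCounts()], [readEndBed()], [writeEndBed()]
#' @export
setClass("EndCounts", representation(gr = "GRanges"))

setValidity("EndCounts", function(object) {
  gr <- object@gr
  msgs <- character()
  if (length(gr)) {
    if (!all(width(gr) == 1L)) msgs <- c(msgs, "all ranges must have width 1")
    cnt <- mcols(gr)$count
    if (is.null(cnt) || !is.numeric(cnt))
      msgs <- c(msgs, "metadata column 'count' required")
    else if (any(cnt < 1)) msgs <- c(msgs, "counts must be >= 1")
    if (!all(as.character(strand(gr)) %in% c("+", "-")))
      msgs <- c(msgs, "strand must be '+' or '-'")
    key <- paste(seqnames(gr), strand(gr), start(gr))
    if (anyDuplicated(key))
      msgs <- c(msgs, "one record per (chrom, strand, pos) required")
    sl <- seqlengths(gr)
    if (!all(is.na(sl))) {
      lim <- sl[as.character(seqnames(gr))]
      bad <- !is.na(lim) & (start(gr) < 1L | start(gr) > lim)
      if (any(bad)) msgs <- c(msgs, "positions outside chromosome bounds")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an EndCounts object
#'
#' @param chrom,strand,pos,count parallel vectors; `pos` is the 1-based
#'   genomic coordinate of the 5' terminus
#' @param seqlengths optional named chromosome length vector used for
#'   bounds checking
#' @return an [EndCounts-class] object (records aggregated per position)
#' @examples
#' endCounts("c1", "+", c(100, 100, 120), c(1, 2, 5))
#' @export
endCounts <- function(chrom, strand, pos, count = 1L, seqlengths = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   strand = checkStrand(as.character(strand)),
                   pos = as.integer(pos),
                   count = as.numeric(count))
  agg <- stats::aggregate(count ~ chrom + strand + pos, df, sum)
  agg <- agg[order(agg$chrom, agg$strand, agg$pos), , drop = FALSE]
  gr <- GRanges(agg$chrom, IRanges(agg$pos, width = 1L), strand = agg$strand,
                count = as.integer(round(agg$count)))
  if (!is.null(seqlengths))
    seqlengths(gr) <- seqlengths[seqlevels(gr)]
  new("EndCounts", gr = GenomicRanges::sort(gr, ignore.strand = TRUE))
}

#' @describeIn EndCounts-class the underlying width-1 `GRanges`
#' @param x an `EndCounts` object
#' @export
endPositions <- function(x) x@gr

#' @describeIn EndCounts-class per-record read counts
#' @export
endCountsOf <- function(x) mcols(x@gr)$count

setMethod("show", "EndCounts", function(object) {
  cat(sprintf("EndCounts: %d positions, %d reads on %d sequence(s)\n",
              length(object@gr), sum(mcols(object@gr)$count),
              length(unique(as.character(seqnames(object@gr))))))
})

setMethod("length", "EndCounts", function(x) length(x@gr))

#' Genome annotation for degradome analysis
#'
#' Holds genes, transcripts, per-transcript exon/CDS/UTR structure and
#' ncRNA features parsed from GFF3.  UTRs absent from the file are derived
#' as exon minus CDS when a CDS is annotated.
#'
#' @slot genes `GRanges` with `gene_id`
#' @slot transcripts `GRanges` with `tx_id`, `gene_id`
#' @slot exons,cds,utr5,utr3 `GRangesList` named by transcript id
#' @slot ncrna `GRanges` with `nc_id`, `nc_class` (e.g. `CD_box`,
#'   `HACA_box`, `other`)
#' @seealso [readAnnotation()], [classifyPositions()]
#' @export
setClass("DegAnnotation",
         representation(genes = "GRanges", transcripts = "GRanges",
                        exons = "GRangesList", cds = "GRangesList",
                        utr5 = "GRangesList", utr3 = "GRangesList",
                        ncrna = "GRanges"))

setMethod("show", "DegAnnotation", function(object) {
  cat(sprintf(paste0("DegAnnotation: %d genes, %d transcripts, ",
                     "%d ncRNA features\n"),
              length(object@genes), length(object@transcripts),
              length(object@ncrna)))
})

#' A position-anchored motif model
#'
#' An IUPAC consensus together with its ZOOPS site list over a set of
#' 50-nt peak windows, the number of sequences with a site (`k`) out of
#' `N` inputs, an internal E-value-like score, and the positional anchor:
#' `modalOffset` is the most frequent frame offset of the motif's first
#' base relative to the uncapped end (end = +1, no zero), and
#' `positionalDominance` the fraction of sites at that offset or 1 nt to
#' either side.
#'
#' @slot consensus IUPAC consensus string
#' @slot sites data.frame with columns `seq`, `start`, `offset`, `word`
#' @slot k,N integer site / input counts
#' @slot eValue internal expected-false-discoveries score (see vignette)
#' @slot modalOffset,positionalDominance positional anchor statistics
#' @slot provenance free-text origin tag (e.g. region)
#' @export
setClass("MotifModel",
         representation(consensus = "character", sites = "data.frame",
                        k = "integer", N = "integer", eValue = "numeric",
                        modalOffset = "integer",
                        positionalDominance = "numeric",
                        provenance = "character"))

setValidity("MotifModel", function(object) {
  msgs <- character()
  if (nchar(object@consensus) < 4) msgs <- c(msgs, "width must be >= 4")
  if (!all(strsplit(object@consensus, "")[[1]] %in% names(IUPAC_CODE_MAP)))
    msgs <- c(msgs, "consensus must be IUPAC")
  if (length(object@positionalDominance) &&
      (object@positionalDominance < 0 || object@positionalDominance > 1))
    msgs <- c(msgs, "positionalDominance must be in [0,1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MotifModel", function(object) {
  cat(sprintf("MotifModel %s  k=%d/%d  E=%.3g  offset=%+d  dominance=%.2f\n",
              object@consensus, object@k, object@N, object@eValue,
              object@modalOffset, object@positionalDominance))
})

#' @describeIn MotifModel-class the IUPAC consensus string
#' @param x a `MotifModel`
#' @export
consensusOf <- function(x) x@consensus

#' @describeIn MotifModel-class E-value-like score
#' @export
eValueOf <- function(x) x@eValue

#' @describeIn MotifModel-class modal frame offset (end = +1)
#' @export
modalOffsetOf <- function(x) x@modalOffset

#' @describeIn MotifModel-class positional dominance fraction
#' @export
positionalDominanceOf <- function(x) x@positionalDominance

#' @describeIn MotifModel-class ZOOPS site table
#' @export
motifSites <- function(x) x@sites

#' A group of merged motif models
#'
#' Models from different runs/regions whose consensi are compatible under
#' the ungapped-alignment similarity threshold are merged; the
#' representative consensus is the column-wise IUPAC union over the
#' offset-aligned members.
#'
#' @slot members list of [MotifModel-class]
#' @slot representative IUPAC consensus of the group
#' @slot shifts integer alignment shift of each member relative to the
#'   representative's first column
#' @export
setClass("MotifGroup",
         representation(members = "list", representative = "character",
                        shifts = "integer"))

setMethod("show", "MotifGroup", function(object) {
  cat(sprintf("MotifGroup %s (%d member%s)\n", object@representative,
              length(object@members),
              if (length(object@members) == 1) "" else "s"))
})

#' MORPH matrix: loci x 20 signed-offset columns
#'
#' Rows are anchored loci; columns are frame offsets -10..-1, +1..+10
#' (anchor base = +1, no zero).  Values are per-row read fractions
#' (counts divided by the row total within the 20-nt region).  Rows with
#' zero reads are always dropped; with the abundance filter on, rows whose
#' total is not strictly greater than `minTotal` are dropped too.
#'
#' @slot mat numeric matrix of normalized fractions (rows sum to 1)
#' @slot anchors retained anchors as width-1 `GRanges`
#' @slot rowTotals pre-normalization per-row read totals
#' @slot nAnchors number of anchors before read-based filtering
#' @slot tree `hclust` merge tree (after [wardCluster()]); may be empty
#' @slot leafOrder row display order (after [wardCluster()])
#' @export
setClass("MorphMatrix",
         representation(mat = "matrix", anchors = "GRanges",
                        rowTotals = "numeric", nAnchors = "integer",
                        tree = "list", leafOrder = "integer"))

setValidity("MorphMatrix", function(object) {
  msgs <- character()
  if (nrow(object@mat)) {
    if (max(abs(rowSums(object@mat) - 1)) > 1e-9)
      msgs <- c(msgs, "retained rows must sum to 1")
  }
  if (ncol(object@mat) && ncol(object@mat) %% 2 != 0)
    msgs <- c(msgs, "even number of offset columns required")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MorphMatrix", function(object) {
  cat(sprintf("MorphMatrix: %d retained / %d anchored loci, %d columns%s\n",
              nrow(object@mat), object@nAnchors, ncol(object@mat),
              if (length(object@leafOrder)) " (clustered)" else ""))
})

#' @describeIn MorphMatrix-class the normalized matrix
#' @param x a `MorphMatrix`
#' @export
morphMat <- function(x) x@mat

#' @describeIn MorphMatrix-class pre-normalization row totals
#' @export
morphRowTotals <- function(x) x@rowTotals

#' @describeIn MorphMatrix-class retained anchors
#' @export
morphAnchors <- function(x) x@anchors

#' Adaptor-mispriming artifact report
#'
#' @slot adaptor 3'-terminal adaptor sequence screened
#' @slot anchorCount genomic matches of the adaptor in the region
#' @slot matrix the underlying [MorphMatrix-class]
#' @slot flags per-retained-locus logical: modal column immediately
#'   downstream of the adaptor match
#' @slot flaggedFraction fraction of retained loci flagged
#' @export
setClass("ArtifactReport",
         representation(adaptor = "character", anchorCount = "integer",
                        matrix = "MorphMatrix", flags = "logical",
                        flaggedFraction = "numeric"))

setMethod("show", "ArtifactReport", function(object) {
  cat(sprintf(paste0("ArtifactReport '%s': %d anchors, %d retained loci, ",
                     "%.1f%% flagged\n"),
              object@adaptor, object@anchorCount, length(object@flags),
              100 * object@flaggedFraction))
})

#' @describeIn ArtifactReport-class fraction of retained loci whose modal
#'   column lies immediately downstream of the adaptor match
#' @param x an `ArtifactReport`
#' @export
flaggedFraction <- function(x) x@flaggedFraction
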