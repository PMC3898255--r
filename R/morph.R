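# MORPH: motif-oriented read positioning heat maps.  Per-locus normalized
# 20-position profiles of uncapped 5' ends around motif matches or feature
# 5' ends, abundance filtering, Ward clustering, summaries and rendering.

#' Anchors at every genomic match of a motif in one region class
#'
#' For `FIVE_UTR`/`CDS`/`THREE_UTR`/`INTRON` the region subsequences of
#' every transcript are scanned on the transcript strand; for `IGR` both
#' genome strands are scanned and matches whose anchor classifies as IGR
#' on the matched strand are kept.  The anchor is the genomic coordinate
#' of the motif's first base on the matched strand; overlapping matches
#' are all kept, duplicate anchors collapsed.
#'
#' @param ann a [DegAnnotation-class]
#' @param genome a [Biostrings::DNAStringSet]
#' @param consensus IUPAC motif
#' @param region one of [REGION_LEVELS]
#' @return width-1 `GRanges` of anchors (strand = frame orientation)
#' @export
anchorsFromMotif <- function(ann, genome, consensus, region) {
  region <- match.arg(region, REGION_LEVELS)
  w <- nchar(consensus)
  out <- list()
  collect <- function(chrom, st, a) {
    if (length(a))
      out[[length(out) + 1L]] <<- data.frame(chrom = chrom, strand = st,
                                             pos = as.integer(a))
  }
  asAnchors <- function() {
    if (!length(out)) return(GRanges())
    df <- unique(do.call(rbind, out))
    df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
    GRanges(df$chrom, IRanges(df$pos, width = 1L), strand = df$strand)
  }
  if (region == "IGR") {
    for (chrom in names(genome)) {
      for (st in c("+", "-")) {
        subject <- if (st == "+") genome[[chrom]]
                   else reverseComplement(genome[[chrom]])
        m <- Biostrings::matchPattern(consensus, subject, fixed = "subject")
        if (!length(m)) next
        a <- if (st == "+") IRanges::start(m)
             else length(subject) - IRanges::start(m) + 1L
        collect(chrom, st, a)
      }
    }
    anchors <- asAnchors()
    if (length(anchors)) {
      lab <- classifyPositions(ann, as.character(seqnames(anchors)),
                               as.character(strand(anchors)),
                               start(anchors))
      anchors <- anchors[lab == "IGR"]
    }
    return(anchors)
  }
  byTx <- regionIntervalsByTx(ann, region)
  txs <- ann@transcripts
  for (i in seq_along(txs)) {
    iv <- byTx[[txs$tx_id[i]]]
    if (is.null(iv) || !length(iv)) next
    st <- as.character(strand(txs)[i])
    chrom <- as.character(seqnames(txs)[i])
    for (j in seq_along(iv)) {
      s <- start(iv)[j]; e <- end(iv)[j]
      if (e - s + 1L < w) next
      piece <- subseq(genome[[chrom]], s, e)
      if (st == "-") piece <- reverseComplement(piece)
      m <- Biostrings::matchPattern(consensus, piece, fixed = "subject")
      if (!length(m)) next
      a <- if (st == "+") s + IRanges::start(m) - 1L
           else e - IRanges::start(m) + 1L
      collect(chrom, st, a)
    }
  }
  asAnchors()
}

#' Anchors at the 5'-terminal base of annotated features
#'
#' @param ann a [DegAnnotation-class]
#' @param featureClass ncRNA class label (e.g. `"CD_box"`) or `"all"`
#' @return width-1 `GRanges` of anchors
#' @export
anchorsFromFeatures <- function(ann, featureClass = "all") {
  nc <- ann@ncrna
  if (featureClass != "all") nc <- nc[nc$nc_class == featureClass]
  if (!length(nc)) return(GRanges())
  a <- ifelse(as.character(strand(nc)) == "+", start(nc), end(nc))
  GRanges(seqnames(nc), IRanges(a, width = 1L), strand = strand(nc))
}

#' Build a MORPH matrix
#'
#' For every anchor, uncapped-end counts are gathered at frame offsets
#' `-halfwidth..-1, +1..+halfwidth` (anchor base = +1, no zero) on the
#' anchor's strand.  Rows with zero reads are always dropped; with
#' `filterOn`, rows whose total is not strictly greater than `minTotal`
#' are dropped ("greater than five").  Retained rows are divided by their
#' total.
#'
#' @param anchors width-1 `GRanges` (from [anchorsFromMotif()] or
#'   [anchorsFromFeatures()])
#' @param ect an [EndCounts-class]
#' @param halfwidth columns per side (default 10, the 20-nt region)
#' @param minTotal abundance filter threshold (strict)
#' @param filterOn apply the abundance filter
#' @return a [MorphMatrix-class]
#' @export
buildMorphMatrix <- function(anchors, ect, halfwidth = 10L, minTotal = 5,
                             filterOn = TRUE) {
  if (halfwidth < 1) stop("halfwidth must be >= 1", call. = FALSE)
  offs <- c(-(halfwidth:1), 1:halfwidth)
  colnm <- paste0("m", ifelse(offs > 0, "+", ""), offs)
  if (!length(anchors)) {
    mat <- matrix(numeric(), 0, 2L * halfwidth,
                  dimnames = list(NULL, colnm))
    return(new("MorphMatrix", mat = mat, anchors = GRanges(),
               rowTotals = numeric(), nAnchors = 0L, tree = list(),
               leafOrder = integer()))
  }
  lk <- endCountLookup(ect)
  chrom <- as.character(seqnames(anchors))
  st <- as.character(strand(anchors))
  a <- start(anchors)
  counts <- matrix(0, length(anchors), length(offs),
                   dimnames = list(NULL, colnm))
  for (j in seq_along(offs)) {
    g <- frameToGenomic(a, st, offs[j])
    counts[, j] <- lookupCounts(lk, chrom, st, g)
  }
  totals <- rowSums(counts)
  keep <- totals > 0
  if (filterOn) keep <- keep & (totals > minTotal)
  mat <- counts[keep, , drop = FALSE] / totals[keep]
  rownames(mat) <- paste(chrom[keep], a[keep], st[keep], sep = ":")
  new("MorphMatrix", mat = mat, anchors = anchors[keep],
      rowTotals = unname(totals[keep]), nAnchors = length(anchors),
      tree = list(), leafOrder = seq_len(sum(keep)))
}

#' Ward-cluster the rows of a MORPH matrix
#'
#' Agglomerative clustering with Euclidean distance on the normalized
#' rows and Ward linkage (`ward.D2` by default: Lance-Williams
#' minimum-variance update on squared distances, heights reported on the
#' distance scale).  Leaf order is the deterministic standard dendrogram
#' order.
#'
#' @param mm a [MorphMatrix-class] with at least one retained row
#' @param variant `"ward.D2"` (default) or `"ward.D"`
#' @return `mm` with `tree` and `leafOrder` filled
#' @export
wardCluster <- function(mm, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  n <- nrow(mm@mat)
  if (n < 1) stop("no retained rows", call. = FALSE)
  if (n == 1) {
    mm@leafOrder <- 1L
    mm@tree <- list()
    return(mm)
  }
  h <- hclust(dist(mm@mat), method = variant)
  mm@tree <- unclass(h)[c("merge", "height", "order", "labels", "method")]
  mm@leafOrder <- as.integer(h$order)
  mm
}

morphTree <- function(mm) {
  if (!length(mm@tree)) return(NULL)
  structure(c(mm@tree, list(call = quote(wardCluster()),
                            dist.method = "euclidean")),
            class = "hclust")
}

# modal column index per row; ties go to the most upstream tied column
modalColumns <- function(mat) {
  apply(mat, 1L, function(r) which(r == max(r))[1])
}

#' Summarize a MORPH matrix
#'
#' Per-offset mean profile over retained rows and the per-offset
#' modal-locus fraction (share of loci whose row maximum is at that
#' offset; a tied row contributes only to the most upstream tied column).
#'
#' @param mm a [MorphMatrix-class]
#' @return data.frame with `offset`, `mean_fraction`, `modal_fraction`,
#'   plus attributes `retained` and `total`
#' @export
summarizeMorph <- function(mm) {
  offs <- as.integer(sub("^m\\+?", "", colnames(mm@mat)))
  n <- nrow(mm@mat)
  if (n == 0) {
    out <- data.frame(offset = offs, mean_fraction = 0, modal_fraction = 0)
  } else {
    modal <- modalColumns(mm@mat)
    out <- data.frame(offset = offs,
                      mean_fraction = unname(colMeans(mm@mat)),
                      modal_fraction = as.numeric(
                        tabulate(modal, ncol(mm@mat)) / n))
  }
  attr(out, "retained") <- n
  attr(out, "total") <- mm@nAnchors
  out
}

#' Write a MORPH matrix TSV
#'
#' Columns: anchor id, chrom, strand, 1-based anchor position, row total,
#' then the 20 normalized columns in fixed `m-10..m+10` order.
#'
#' @param mm a [MorphMatrix-class]
#' @param path output file
#' @param extraHeader optional `#`-prefixed provenance lines
#' @export
writeMorphMatrix <- function(mm, path, extraHeader = character()) {
  an <- mm@anchors
  df <- data.frame(anchor = rownames(mm@mat),
                   chrom = as.character(seqnames(an)),
                   strand = as.character(strand(an)),
                   anchor_pos = start(an),
                   row_total = mm@rowTotals)
  df <- cbind(df, as.data.frame(mm@mat, row.names = NULL))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in extraHeader) writeLines(paste0("# ", h), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the Ward merge tree as newick
#'
#' @param mm a clustered [MorphMatrix-class]
#' @param path output file
#' @export
writeMorphTree <- function(mm, path) {
  h <- morphTree(mm)
  if (is.null(h)) {
    writeLines(sprintf("(%s);", paste(rownames(mm@mat), collapse = ",")),
               path)
    return(invisible(path))
  }
  h$labels <- rownames(mm@mat)
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Render a MORPH heat map
#'
#' Rows in dendrogram leaf order (clustered first with [wardCluster()] if
#' needed), columns `-halfwidth..+halfwidth`, the motif span boxed, and
#' the locus counts annotated above as `retained (total)`.  Output format
#' follows the file extension (`.png` or `.svg`).
#'
#' @param mm a [MorphMatrix-class]
#' @param path output image path
#' @param motifWidth columns `+1..+motifWidth` get the box (skip if NULL)
#' @param main optional title prefix
#' @export
renderHeatmap <- function(mm, path, motifWidth = NULL, main = NULL) {
  if (nrow(mm@mat) == 0) stop("no loci retained", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
                png = function(p) png(p, width = 720, height = 640),
                svg = function(p) svg(p, width = 8, height = 7),
                stop("unsupported extension: ", ext, call. = FALSE))
  ord <- if (length(mm@leafOrder) == nrow(mm@mat)) mm@leafOrder
         else seq_len(nrow(mm@mat))
  m <- mm@mat[ord, , drop = FALSE]
  dev(path)
  on.exit(dev.off())
  pal <- colorRampPalette(c("white", "orange", "red3"))(100)
  par(mar = c(4, 4, 3, 1))
  image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
        z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
        col = pal, zlim = c(0, 1), xlab = "position (motif base 1 = +1)",
        ylab = "loci", axes = FALSE)
  axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
       cex.axis = 0.7)
  box()
  if (!is.null(motifWidth)) {
    first <- match("m+1", colnames(m))
    if (!is.na(first))
      rect(first - 0.5, 0.5,
           min(first + motifWidth - 1, ncol(m)) + 0.5, nrow(m) + 0.5,
           border = "blue", lwd = 2)
  }
  title(main = sprintf("%s%d (%d)", if (is.null(main)) "" else
                         paste0(main, "  "), nrow(m), mm@nAnchors))
  invisible(path)
}
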