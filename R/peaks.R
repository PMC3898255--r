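# Predominant uncapped 5'-end calling: 21-nt window profiles, the local
# dominance criterion, the binomial significance test, miRNA-site
# exclusion, abundance ranking, and 50-nt window extraction.

#' Parameters of the predominant-end test
#'
#' Defaults follow the published procedure: a 21-position window centred on
#' the candidate end, per-position null probability `q = 1/21`, dominance
#' threshold 0.5 (the end plus its two immediate neighbours must carry at
#' least half the window's reads), `P < 1e-5`, and at most the top 1000
#' most abundant ends per genomic region.
#'
#' @param windowSize odd window size in nt
#' @param q per-position null probability
#' @param dominanceMin minimum centre-fraction (inclusive)
#' @param pThreshold binomial P-value cutoff (exclusive)
#' @param topK per-region cap on ends forwarded to motif analysis
#' @param mirnaTolerance +/- nt tolerance for miRNA-site exclusion
#' @param pvalueMode `"tail"` (upper tail, default) or `"point"` (the
#'   literal point-mass formula)
#' @return a list of class `PeakTestParams`
#' @export
peakParams <- function(windowSize = 21L, q = 1 / 21, dominanceMin = 0.5,
                       pThreshold = 1e-5, topK = 1000L, mirnaTolerance = 0L,
                       pvalueMode = c("tail", "point")) {
  pvalueMode <- match.arg(pvalueMode)
  stopifnot(windowSize %% 2 == 1, windowSize >= 3,
            q > 0, q < 1, dominanceMin > 0, dominanceMin <= 1, topK >= 1)
  structure(list(windowSize = as.integer(windowSize), q = q,
                 dominanceMin = dominanceMin, pThreshold = pThreshold,
                 topK = as.integer(topK),
                 mirnaTolerance = as.integer(mirnaTolerance),
                 pvalueMode = pvalueMode),
            class = "PeakTestParams")
}

#' Upper-tail binomial probability, computed in log space
#'
#' `P(X >= x)` for `X ~ Binomial(n, q)`, summed over exact log point
#' masses with a log-sum-exp accumulator for numerical stability.  With
#' `mode = "point"` the single point mass `C(n, x) q^x (1-q)^(n-x)` is
#' returned instead.
#'
#' @param x,n observed and total counts (vectorized)
#' @param q success probability in (0, 1)
#' @param mode `"tail"` or `"point"`
#' @return P-value(s) in (0, 1]
#' @examples
#' binomTail(4, 4, 1 / 21)  # (1/21)^4, just below 1e-5
#' @export
binomTail <- function(x, n, q, mode = c("tail", "point")) {
  mode <- match.arg(mode)
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)", call. = FALSE)
  x <- as.integer(x); n <- as.integer(n)
  if (any(n < 1) || any(x < 0) || any(x > n))
    stop("need 0 <= x <= n, n >= 1", call. = FALSE)
  lq <- log(q); l1q <- log1p(-q)
  one <- function(xi, ni) {
    if (mode == "point")
      return(exp(lchoose(ni, xi) + xi * lq + (ni - xi) * l1q))
    if (xi == 0L) return(1)
    k <- xi:ni
    min(1, exp(logSumExp(lchoose(ni, k) + k * lq + (ni - k) * l1q)))
  }
  mapply(one, x, n)
}

#' 21-position read profile around a focal end
#'
#' Counts at signed offsets `-h..+h` (`h = (windowSize - 1) / 2`), oriented
#' 5' to 3' along the read's strand (offset +1 is 1 nt 3' of the end on
#' that strand); offset 0 is the end itself.  Positions beyond chromosome
#' bounds contribute 0.
#'
#' @param ect an [EndCounts-class]
#' @param chrom,strand,pos the focal end (1-based)
#' @param windowSize odd window size
#' @return named numeric vector of length `windowSize` (names `-h`..`h`)
#' @export
windowProfile <- function(ect, chrom, strand, pos, windowSize = 21L) {
  checkStrand(strand)
  h <- (windowSize - 1L) %/% 2L
  off <- (-h):h
  gpos <- if (strand == "+") pos + off else pos - off
  lk <- endCountLookup(ect)
  structure(lookupCounts(lk, chrom, strand, gpos), names = off)
}

#' Dominance fraction of a window profile
#'
#' The fraction of the window's reads carried by the focal end plus the
#' positions 1 nt upstream and 1 nt downstream of it.
#'
#' @param profile output of [windowProfile()]
#' @return fraction in [0, 1]
#' @export
dominanceFraction <- function(profile) {
  n <- sum(profile)
  if (n == 0) stop("empty window", call. = FALSE)
  ctr <- match(c("-1", "0", "1"), names(profile))
  sum(profile[ctr[!is.na(ctr)]]) / n
}

#' Call predominant uncapped 5' ends
#'
#' Every position with at least one read is a candidate.  A candidate is
#' retained iff its dominance fraction is >= `dominanceMin` and its
#' binomial P-value is < `pThreshold`.  Retained ends are labelled by
#' [classifyPositions()] at the end position.
#'
#' @param ect an [EndCounts-class]
#' @param ann a [DegAnnotation-class] (or `NULL` to skip region labels)
#' @param params a [peakParams()] list
#' @return data.frame with columns `chrom`, `strand`, `pos` (1-based),
#'   `region`, `x` (reads at the end), `n` (window total), `dominance`,
#'   `p_value`, `excluded_mirna` (all `FALSE` until
#'   [filterMirnaSites()]); filter-stage counts are attached as
#'   `attr(, "stageCounts")`
#' @export
callPeaks <- function(ect, ann = NULL, params = peakParams()) {
  gr <- endPositions(ect)
  empty <- data.frame(chrom = character(), strand = character(),
                      pos = integer(), region = character(),
                      x = numeric(), n = numeric(), dominance = numeric(),
                      p_value = numeric(), excluded_mirna = logical())
  if (length(gr) == 0) {
    attr(empty, "stageCounts") <- c(candidates = 0, dominance_pass = 0,
                                    p_pass = 0, retained = 0)
    return(empty)
  }
  h <- (params$windowSize - 1L) %/% 2L
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   strand = as.character(strand(gr)),
                   pos = start(gr), x = as.numeric(mcols(gr)$count))
  parts <- split(seq_len(nrow(df)), paste(df$chrom, df$strand))
  res <- lapply(parts, function(ix) {
    d <- df[ix, ]
    o <- order(d$pos)
    d <- d[o, ]
    p <- d$pos; cnt <- d$x
    cs <- c(0, cumsum(cnt))
    lo <- findInterval(p - h - 1L, p)   # records strictly left of window
    hi <- findInterval(p + h, p)        # records inside or left of window
    n <- cs[hi + 1L] - cs[lo + 1L]
    up <- match(p - 1L, p); dn <- match(p + 1L, p)
    ctr <- cnt +
      ifelse(is.na(up), 0, cnt[ifelse(is.na(up), 1L, up)]) +
      ifelse(is.na(dn), 0, cnt[ifelse(is.na(dn), 1L, dn)])
    d$n <- n
    d$dominance <- ctr / n
    d
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$p_value <- binomTail(out$x, out$n, params$q, mode = params$pvalueMode)
  domPass <- out$dominance >= params$dominanceMin
  pPass <- out$p_value < params$pThreshold
  stage <- c(candidates = nrow(out), dominance_pass = sum(domPass),
             p_pass = sum(pPass), retained = sum(domPass & pPass))
  out <- out[domPass & pPass, , drop = FALSE]
  out$region <- if (!is.null(ann) && nrow(out))
    classifyPositions(ann, out$chrom, out$strand, out$pos)
  else rep(NA_character_, nrow(out))
  out$excluded_mirna <- rep(FALSE, nrow(out))
  out <- out[order(out$chrom, out$pos, out$strand),
             c("chrom", "strand", "pos", "region", "x", "n",
               "dominance", "p_value", "excluded_mirna")]
  rownames(out) <- NULL
  attr(out, "stageCounts") <- stage
  out
}

#' Flag peaks at known miRNA cleavage sites
#'
#' Peaks whose end position lies within `tolerance` nt of an exclusion
#' site on the same strand get `excluded_mirna = TRUE`.  They stay in the
#' returned table (the full report keeps them) but are omitted from motif
#' analysis downstream.  The flag never alters `p_value` or `dominance`.
#'
#' @param peaks output of [callPeaks()]
#' @param sites exclusion sites: a width-1 `GRanges`, or a BED file path
#' @param tolerance +/- nt window
#' @return `peaks` with the `excluded_mirna` column set
#' @export
filterMirnaSites <- function(peaks, sites, tolerance = 0L) {
  if (is.character(sites)) {
    gr <- rtracklayer::import(sites, format = "BED")
    sites <- GRanges(seqnames(gr), IRanges(end(gr), width = 1L),
                     strand = strand(gr))
    # BED half-open single positions: chromEnd is the 1-based coordinate
  }
  if (!nrow(peaks)) return(peaks)
  key <- paste(as.character(seqnames(sites)), as.character(strand(sites)))
  spos <- split(start(sites), key)
  pkey <- paste(peaks$chrom, peaks$strand)
  hit <- vapply(seq_len(nrow(peaks)), function(i) {
    sp <- spos[[pkey[i]]]
    !is.null(sp) && any(abs(sp - peaks$pos[i]) <= tolerance)
  }, logical(1))
  peaks$excluded_mirna <- hit
  peaks
}

#' Keep the top-k most abundant peaks of one region
#'
#' Ranked by `x` (reads at the end itself) descending; ties broken by
#' (chrom, pos) ascending for determinism.
#'
#' @param peaks peaks sharing one region label
#' @param topK cap
#' @return at most `topK` rows
#' @export
selectTop <- function(peaks, topK = 1000L) {
  if (nrow(peaks) <= topK) return(peaks)
  o <- order(-peaks$x, peaks$chrom, peaks$pos)
  out <- peaks[o[seq_len(topK)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract 50-nt strand-oriented windows around peaks
#'
#' The window spans frame offsets -25..-1 and +1..+25 (no zero; the end
#' nucleotide is offset +1, i.e. the 26th character).  Minus-strand
#' windows are reverse-complemented.  Windows truncated at a chromosome
#' edge are padded with `N` and flagged.
#'
#' @param peaks output of [callPeaks()] (rows to extract)
#' @param genome a [Biostrings::DNAStringSet]
#' @param flank half-window in nt (default 25)
#' @return [Biostrings::DNAStringSet] named
#'   `"<chrom>:<pos>:<strand>:<region>"`, with a logical `truncated`
#'   metadata column
#' @export
extractWindows <- function(peaks, genome, flank = 25L) {
  if (!nrow(peaks)) {
    out <- DNAStringSet()
    mcols(out) <- DataFrame(truncated = logical())
    return(out)
  }
  missing <- setdiff(unique(peaks$chrom), names(genome))
  if (length(missing))
    stop("chromosome missing from genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sl <- genomeSeqlengths(genome)
  seqs <- character(nrow(peaks)); trunc <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    e <- peaks$pos[i]; chrom <- peaks$chrom[i]; st <- peaks$strand[i]
    if (st == "+") { from <- e - flank; to <- e + flank - 1L }
    else          { from <- e - flank + 1L; to <- e + flank }
    cf <- max(1L, from); ct <- min(sl[[chrom]], to)
    body <- as.character(subseq(genome[[chrom]], cf, ct))
    s <- paste0(strrep("N", cf - from), body, strrep("N", to - ct))
    if (st == "-") s <- revcompChar(s)
    seqs[i] <- s
    trunc[i] <- (cf != from) || (ct != to)
  }
  out <- DNAStringSet(seqs)
  names(out) <- paste(peaks$chrom, peaks$pos, peaks$strand,
                      ifelse(is.na(peaks$region), "NA", peaks$region),
                      sep = ":")
  mcols(out) <- DataFrame(truncated = trunc)
  out
}

#' Write a peak report TSV
#'
#' @param peaks output of [callPeaks()]
#' @param path output file
#' @param extraHeader optional `#`-prefixed provenance lines
#' @export
writePeaks <- function(peaks, path, extraHeader = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in extraHeader) writeLines(paste0("# ", h), con)
  write.table(peaks, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
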