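# Shared helpers: no-zero coordinate frames, log-space sums, small utilities.

#' Region labels used throughout the package
#'
#' Every strand-aware genomic position is classified into exactly one of
#' five classes: 5' UTR, CDS, 3' UTR, intron, or intergenic region (IGR).
#' @export
REGION_LEVELS <- c("FIVE_UTR", "CDS", "THREE_UTR", "INTRON", "IGR")

# log(sum(exp(x))) without overflow; -Inf-safe
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# ---- no-zero frames ---------------------------------------------------------
# Positions relative to an anchor base use the field's 1-based no-zero
# convention: the anchor base itself is +1, 1 nt downstream is +2, 1 nt
# upstream is -1.  "delta" is the plain signed nt distance from the anchor
# base (0 = anchor base).

frameToDelta <- function(o) {
  stopifnot(all(o != 0L))
  ifelse(o > 0L, o - 1L, o)
}

deltaToFrame <- function(d) {
  as.integer(ifelse(d >= 0L, d + 1L, d))
}

# frame offsets of the two positions 1 nt up/downstream of frame offset o
frameNeighbors <- function(o) {
  deltaToFrame(frameToDelta(o) + c(-1L, 1L))
}

# genomic coordinate of frame offset o relative to anchor base a on strand s
frameToGenomic <- function(anchor, strand, o) {
  d <- frameToDelta(o)
  ifelse(strand == "+", anchor + d, anchor - d)
}

# frame offset of genomic position g relative to anchor base a on strand s
genomicToFrame <- function(anchor, strand, g) {
  d <- ifelse(strand == "+", g - anchor, anchor - g)
  deltaToFrame(d)
}

# 1-based start position within a peak window (end base = position
# WINDOW_ANCHOR) -> frame offset (end = +1)
WINDOW_ANCHOR <- 26L

windowFrameOffset <- function(start, anchor = WINDOW_ANCHOR) {
  deltaToFrame(as.integer(start) - anchor)
}

# ---- small utilities --------------------------------------------------------

revcompChar <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits; used to stamp
# pipeline outputs with a configuration fingerprint
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x01")) %% 256L
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- (h - lo) + bitwXor(as.integer(lo), as.integer(b))
    # h * prime mod 2^32, split to stay within exact double arithmetic
    h1 <- floor(h / 65536); h0 <- h %% 65536
    h <- (h0 * prime + ((h1 * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(floor(h / 65536)),
          as.integer(h %% 65536))
}

configHash <- function(config) {
  fnv1a(paste(deparse(config), collapse = "\n"))
}

checkStrand <- function(strand) {
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  strand
}

# fast per-position count lookup: key "chrom|strand|pos" -> count
endCountLookup <- function(ect) {
  gr <- endPositions(ect)
  key <- paste(as.character(seqnames(gr)), as.character(strand(gr)),
               start(gr), sep = "|")
  structure(as.numeric(mcols(gr)$count), names = key)
}

lookupCounts <- function(lk, chrom, strand, pos) {
  v <- lk[paste(chrom, strand, pos, sep = "|")]
  v[is.na(v)] <- 0
  unname(v)
}
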