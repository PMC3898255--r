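# Library-quality diagnostics: 3'-terminal base composition of reads and
# adaptor-mispriming artifact screening.

#' Default 5'-adaptor 3'-end presets by library protocol
#' @export
ADAPTOR_PRESETS <- c(PARE = "GTCCGAC", PARE_full = "AGTCCGAC",
                     degradome_seq = "GATCCAAC", GMUCT = "GACGATC")

#' Base composition of the last k nucleotides of unique reads
#'
#' Duplicate read sequences are removed first ("unique reads"); fractions
#' of A/C/G/T are reported for each of the last `k` positions.  A biased
#' terminal composition (e.g. reads ending in "GC") indicates ligation or
#' size-selection bias that distorts the whole library.
#'
#' @param reads [Biostrings::DNAStringSet] or character vector of read
#'   sequences
#' @param k number of terminal positions (default 5)
#' @return k x 4 matrix of fractions; rows named `-k..-1` (3'-most last),
#'   columns `A`, `C`, `G`, `T`; each row sums to 1
#' @export
terminalComposition <- function(reads, k = 5L) {
  s <- unique(as.character(reads))
  if (!length(s)) stop("empty input", call. = FALSE)
  if (any(nchar(s) < k))
    stop("k larger than shortest read", call. = FALSE)
  out <- matrix(0, k, 4, dimnames = list(paste0(-(k:1)),
                                         c("A", "C", "G", "T")))
  for (j in seq_len(k)) {
    pos <- nchar(s) - k + j
    b <- substr(s, pos, pos)
    tab <- table(factor(b, levels = c("A", "C", "G", "T")))
    out[j, ] <- as.numeric(tab) / length(s)
  }
  out
}

#' Overall base composition of a sequence set
#'
#' Reference background (e.g. annotated cDNA) for comparing against
#' [terminalComposition()].
#'
#' @param seqs [Biostrings::DNAStringSet] or character vector
#' @return named fractions of A/C/G/T
#' @export
overallComposition <- function(seqs) {
  backgroundFreqs(as.character(seqs))
}

#' Screen for adaptor-mispriming artifacts
#'
#' Capped transcripts whose internal sequence anneals to the 3' end of
#' the 5'-adaptor primer yield false uncapped 5' ends starting immediately
#' downstream of the genomic adaptor match.  All matches of `adaptor3p`
#' in the region are anchored, a MORPH matrix is built, and each retained
#' locus is flagged iff its modal column is the first base after the
#' match (frame offset `nchar(adaptor3p) + 1`).
#'
#' @param ect an [EndCounts-class]
#' @param genome a [Biostrings::DNAStringSet]
#' @param ann a [DegAnnotation-class]
#' @param adaptor3p 3'-terminal adaptor sequence (>= 5 nt); see
#'   [ADAPTOR_PRESETS]
#' @param region region class to scan (default CDS)
#' @param minTotal,filterOn MORPH abundance filter (see
#'   [buildMorphMatrix()])
#' @return an [ArtifactReport-class]
#' @export
artifactScreen <- function(ect, genome, ann, adaptor3p = "GTCCGAC",
                           region = "CDS", minTotal = 5, filterOn = TRUE) {
  if (nchar(adaptor3p) < 5)
    stop("adaptor3p must be at least 5 nt", call. = FALSE)
  anchors <- anchorsFromMotif(ann, genome, adaptor3p, region)
  mm <- buildMorphMatrix(anchors, ect, minTotal = minTotal,
                         filterOn = filterOn)
  flagCol <- paste0("m+", nchar(adaptor3p) + 1L)
  flags <- logical(0)
  if (nrow(mm@mat)) {
    target <- match(flagCol, colnames(mm@mat))
    flags <- if (is.na(target)) rep(FALSE, nrow(mm@mat))
             else modalColumns(mm@mat) == target
  }
  new("ArtifactReport", adaptor = adaptor3p,
      anchorCount = length(anchors), matrix = mm, flags = flags,
      flaggedFraction = if (length(flags)) mean(flags) else 0)
}
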