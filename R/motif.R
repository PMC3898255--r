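# Position-anchored motif machinery: IUPAC consensus handling, scanning,
# ZOOPS site selection, the anchored exact-word + Hamming-merge finder,
# E-value and positional filtering, cross-run merging, shuffled controls,
# and the import bridge for externally discovered sites.

iupacSets <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- lapply(IUPAC_CODE_MAP, function(s) strsplit(s, "")[[1]])
    cache
  }
})

setToIupac <- function(set) {
  sets <- iupacSets()
  key <- paste(sort(unique(set)), collapse = "")
  hit <- names(sets)[vapply(sets, function(s)
    paste(sort(s), collapse = "") == key, logical(1))]
  if (!length(hit)) stop("no IUPAC letter for base set ", key, call. = FALSE)
  hit[[1]]
}

#' Expand an IUPAC consensus into per-column base sets
#'
#' @param consensus IUPAC string
#' @return list of character vectors, one per column
#' @examples
#' iupacExpand("TGTAHAKA")[[5]]  # A, C, T
#' @export
iupacExpand <- function(consensus) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- !(letters %in% names(IUPAC_CODE_MAP))
  if (any(bad))
    stop("illegal IUPAC character(s): ",
         paste(unique(letters[bad]), collapse = ", "), call. = FALSE)
  unname(iupacSets()[letters])
}

#' Does a word match an IUPAC consensus?
#'
#' @param consensus IUPAC string
#' @param word plain A/C/G/T word of the same width
#' @return logical
#' @export
iupacMatch <- function(consensus, word) {
  sets <- iupacExpand(consensus)
  w <- strsplit(toupper(word), "")[[1]]
  if (length(w) != length(sets))
    stop("word length does not match consensus width", call. = FALSE)
  all(mapply(function(s, b) b %in% s, sets, w))
}

#' Scan sequences for an IUPAC consensus
#'
#' Reports every match start (1-based within each sequence).  With
#' `zoops = TRUE` at most one site per sequence is kept: the occurrence
#' nearest the global modal start, ties resolved to the more upstream
#' (smaller) start.
#'
#' @param consensus IUPAC string
#' @param seqs [Biostrings::DNAStringSet] or character vector
#' @param zoops keep at most one site per sequence
#' @return data.frame with columns `seq` (index), `start`, `word`
#' @export
scanSequences <- function(consensus, seqs, zoops = FALSE) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  if (!length(seqs)) stop("no sequences", call. = FALSE)
  m <- vmatchPattern(consensus, seqs, fixed = "subject")
  starts <- IRanges::start(m)
  n <- lengths(starts)
  df <- data.frame(seq = rep(seq_along(seqs), n),
                   start = unlist(starts, use.names = FALSE))
  if (!nrow(df)) return(cbind(df, word = character()))
  df$word <- substr(as.character(seqs)[df$seq], df$start,
                    df$start + nchar(consensus) - 1L)
  if (zoops && nrow(df)) {
    tab <- table(df$start)
    modal <- as.integer(names(tab)[which.max(tab)])  # ties: smallest start
    df <- df[order(df$seq, abs(df$start - modal), df$start), ]
    df <- df[!duplicated(df$seq), ]
    rownames(df) <- NULL
  }
  df
}

#' Modal frame offset and positional dominance of a site list
#'
#' The modal offset is the most frequent frame offset (ties resolved to
#' the smallest absolute value, then the negative one).  Dominance is the
#' fraction of sites at the modal offset or 1 nt to either side.
#'
#' @param offsets integer frame offsets (no zero)
#' @return list with `modalOffset` and `positionalDominance`
#' @export
positionalStats <- function(offsets) {
  if (!length(offsets)) stop("empty site list", call. = FALSE)
  tab <- table(offsets)
  best <- as.integer(names(tab)[tab == max(tab)])
  best <- best[order(abs(best), best)][1]
  near <- c(best, frameNeighbors(best))
  list(modalOffset = best,
       positionalDominance = sum(offsets %in% near) / length(offsets))
}

# Hamming distance between two equal-width plain words
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# 0-order background base frequencies of a window set (ACGT only)
backgroundFreqs <- function(seqs) {
  s <- paste(as.character(seqs), collapse = "")
  tab <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
  p <- as.numeric(tab) / sum(tab)
  names(p) <- c("A", "C", "G", "T")
  p
}

# E-value-like score: expected number of equally good motifs under a
# 0-order background.  p0 = per-sequence occurrence probability of the
# consensus, E = W * P(K >= k), K ~ Binomial(N, p0), W = number of
# distinct observed words of this width (Bonferroni-style).
motifEvalue <- function(consensus, k, N, L, W, bg) {
  sets <- iupacExpand(consensus)
  pWord <- prod(vapply(sets, function(s) sum(bg[s]), numeric(1)))
  pWord <- min(max(pWord, 1e-300), 1 - 1e-12)
  p0 <- 1 - (1 - pWord)^(L - length(sets) + 1)
  W * binomTail(k, N, p0)
}

buildMotifModel <- function(consensus, windows, W, bg, provenance = "") {
  sites <- scanSequences(consensus, windows, zoops = TRUE)
  if (!nrow(sites)) return(NULL)
  sites$offset <- windowFrameOffset(sites$start)
  ps <- positionalStats(sites$offset)
  L <- nchar(as.character(windows)[1])
  new("MotifModel", consensus = consensus, sites = sites,
      k = nrow(sites), N = length(windows),
      eValue = as.numeric(motifEvalue(consensus, nrow(sites),
                                      length(windows), L, W, bg)),
      modalOffset = ps$modalOffset,
      positionalDominance = ps$positionalDominance,
      provenance = provenance)
}

#' Discover position-anchored motifs in peak windows
#'
#' An anchored exact-word finder: all A/C/G/T words of the requested
#' widths are counted over the windows (one presence per sequence); words
#' present in at least `minSites` sequences are seeds.  Seeds within
#' Hamming distance 1 whose modal starts agree within 1 nt are greedily
#' merged into IUPAC consensi (column-wise union), ZOOPS site lists are
#' recomputed by scanning each consensus, and models are scored with an
#' internal E-value (see vignette) and sorted by it.
#'
#' @param windows 50-nt peak windows ([Biostrings::DNAStringSet]); `N`
#'   padding at truncated edges is ignored (words containing `N` are
#'   skipped)
#' @param widths motif widths to search (default 6-8)
#' @param minSites minimum number of sequences carrying the word
#' @param provenance tag stored on each model
#' @return list of [MotifModel-class], sorted by E-value ascending
#' @export
discoverAnchored <- function(windows, widths = 6:8, minSites = 5L,
                             provenance = "") {
  if (is.character(windows)) windows <- DNAStringSet(windows)
  if (length(windows) < minSites)
    stop("fewer than ", minSites, " windows", call. = FALSE)
  chars <- as.character(windows)
  L <- unique(nchar(chars))
  if (length(L) != 1) stop("windows must have equal length", call. = FALSE)
  bg <- backgroundFreqs(gsub("N", "", chars))
  models <- list()
  for (w in widths) {
    starts <- seq_len(L - w + 1L)
    words <- unlist(lapply(chars, function(s)
      substring(s, starts, starts + w - 1L)), use.names = FALSE)
    seqIdx <- rep(seq_along(chars), each = length(starts))
    keep <- !grepl("N", words, fixed = TRUE)
    words <- words[keep]; seqIdx <- seqIdx[keep]
    startIdx <- rep(starts, times = length(chars))[keep]
    if (!length(words)) next
    W <- length(unique(words))
    # per-sequence presence counts
    presKey <- !duplicated(paste(seqIdx, words))
    kTab <- table(words[presKey])
    cand <- names(kTab)[kTab >= minSites]
    if (!length(cand)) next
    modalStart <- vapply(cand, function(wd) {
      st <- startIdx[words == wd]
      tab <- table(st)
      as.integer(names(tab)[which.max(tab)])
    }, integer(1))
    ord <- order(-as.integer(kTab[cand]), cand)
    cand <- cand[ord]; modalStart <- modalStart[ord]
    used <- logical(length(cand))
    for (i in seq_along(cand)) {
      if (used[i]) next
      grp <- i
      for (j in seq_along(cand)) {
        if (j == i || used[j]) next
        if (hamming(cand[i], cand[j]) <= 1 &&
            abs(modalStart[i] - modalStart[j]) <= 1)
          grp <- c(grp, j)
      }
      used[grp] <- TRUE
      cols <- lapply(seq_len(w), function(cc)
        unique(substr(cand[grp], cc, cc)))
      consensus <- paste(vapply(cols, setToIupac, character(1)),
                         collapse = "")
      mod <- buildMotifModel(consensus, windows, W, bg, provenance)
      if (!is.null(mod) && mod@k >= minSites)
        models[[length(models) + 1L]] <- mod
    }
  }
  models <- models[!duplicated(vapply(models, consensusOf, character(1)))]
  models[order(vapply(models, eValueOf, numeric(1)))]
}

#' Filter motif models by E-value and positional dominance
#'
#' Keeps models with `eValue < eMax` and `positionalDominance >=
#' dominanceMin`.
#'
#' @param models list of [MotifModel-class]
#' @param eMax E-value ceiling (exclusive)
#' @param dominanceMin positional-dominance floor (inclusive)
#' @return filtered list (a subset of the input)
#' @export
filterMotifs <- function(models, eMax = 1, dominanceMin = 0.5) {
  Filter(function(m) m@eValue < eMax &&
           m@positionalDominance >= dominanceMin, models)
}

# best ungapped alignment similarity of two IUPAC consensi:
# compatible overlap columns (non-empty set intersection) divided by the
# total aligned span (union of both widths at that shift)
consensusSimilarity <- function(c1, c2) {
  s1 <- iupacExpand(c1); s2 <- iupacExpand(c2)
  w1 <- length(s1); w2 <- length(s2)
  best <- 0; bestShift <- 0L
  for (shift in (-(w2 - 1L)):(w1 - 1L)) {
    # column i of c1 aligns with column i - shift of c2
    i1 <- max(1L, shift + 1L):min(w1, shift + w2)
    if (!length(i1)) next
    i2 <- i1 - shift
    compat <- sum(mapply(function(a, b) length(intersect(a, b)) > 0,
                         s1[i1], s2[i2]))
    span <- w1 + w2 - length(i1)
    sim <- compat / span
    if (sim > best) { best <- sim; bestShift <- shift }
  }
  list(similarity = best, shift = bestShift)
}

#' Merge motif models into homology groups
#'
#' Greedy single-linkage over the best ungapped offset alignment of the
#' IUPAC consensi: columns are compatible when their base sets intersect;
#' similarity is compatible columns divided by the aligned span; two
#' models link when similarity >= `similarityMin`.  Each group's
#' representative is the column-wise IUPAC union over its offset-aligned
#' members.  Every input model lands in exactly one group.
#'
#' @param models list of [MotifModel-class]
#' @param similarityMin linkage threshold (default 0.75)
#' @return list of [MotifGroup-class]
#' @export
mergeMotifs <- function(models, similarityMin = 0.75) {
  if (!length(models)) stop("no models to merge", call. = FALSE)
  n <- length(models)
  cons <- vapply(models, consensusOf, character(1))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (consensusSimilarity(cons[i], cons[j])$similarity >= similarityMin) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  lapply(unique(comp), function(cid) {
    ix <- which(comp == cid)
    # seed = lowest E-value member; align every member to the seed
    seed <- ix[which.min(vapply(models[ix], eValueOf, numeric(1)))]
    shifts <- vapply(ix, function(i)
      consensusSimilarity(cons[seed], cons[i])$shift, integer(1))
    widths <- nchar(cons[ix])
    lo <- min(shifts); hi <- max(shifts + widths - 1L)
    span <- hi - lo + 1L
    colSets <- vector("list", span)
    for (m in seq_along(ix)) {
      sets <- iupacExpand(cons[ix[m]])
      for (cc in seq_along(sets)) {
        at <- shifts[m] + cc - 1L - lo + 1L
        colSets[[at]] <- union(colSets[[at]], sets[[cc]])
      }
    }
    rep_cons <- paste(vapply(colSets, setToIupac, character(1)),
                      collapse = "")
    new("MotifGroup", members = models[ix], representative = rep_cons,
        shifts = as.integer(shifts - lo))
  })
}

#' Shuffle a motif consensus (seeded)
#'
#' Draws a uniformly random permutation of the consensus letters,
#' rejecting the identity permutation, as a negative control for
#' position-anchored read accumulation.
#'
#' @param consensus IUPAC string, width >= 2, with at least two distinct
#'   letters
#' @param seed RNG seed (the draw is reproducible and leaves the global
#'   RNG state untouched)
#' @return shuffled consensus (same letter multiset)
#' @export
shuffleMotif <- function(consensus, seed) {
  letters <- strsplit(consensus, "")[[1]]
  if (length(letters) < 2) stop("width must be >= 2", call. = FALSE)
  if (length(unique(letters)) < 2)
    stop("no non-identity anagram exists", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    repeat {
      p <- sample(letters)
      if (any(p != letters)) break
    }
    paste(p, collapse = "")
  })
}

#' Import externally discovered motif sites from TSV
#'
#' Bridge for motif finders run outside the package (e.g. on the exported
#' 50-nt window FASTA).  Required columns: `sequence_id`, `offset`
#' (no-zero frame, end = +1), `matched_word`, `consensus`.
#'
#' @param path TSV file
#' @return data.frame of sites (possibly empty)
#' @export
importSitesTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "offset", "matched_word", "consensus")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(df)) return(df)
  bad <- which(is.na(suppressWarnings(as.integer(df$offset))))
  if (length(bad))
    stop("malformed offset at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  df$offset <- as.integer(df$offset)
  zero <- which(df$offset == 0L)
  if (length(zero))
    stop("offset 0 is invalid (the frame has no zero) at line(s): ",
         paste(zero + 1L, collapse = ", "), call. = FALSE)
  df
}

#' Write a motif report TSV
#'
#' @param models list of [MotifModel-class]
#' @param path output file
#' @param extraHeader optional `#`-prefixed provenance lines
#' @export
writeMotifs <- function(models, path, extraHeader = character()) {
  df <- data.frame(
    consensus = vapply(models, consensusOf, character(1)),
    width = vapply(models, function(m) nchar(m@consensus), integer(1)),
    k = vapply(models, function(m) m@k, integer(1)),
    N = vapply(models, function(m) m@N, integer(1)),
    e_value = vapply(models, eValueOf, numeric(1)),
    modal_offset = vapply(models, modalOffsetOf, integer(1)),
    positional_dominance = vapply(models, positionalDominanceOf,
                                  numeric(1)),
    provenance = vapply(models, function(m) m@provenance, character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  for (h in extraHeader) writeLines(paste0("# ", h), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
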