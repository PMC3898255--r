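# Independent oracles, deliberately naive and separate from the package
# implementation paths they check.

# exhaustive upper-tail binomial probability via choose()
oracleBinomTail <- function(x, n, q) {
  if (x == 0) return(1)
  k <- x:n
  sum(choose(n, k) * q^k * (1 - q)^(n - k))
}

# brute-force IUPAC scan: slide every offset, test column membership
oracleScan <- function(consensus, seqs) {
  map <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
              Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
              K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
              D = c("A", "G", "T"), H = c("A", "C", "T"),
              V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  sets <- map[strsplit(consensus, "")[[1]]]
  w <- length(sets)
  hits <- list()
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[i], "")[[1]]
    for (st in seq_len(max(0, length(s) - w + 1))) {
      ok <- TRUE
      for (cc in seq_len(w))
        if (!(s[st + cc - 1] %in% sets[[cc]])) { ok <- FALSE; break }
      if (ok) hits[[length(hits) + 1]] <- c(i, st)
    }
  }
  if (!length(hits)) return(data.frame(seq = integer(), start = integer()))
  m <- do.call(rbind, hits)
  data.frame(seq = m[, 1], start = m[, 2])
}

# naive O(n^3) agglomerative Ward clustering (ward.D2 flavour:
# Lance-Williams update on squared Euclidean distances, heights reported
# on the distance scale).  Returns the merge member-sets and heights.
naiveWardD2 <- function(mat) {
  n <- nrow(mat)
  D2 <- as.matrix(dist(mat))^2
  size <- rep(1, n)
  members <- lapply(seq_len(n), identity)
  active <- rep(TRUE, n)
  sets <- list(); heights <- numeric()
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    idx <- which(active)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      i <- idx[a]; j <- idx[b]
      if (D2[i, j] < best) { best <- D2[i, j]; bi <- i; bj <- j }
    }
    heights[step] <- sqrt(best)
    newMembers <- sort(c(members[[bi]], members[[bj]]))
    sets[[step]] <- newMembers
    dij <- D2[bi, bj]
    for (k in which(active)) {
      if (k == bi || k == bj) next
      D2[bi, k] <- D2[k, bi] <-
        ((size[bi] + size[k]) * D2[bi, k] +
         (size[bj] + size[k]) * D2[bj, k] -
         size[k] * dij) / (size[bi] + size[bj] + size[k])
    }
    size[bi] <- size[bi] + size[bj]
    members[[bi]] <- newMembers
    active[bj] <- FALSE
  }
  list(sets = sets, heights = heights)
}

# merge member-sets and heights from an hclust tree
hclustSets <- function(h) {
  n <- length(h$height) + 1
  members <- vector("list", n - 1)
  getm <- function(v) if (v < 0) -v else members[[v]]
  for (s in seq_len(n - 1))
    members[[s]] <- sort(c(getm(h$merge[s, 1]), getm(h$merge[s, 2])))
  list(sets = members, heights = h$height)
}
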