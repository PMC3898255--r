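# A tiny two-gene genome for anchor tests: motifs planted at known spots.
morphFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    base <- strrep("ACGTTGCA", 200)  # 1600 nt, no AATAAA / CACACACA
    s <- strsplit(base, "")[[1]]
    # plant AATAAA at 1-based 1210 (inside geneP 3'UTR 1201-1300, +)
    s[1210:1215] <- strsplit("AATAAA", "")[[1]]
    # plant a 10-nt CA run at 1240 -> CACACACA anchors at 1240 and 1242
    s[1240:1249] <- strsplit("CACACACACA", "")[[1]]
    # geneM (-) 3'UTR 301-400: plant revcomp(AATAAA)=TTTATT at 350-355,
    # so the - strand anchor (motif base 1) is at genomic 355
    s[350:355] <- strsplit("TTTATT", "")[[1]]
    seqs <- c(cM = paste(s, collapse = ""))
    gff <- c("##gff-version 3",
             "cM\tt\tgene\t1001\t1300\t.\t+\t.\tID=geneP",
             "cM\tt\tmRNA\t1001\t1300\t.\t+\t.\tID=txP;Parent=geneP",
             "cM\tt\texon\t1001\t1300\t.\t+\t.\tParent=txP",
             "cM\tt\tCDS\t1051\t1200\t.\t+\t0\tParent=txP",
             "cM\tt\tgene\t301\t600\t.\t-\t.\tID=geneM",
             "cM\tt\tmRNA\t301\t600\t.\t-\t.\tID=txM;Parent=geneM",
             "cM\tt\texon\t301\t600\t.\t-\t.\tParent=txM",
             "cM\tt\tCDS\t401\t500\t.\t-\t0\tParent=txM",
             "cM\tt\tncRNA\t701\t790\t.\t+\t.\tID=ncP;ncrna_class=CD_box",
             "cM\tt\tncRNA\t801\t890\t.\t-\t.\tID=ncM;ncrna_class=CD_box")
    fa <- tempfile(fileext = ".fa"); gf <- tempfile(fileext = ".gff3")
    writeLines(paste0(">cM\n", seqs), fa)
    writeLines(gff, gf)
    cache <<- list(genome = readGenome(fa), ann = readAnnotation(gf))
    cache
  }
})

test_that("anchorsFromMotif finds strand-aware region matches", {
  fx <- morphFixture()
  a <- anchorsFromMotif(fx$ann, fx$genome, "AATAAA", "THREE_UTR")
  df <- data.frame(pos = start(a), strand = as.character(strand(a)))
  expect_equal(nrow(df), 2)
  expect_true(any(df$pos == 1210 & df$strand == "+"))
  expect_true(any(df$pos == 355 & df$strand == "-"))
  # self-overlapping CA run: two anchors
  ca <- anchorsFromMotif(fx$ann, fx$genome, "CACACACA", "THREE_UTR")
  expect_setequal(start(ca), c(1240, 1242))
  # absent motif: empty set
  expect_length(anchorsFromMotif(fx$ann, fx$genome, "GGGGGGGG",
                                 "THREE_UTR"), 0)
})

test_that("anchorsFromFeatures anchors the strand-aware 5' base", {
  fx <- morphFixture()
  a <- anchorsFromFeatures(fx$ann, "CD_box")
  df <- data.frame(pos = start(a), strand = as.character(strand(a)))
  expect_equal(nrow(df), 2)
  expect_true(any(df$pos == 701 & df$strand == "+"))
  expect_true(any(df$pos == 890 & df$strand == "-"))
  expect_length(anchorsFromFeatures(fx$ann, "HACA_box"), 0)
})

test_that("buildMorphMatrix normalizes rows and applies the > filter", {
  anchors <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    c(100, 200, 300, 400), width = 1), strand = "+")
  # locus 1: all reads at frame -3 (genomic 97); locus 2: total 5 (boundary)
  # locus 3: total 6; locus 4: zero reads
  ect <- mkEct(rep("c1", 4), rep("+", 4),
               c(97L, 197L, 297L, 305L), c(8L, 5L, 4L, 2L))
  mm <- buildMorphMatrix(anchors, ect, filterOn = TRUE)
  expect_equal(nrow(morphMat(mm)), 2)   # 5 dropped (strictly greater), 0 too
  expect_true(all(abs(rowSums(morphMat(mm)) - 1) < 1e-9))
  expect_equal(morphMat(mm)["c1:100:+", "m-3"], 1.0)
  expect_equal(mm@nAnchors, 4L)
  # filter off: low-count rows kept, zero rows still dropped (monotone)
  m0 <- buildMorphMatrix(anchors, ect, filterOn = FALSE)
  expect_equal(nrow(morphMat(m0)), 3)
  expect_true(all(rownames(morphMat(mm)) %in% rownames(morphMat(m0))))
  # column layout: 20 columns, no zero
  expect_identical(colnames(morphMat(mm))[10:11], c("m-1", "m+1"))
  expect_error(buildMorphMatrix(anchors, ect, halfwidth = 0), "halfwidth")
})

test_that("buildMorphMatrix frame is strand-aware (anchor base = +1)", {
  anchors <- GenomicRanges::GRanges("c1", IRanges::IRanges(100, width = 1),
                                    strand = "-")
  # on '-': offset +1 is the anchor base itself; -3 is genomic 103
  ect <- mkEct(c("c1", "c1"), c("-", "-"), c(103L, 100L), c(6L, 3L))
  mm <- buildMorphMatrix(anchors, ect, filterOn = FALSE)
  expect_equal(morphMat(mm)[1, "m-3"], 6 / 9)
  expect_equal(morphMat(mm)[1, "m+1"], 3 / 9)
})

test_that("buildMorphMatrix is invariant to record order and naming", {
  anchors <- GenomicRanges::GRanges("zzz", IRanges::IRanges(
    c(500, 900), width = 1), strand = "+")
  ect1 <- mkEct(rep("zzz", 4), rep("+", 4), c(497L, 503L, 897L, 905L),
                c(3L, 4L, 8L, 2L))
  ect2 <- mkEct(rep("zzz", 4), rep("+", 4), c(905L, 897L, 503L, 497L),
                c(2L, 8L, 4L, 3L))
  expect_identical(morphMat(buildMorphMatrix(anchors, ect1)),
                   morphMat(buildMorphMatrix(anchors, ect2)))
})

test_that("wardCluster agrees with the naive agglomerative oracle", {
  withr::with_seed(99, {
    for (rep in 1:6) {
      n <- sample(4:30, 1)
      mat <- matrix(stats::runif(n * 20), n)
      mat <- mat / rowSums(mat)
      mm <- new("MorphMatrix", mat = mat,
                anchors = GenomicRanges::GRanges(
                  rep("c1", n), IRanges::IRanges(seq_len(n), width = 1),
                  strand = "+"),
                rowTotals = rep(10, n), nAnchors = as.integer(n),
                tree = list(), leafOrder = seq_len(n))
      mm <- wardCluster(mm)
      tree <- structure(c(mm@tree, list(call = quote(x),
                                        dist.method = "euclidean")),
                        class = "hclust")
      got <- hclustSets(tree)
      want <- naiveWardD2(mat)
      expect_equal(got$heights, want$heights, tolerance = 1e-8)
      expect_identical(got$sets, want$sets)
      # merge heights are non-decreasing
      expect_true(all(diff(got$heights) >= -1e-12))
    }
  })
})

test_that("wardCluster separates two planted positioning patterns", {
  mk <- function(col) { v <- rep(0, 20); v[col] <- 1; v }
  mat <- rbind(t(replicate(10, mk(8) + stats::runif(20, 0, 0.02))),
               t(replicate(10, mk(18) + stats::runif(20, 0, 0.02))))
  mat <- mat / rowSums(mat)
  colnames(mat) <- paste0("m", c(-(10:1), paste0("+", 1:10)))
  mm <- new("MorphMatrix", mat = mat, anchors = GenomicRanges::GRanges(
    rep("c1", 20), IRanges::IRanges(1:20, width = 1), strand = "+"),
    rowTotals = rep(10, 20), nAnchors = 20L, tree = list(),
    leafOrder = 1:20)
  mm <- wardCluster(mm)
  h <- structure(c(mm@tree, list(call = quote(x),
                                 dist.method = "euclidean")),
                 class = "hclust")
  expect_identical(sort(unname(stats::cutree(h, 2)[1:10])), rep(1L, 10))
  expect_identical(sort(unname(stats::cutree(h, 2)[11:20])), rep(2L, 10))
  # identical rows merge first at height 0
  two <- matrix(rep(c(1, rep(0, 19)), 2), 2, byrow = TRUE)
  m2 <- new("MorphMatrix", mat = two, anchors = GenomicRanges::GRanges(
    c("c1", "c1"), IRanges::IRanges(1:2, width = 1), strand = "+"),
    rowTotals = c(6, 6), nAnchors = 2L, tree = list(), leafOrder = 1:2)
  m2 <- wardCluster(m2)
  expect_equal(m2@tree$height[1], 0)
  # single row: trivial tree, leaf order [1]
  one <- new("MorphMatrix", mat = two[1, , drop = FALSE],
             anchors = GenomicRanges::GRanges(
               "c1", IRanges::IRanges(1, width = 1), strand = "+"),
             rowTotals = 6, nAnchors = 1L, tree = list(),
             leafOrder = 1L)
  expect_identical(wardCluster(one)@leafOrder, 1L)
  expect_error(wardCluster(new("MorphMatrix",
                               mat = matrix(numeric(), 0, 20),
                               anchors = GenomicRanges::GRanges(),
                               rowTotals = numeric(), nAnchors = 0L,
                               tree = list(), leafOrder = integer())),
               "no retained rows")
})

test_that("summarizeMorph modal fractions respect the upstream tie rule", {
  mat <- rbind(c(rep(0, 9), 1, rep(0, 10)),          # modal at m-1
               rep(1 / 20, 20),                      # uniform tie -> m-10
               c(rep(0, 9), 1, rep(0, 10)))
  colnames(mat) <- paste0("m", c(paste0(-(10:1)), paste0("+", 1:10)))
  mm <- new("MorphMatrix", mat = mat, anchors = GenomicRanges::GRanges(
    rep("c1", 3), IRanges::IRanges(1:3, width = 1), strand = "+"),
    rowTotals = rep(10, 3), nAnchors = 5L, tree = list(), leafOrder = 1:3)
  sm <- summarizeMorph(mm)
  expect_equal(sm$modal_fraction[sm$offset == -1], 2 / 3)
  expect_equal(sm$modal_fraction[sm$offset == -10], 1 / 3)
  expect_equal(sum(sm$modal_fraction), 1)
  expect_equal(attr(sm, "retained"), 3)
  expect_equal(attr(sm, "total"), 5)
  # zero retained rows: all-zero summary instead of an error
  empty <- buildMorphMatrix(GenomicRanges::GRanges(), mkEct("c1", "+",
                                                            1L, 1L))
  s0 <- summarizeMorph(empty)
  expect_true(all(s0$modal_fraction == 0))
})

test_that("MORPH TSV export is stable across runs (golden file)", {
  fx <- morphFixture()
  ect <- mkEct(rep("cM", 3), rep("+", 3), c(1207L, 1206L, 1239L),
               c(6L, 2L, 9L))
  a <- anchorsFromMotif(fx$ann, fx$genome, "AATAAA", "THREE_UTR")
  mm <- buildMorphMatrix(a, ect)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeMorphMatrix(mm, f1)
  writeMorphMatrix(buildMorphMatrix(a, ect), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[1], "anchor\tchrom\tstrand\tanchor_pos")
})

test_that("renderHeatmap writes raster and vector output", {
  mat <- matrix(c(0.8, 0.2, rep(0, 18)), 1, 20,
                dimnames = list("c1:5:+", paste0(
                  "m", c(paste0(-(10:1)), paste0("+", 1:10)))))
  mm <- new("MorphMatrix", mat = mat, anchors = GenomicRanges::GRanges(
    "c1", IRanges::IRanges(5, width = 1), strand = "+"),
    rowTotals = 10, nAnchors = 1L, tree = list(), leafOrder = 1L)
  png <- withr::local_tempfile(fileext = ".png")
  svg <- withr::local_tempfile(fileext = ".svg")
  renderHeatmap(mm, png, motifWidth = 6)
  renderHeatmap(mm, svg, motifWidth = 6)
  expect_gt(file.size(png), 0)
  expect_match(readLines(svg, n = 2, warn = FALSE)[2], "svg",
               ignore.case = TRUE)
  empty <- buildMorphMatrix(GenomicRanges::GRanges(),
                            mkEct("c1", "+", 1L, 1L))
  expect_error(renderHeatmap(empty, png), "no loci retained")
})
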