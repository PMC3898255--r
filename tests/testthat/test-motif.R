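test_that("IUPAC expansion and matching follow the standard code", {
  expect_setequal(iupacExpand("R")[[1]], c("A", "G"))
  expect_setequal(iupacExpand("TGTAHAKA")[[5]], c("A", "C", "T"))
  expect_setequal(iupacExpand("N")[[1]], c("A", "C", "G", "T"))
  expect_error(iupacExpand("AXC"), "illegal")
  expect_true(iupacMatch("TGTAHAKA", "TGTACATA"))
  expect_false(iupacMatch("TGTAHAKA", "TGTAGATA"))  # G not in H
  expect_true(iupacMatch("NNNN", "ACGT"))
  expect_error(iupacMatch("NNNN", "ACGTT"), "width")
})

test_that("scanSequences equals the brute-force oracle, incl. overlaps", {
  seqs <- c("TTCACACACATT", "GGGGGGGG", "CACACACACA",
            randomWindows(10, 40, seed = 7))
  for (cons in c("CACACACA", "TGTAHAKA", "RTGATGA", "ACGT")) {
    got <- scanSequences(cons, seqs)
    want <- oracleScan(cons, seqs)
    expect_identical(got[c("seq", "start")],
                     want[order(want$seq, want$start), , drop = FALSE],
                     label = cons)
  }
  # self-overlapping run: offsets 3 and 5 (1-based), ZOOPS keeps one
  hits <- scanSequences("CACACACA", "TTCACACACACATT")
  expect_identical(hits$start, c(3L, 5L))
  z <- scanSequences("CACACACA", c("TTCACACACACATT", "CACACACA"),
                     zoops = TRUE)
  expect_equal(nrow(z), 2)
  expect_equal(anyDuplicated(z$seq), 0)
  expect_equal(nrow(scanSequences("TGTACATA", "AAAA")), 0)
})

test_that("window frame conversion places the end at +1 with no zero", {
  # match at window position 26 starts at the uncapped end: offset +1
  expect_equal(windowFrameOffset(26L), 1L)
  expect_equal(windowFrameOffset(28L), 3L)
  expect_equal(windowFrameOffset(25L), -1L)
  expect_equal(windowFrameOffset(1L), -25L)
  expect_equal(windowFrameOffset(18L), -8L)  # 8-mer ending right before +1
})

test_that("positional statistics pick modal offsets with documented ties", {
  expect_equal(positionalStats(rep(3L, 5)),
               list(modalOffset = 3L, positionalDominance = 1.0))
  s <- c(rep(3L, 6), rep(4L, 4), rep(-8L, 2))
  ps <- positionalStats(s)
  expect_equal(ps$modalOffset, 3L)
  expect_equal(ps$positionalDominance, 10 / 12)
  # uniform spread: dominance too low to pass the 50% filter
  u <- positionalStats(c(-5L, -3L, -1L, 1L, 2L, 4L, 6L, 8L, 9L, 10L))
  expect_lte(u$positionalDominance, 0.3)
  # tie between +2 and -2: smaller absolute then negative first
  expect_equal(positionalStats(c(2L, 2L, -2L, -2L))$modalOffset, -2L)
  # +1 neighbours skip the nonexistent zero: -1 and +2 count
  expect_equal(positionalStats(c(1L, 1L, -1L, 2L))$positionalDominance, 1)
  expect_error(positionalStats(integer()), "empty")
})

test_that("discoverAnchored recovers a planted anchored word", {
  word <- "TGTACATA"
  wins <- randomWindows(60, 50, seed = 11)
  wins <- vapply(wins, function(s)
    paste0(substr(s, 1, 27), word, substr(s, 36, 50)), character(1))
  models <- discoverAnchored(wins, widths = 8L, minSites = 5L)
  expect_gt(length(models), 0)
  top <- models[[1]]
  expect_true(iupacMatch(consensusOf(top), word))
  expect_equal(modalOffsetOf(top), 3L)  # window position 28
  expect_equal(positionalDominanceOf(top), 1.0)
  expect_lt(eValueOf(top), 1e-10)
})

test_that("discoverAnchored negative and threshold behaviour", {
  # i.i.d. uniform windows, fixed seed: nothing survives the retention
  # filter (E < 1 together with positional dominance >= 0.5)
  rnd <- randomWindows(60, 50, seed = 5)
  models <- discoverAnchored(rnd, widths = 6:8, minSites = 5L)
  expect_length(filterMotifs(models), 0)
  # a word planted in only 3 of 60 windows is below min_sites
  word <- "GGGCCCGG"
  wins <- rnd
  wins[1:3] <- paste0(substr(wins[1:3], 1, 10), word,
                      substr(wins[1:3], 19, 50))
  m2 <- discoverAnchored(wins, widths = 8L, minSites = 5L)
  expect_false(any(vapply(m2, function(m)
    iupacMatch(paste(consensusOf(m), collapse = ""), word), logical(1))))
  expect_error(discoverAnchored(rnd[1:4], minSites = 5L), "fewer than")
})

test_that("filterMotifs keeps the E and dominance conjunction", {
  mk <- function(e, dom) new("MotifModel", consensus = "ACGTAC",
                             sites = data.frame(), k = 5L, N = 10L,
                             eValue = e, modalOffset = 1L,
                             positionalDominance = dom, provenance = "")
  models <- list(mk(1e-6, 0.9), mk(0.5, 0.3), mk(2, 0.9))
  kept <- filterMotifs(models)
  expect_length(kept, 1)
  expect_equal(eValueOf(kept[[1]]), 1e-6)
  expect_true(all(vapply(kept, function(m) m@eValue < 1, logical(1))))
})

test_that("mergeMotifs groups homologous consensi and partitions input", {
  mk <- function(cons, e = 0.1) new("MotifModel", consensus = cons,
                                    sites = data.frame(), k = 5L, N = 10L,
                                    eValue = e, modalOffset = 5L,
                                    positionalDominance = 1,
                                    provenance = "")
  # C-box length variants from different runs collapse to one group
  trio <- list(mk("RTGATGA"), mk("RATGATGA"), mk("DRTGATGA"))
  groups <- mergeMotifs(trio)
  members <- lapply(groups, function(g)
    vapply(g@members, consensusOf, character(1)))
  expect_length(groups, 1)
  expect_setequal(members[[1]], c("RTGATGA", "RATGATGA", "DRTGATGA"))
  # dissimilar consensi stay apart
  far <- mergeMotifs(list(mk("TGTAHAKA"), mk("AATAAA")))
  expect_length(far, 2)
  # partition: every model in exactly one group
  expect_identical(sort(unlist(members)),
                   sort(vapply(trio, consensusOf, character(1))))
  # representative expansion covers every member word position-wise
  g1 <- groups[[1]]
  expect_true(iupacMatch(g1@representative,
                         gsub("R", "A", gsub("D", "A", "DRTGATGA"))))
  # a single model yields a singleton group representing itself
  solo <- mergeMotifs(list(mk("TGTAHAKA")))
  expect_length(solo, 1)
  expect_identical(solo[[1]]@representative, "TGTAHAKA")
})

test_that("shuffleMotif is a seeded non-identity anagram", {
  s1 <- shuffleMotif("TGTAHAKA", 7)
  s2 <- shuffleMotif("TGTAHAKA", 7)
  expect_identical(s1, s2)
  expect_false(identical(s1, "TGTAHAKA"))
  expect_identical(sort(strsplit(s1, "")[[1]]),
                   sort(strsplit("TGTAHAKA", "")[[1]]))
  expect_error(shuffleMotif("AA", 1), "anagram")
  expect_error(shuffleMotif("A", 1), "width")
  # the draw must not disturb the global RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(shuffleMotif("TGTAHAKA", 9)); after <- runif(1)
  expect_identical(before, after)
})

test_that("importSitesTsv validates the no-zero frame", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sequence_id\toffset\tmatched_word\tconsensus", f)
  expect_equal(nrow(importSitesTsv(f)), 0)
  writeLines(c("sequence_id\toffset\tmatched_word\tconsensus",
               sprintf("s%d\t%d\tTGTACATA\tTGTAHAKA", 1:5,
                       c(3, 3, 4, -8, 3))), f)
  expect_equal(nrow(importSitesTsv(f)), 5)
  writeLines(c("sequence_id\toffset\tmatched_word\tconsensus",
               "s1\t0\tTGTACATA\tTGTAHAKA"), f)
  expect_error(importSitesTsv(f), "no zero")
  writeLines(c("sequence_id\tmatched_word\tconsensus", "s1\tA\tB"), f)
  expect_error(importSitesTsv(f), "missing column")
})
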