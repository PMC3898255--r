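# Handcrafted fixtures built in code at test time.

# A three-gene, multi-isoform annotation on one 1 kb chromosome:
#   geneA (+): two isoforms whose CDS/UTR/intron assignments conflict
#   geneB (-): single isoform with derived UTRs
#   geneC (+): CDS-less transcript antisense-overlapping geneB
tinyGffLines <- function() {
  c("##gff-version 3",
    "c1\ttest\tgene\t101\t400\t.\t+\t.\tID=geneA",
    "c1\ttest\tmRNA\t101\t400\t.\t+\t.\tID=txA1;Parent=geneA",
    "c1\ttest\texon\t101\t200\t.\t+\t.\tParent=txA1",
    "c1\ttest\texon\t251\t400\t.\t+\t.\tParent=txA1",
    "c1\ttest\tCDS\t151\t200\t.\t+\t0\tParent=txA1",
    "c1\ttest\tCDS\t251\t320\t.\t+\t1\tParent=txA1",
    "c1\ttest\tmRNA\t101\t400\t.\t+\t.\tID=txA2;Parent=geneA",
    "c1\ttest\texon\t101\t400\t.\t+\t.\tParent=txA2",
    "c1\ttest\tCDS\t181\t360\t.\t+\t0\tParent=txA2",
    "c1\ttest\tgene\t501\t700\t.\t-\t.\tID=geneB",
    "c1\ttest\tmRNA\t501\t700\t.\t-\t.\tID=txB1;Parent=geneB",
    "c1\ttest\texon\t501\t700\t.\t-\t.\tParent=txB1",
    "c1\ttest\tCDS\t551\t650\t.\t-\t0\tParent=txB1",
    "c1\ttest\tgene\t651\t760\t.\t+\t.\tID=geneC",
    "c1\ttest\tmRNA\t651\t760\t.\t+\t.\tID=txC1;Parent=geneC",
    "c1\ttest\texon\t651\t760\t.\t+\t.\tParent=txC1",
    "c1\ttest\tncRNA\t801\t890\t.\t+\t.\tID=ncX;ncrna_class=CD_box")
}

tinyAnnotation <- function() {
  f <- withr::local_tempfile(fileext = ".gff3",
                             .local_envir = parent.frame())
  writeLines(tinyGffLines(), f)
  readAnnotation(f)
}

# brute-force region oracle over the same fixture, written directly from
# the interval definitions above (independent of the package's parser)
tinyOracleClassify <- function(strand, pos) {
  # per-transcript structures: list(region = list(c(start, end), ...))
  plus <- list(
    txA1 = list(FIVE_UTR = list(c(101, 150)),
                CDS = list(c(151, 200), c(251, 320)),
                THREE_UTR = list(c(321, 400)),
                INTRON = list(c(201, 250))),
    txA2 = list(FIVE_UTR = list(c(101, 180)),
                CDS = list(c(181, 360)),
                THREE_UTR = list(c(361, 400))),
    txC1 = list(CDS = list(c(651, 760))))  # CDS-less exon counts as CDS
  minus <- list(
    txB1 = list(FIVE_UTR = list(c(651, 700)),
                CDS = list(c(551, 650)),
                THREE_UTR = list(c(501, 550))))
  txs <- if (strand == "+") plus else minus
  inAny <- function(region) {
    for (tx in txs) for (iv in tx[[region]] %||% list())
      if (pos >= iv[1] && pos <= iv[2]) return(TRUE)
    FALSE
  }
  for (region in c("CDS", "THREE_UTR", "FIVE_UTR", "INTRON"))
    if (inAny(region)) return(region)
  "IGR"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small genome FASTA: named character vector -> tempfile path
writeTinyFasta <- function(seqs, envir = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".fa", .local_envir = envir)
  writeLines(paste0(">", names(seqs), "\n", seqs), f)
  f
}

# write BED6 read lines; each row one read
writeTinyBed <- function(df, envir = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = envir)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", df$chrom, df$start, df$end,
                     df$name, df$score, df$strand), f)
  f
}

# EndCounts shorthand
mkEct <- function(chrom, strand, pos, count, seqlen = NULL) {
  endCounts(chrom, strand, pos, count, seqlengths = seqlen)
}

# random i.i.d. uniform DNA windows
randomWindows <- function(n, len = 50, seed = 1) {
  withr::with_seed(seed, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1)))
}
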