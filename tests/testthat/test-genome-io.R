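# Readers/writers and the coordinate convention at the I/O boundary:
# BED/narrowPeak are 0-based half-open on disk, GRanges 1-based closed in
# memory; GTF is 1-based closed on both sides.

test_that("BED reading maps 0-based half-open to GRanges and back", {
  p <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t1000\tE1\t500\t+", p)
  x <- readIntervals(p)
  expect_equal(length(x), 1L)
  expect_equal(GenomicRanges::start(x), 1L)
  expect_equal(GenomicRanges::end(x), 1000L)
  expect_equal(as.character(GenomicRanges::strand(x)), "+")
  expect_equal(x$score, 500)
  expect_equal(x$name, "E1")

  # empty file -> empty GRanges
  writeLines(character(0), p)
  expect_equal(length(readIntervals(p)), 0L)

  # unstranded "." becomes "*"
  writeLines("chr2\t10\t20\tx\t1\t.", p)
  expect_equal(as.character(GenomicRanges::strand(readIntervals(p))), "*")
})

test_that("interval round trips preserve order and coordinates exactly", {
  x <- gr(c("chr2", "chr1", "chr1"), c(500L, 1L, 100L),
          c(600L, 50L, 400L), strand = c("+", "-", "*"))
  x$name <- c("b", "a", "c")
  x$score <- c(1, 2, 3)
  p <- tempfile(fileext = ".bed")
  writeIntervals(x, p)
  y <- readIntervals(p)
  expect_equal(as.character(GenomicRanges::seqnames(y)),
               c("chr2", "chr1", "chr1"))
  expect_equal(GenomicRanges::start(y), GenomicRanges::start(x))
  expect_equal(GenomicRanges::end(y), GenomicRanges::end(x))
  expect_equal(y$name, x$name)
  expect_equal(y$score, x$score)
  expect_equal(as.character(GenomicRanges::strand(y)),
               as.character(GenomicRanges::strand(x)))

  # narrowPeak round trip incl. summit; comment headers are skipped
  x$summit_offset <- c(10L, NA, 250L)
  writeIntervals(x, p, format = "narrowPeak", comment = "seed=42")
  z <- readIntervals(p, format = "narrowPeak")
  expect_equal(z$summit_offset, x$summit_offset)
  expect_equal(readLines(p)[1], "# seed=42")

  # empty set -> zero data lines, still readable
  writeIntervals(GenomicRanges::GRanges(), p, format = "narrowPeak",
                 comment = "empty")
  expect_equal(length(readIntervals(p, format = "narrowPeak")), 0L)
})

test_that("narrowPeak summit offsets are validated and parsed", {
  p <- tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t5000\t6000\tpk\t900\t.\t900\t-1\t-1\t499", p)
  x <- readIntervals(p, format = "narrowPeak")
  expect_equal(x$summit_offset, 499L)
  # offset beyond the peak is rejected with the line number
  writeLines("chr1\t5000\t6000\tpk\t900\t.\t900\t-1\t-1\t1000", p)
  expect_error(readIntervals(p, format = "narrowPeak"), "line 1")
})

test_that("malformed interval lines fail with their line number", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10\ta\t1\t+", "chr1\t50\t40\tb\t1\t+"), p)
  expect_error(readIntervals(p), "line 2.*start >= end")
  writeLines("chr1\tzero\t10", p)
  expect_error(readIntervals(p), "non-integer")
})

test_that("GTF exons keep 1-based closed coordinates; TSS follows strand", {
  # + strand single exon at 1001..2000 -> TSS at 1001
  ts <- make_txset(data.frame(tx_id = "t1", gene_id = "g1",
                              chrom = "chr1", start = 1001L, end = 2000L,
                              strand = "+"))
  expect_equal(GenomicRanges::start(tssRanges(ts)), 1001L)
  expect_equal(GenomicRanges::width(transcriptSpans(ts)), 1000L)

  # - strand two-exon transcript -> TSS at the maximum end
  ts2 <- make_txset(data.frame(tx_id = "t2", gene_id = "g2",
                               chrom = "chr1",
                               start = c(5000L, 8000L),
                               end = c(6000L, 9000L), strand = "-"))
  expect_equal(GenomicRanges::start(tssRanges(ts2)), 9000L)

  # strand-inconsistent exons are a parse error
  expect_error(make_txset(data.frame(tx_id = "t3", gene_id = "g3",
                                     chrom = "chr1",
                                     start = c(1L, 100L),
                                     end = c(50L, 200L),
                                     strand = c("+", "-"))),
               "strand-inconsistent")
})

test_that("TSS position matches strand on random exon chains", {
  set.seed(5)
  for (i in 1:20) {
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:4, 1)
    starts <- sort(sample(seq(1, 50000, by = 100), n_ex))
    ends <- starts + sample(50:90, n_ex, replace = TRUE)
    ts <- make_txset(data.frame(tx_id = "t", gene_id = "g",
                                chrom = "chr1", start = starts,
                                end = ends, strand = strand))
    expect_equal(GenomicRanges::start(tssRanges(ts)),
                 if (strand == "+") min(starts) else max(ends))
  }
})

test_that("expression table joins by transcript with replicate means", {
  fp <- data.frame(transcript_id = c("t1", "t1", "ghost"),
                   organ = "liver", replicate = c("r1", "r2", "r1"),
                   fpkm = c(2.0, 0.5, 9))
  expect_warning(
    ts <- make_txset(data.frame(tx_id = "t1", gene_id = "g1",
                                chrom = "chr1", start = 1L, end = 100L,
                                strand = "+"), fp),
    "unknown transcripts")
  expect_equal(unname(meanFpkm(ts, "liver")["t1"]), 1.25)
  # transcript without expression rows -> NA mean
  ts2 <- make_txset(data.frame(tx_id = "t9", gene_id = "g",
                               chrom = "chr1", start = 1L, end = 100L,
                               strand = "+"))
  expect_true(is.na(meanFpkm(ts2, "liver")["t9"]))
})

test_that("FASTA records are uppercased, concatenated, and unique", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">a", "acgt", "ACGT", ">b", "NNNN"), p)
  s <- readSequences(p)
  expect_equal(as.character(s[["a"]]), "ACGTACGT")
  expect_equal(as.character(s[["b"]]), "NNNN")
  writeLines(c(">a", "AC", ">a", "GT"), p)
  expect_error(readSequences(p), "duplicate")
})

test_that("orthology maps validate blocks and round trip via TSV", {
  m <- OrthologyMap(gr("chrA", c(1L, 20001L), c(10000L, 25000L)),
                    gr("chrA2", c(1L, 20101L), c(10000L, 25100L)),
                    orientation = c("+", "-"),
                    sourceAssembly = "A", targetAssembly = "B")
  expect_equal(length(m), 2L)
  p <- tempfile(fileext = ".tsv")
  writeOrthologyMap(m, p, comment = "seed=1")
  m2 <- readOrthologyMap(p)
  expect_equal(GenomicRanges::start(m2@src), GenomicRanges::start(m@src))
  expect_equal(GenomicRanges::end(m2@tgt), GenomicRanges::end(m@tgt))
  expect_equal(m2@orientation, m@orientation)

  # unequal block lengths rejected
  writeLines(c(paste(c("src_chrom", "src_start", "src_end", "tgt_chrom",
                       "tgt_start", "tgt_end", "orientation"),
                     collapse = "\t"),
               "chrA\t0\t100\tchrB\t0\t90\t+"), p)
  expect_error(readOrthologyMap(p), "unequal block lengths")

  # overlapping source blocks rejected
  expect_error(OrthologyMap(gr("chrA", c(1L, 50L), c(100L, 160L)),
                            gr("chrB", c(1L, 50L), c(100L, 160L))),
               "non-overlapping")
})
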