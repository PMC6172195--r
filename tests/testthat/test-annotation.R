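# Promoter/enhancer/inactive annotation rules and their thresholds.

test_that("replicate consensus is summit-centered, 1000 nt, score-ranked", {
  # identical peak in 3/3 replicates at 1-based [5001, 6000], summit
  # offset 499 -> summit base 5500 -> consensus [5000, 5999]
  pk <- peaks_gr("chr1", 5001L, 6000L, score = 900, summit_offset = 499L)
  cons <- harmonizePeakReplicates(list(pk, pk, pk), topN = 100)
  expect_equal(GenomicRanges::start(cons), 5000L)
  expect_equal(GenomicRanges::end(cons), 5999L)
  expect_equal(GenomicRanges::width(cons), 1000L)

  # midpoint centering when the summit is absent
  cons2 <- harmonizePeakReplicates(list(peaks_gr("chr1", 5001L, 6000L)),
                                   topN = 100)
  expect_equal(GenomicRanges::start(cons2), 5001L)

  # peak in 1 of 3 replicates is dropped
  other <- peaks_gr("chr1", 50001L, 51000L, score = 10,
                    summit_offset = 500L)
  cons3 <- harmonizePeakReplicates(list(c(pk, other), pk, pk),
                                   topN = 100)
  expect_equal(length(cons3), 1L)
  expect_equal(GenomicRanges::start(cons3), 5000L)

  # both replicates required when exactly two are given
  cons4 <- harmonizePeakReplicates(list(c(pk, other), pk), topN = 100)
  expect_equal(length(cons4), 1L)

  # topN = 1 with scores 10 > 7 > 3 keeps only the top locus
  reps <- lapply(1:3, function(i)
    peaks_gr("chr1", c(1001L, 2001L, 3001L), c(1200L, 2200L, 3200L),
             score = c(10, 7, 3), summit_offset = 100L))
  cons5 <- harmonizePeakReplicates(reps, topN = 1)
  expect_equal(length(cons5), 1L)
  expect_equal(GenomicRanges::start(cons5), 1101L - 500L)

  # clipping at contig bounds relaxes the length to min(1000, room)
  edge <- peaks_gr("chr1", 1L, 100L, summit_offset = 50L)
  cons6 <- harmonizePeakReplicates(list(edge), topN = 10,
                                   seqlengths = c(chr1 = 600L))
  expect_equal(GenomicRanges::start(cons6), 1L)
  expect_equal(GenomicRanges::end(cons6), 550L)
})

test_that("stability requires mean FPKM > 1 AND span > 1000, strictly", {
  mk <- function(fpkm_vals, span) {
    make_txset(data.frame(tx_id = "t", gene_id = "g", chrom = "chr1",
                          start = 10001L, end = 10000L + span,
                          strand = "+"),
               data.frame(transcript_id = "t", organ = "liver",
                          replicate = paste0("r", seq_along(fpkm_vals)),
                          fpkm = fpkm_vals))
  }
  expect_equal(length(callStableTranscripts(mk(c(1.5, 0.9), 1500),
                                            "liver")), 1L)
  expect_equal(length(callStableTranscripts(mk(c(1.0, 1.0), 1500),
                                            "liver")), 0L)  # mean == 1
  expect_equal(length(callStableTranscripts(mk(c(5, 5), 1000),
                                            "liver")), 0L)  # span == 1000
  expect_warning(callStableTranscripts(mk(c(5, 5), 1500), "kidney"),
                 "absent")
})

test_that("promoter windows sit upstream of the TSS, strand-aware", {
  tsP <- txset_from(stable_tx("p", "chr1", "+", 10001L))
  pr <- definePromoters(callStableTranscripts(tsP, "liver"))
  expect_equal(GenomicRanges::start(pr), 9001L)
  expect_equal(GenomicRanges::end(pr), 10000L)

  tsM <- txset_from(stable_tx("m", "chr1", "-", 20000L))
  prM <- definePromoters(callStableTranscripts(tsM, "liver"))
  expect_equal(GenomicRanges::start(prM), 20001L)
  expect_equal(GenomicRanges::end(prM), 21000L)

  # clipped at the contig start
  tsE <- txset_from(stable_tx("e", "chr1", "+", 301L))
  prE <- definePromoters(callStableTranscripts(tsE, "liver"))
  expect_equal(GenomicRanges::start(prE), 1L)
  expect_equal(GenomicRanges::end(prE), 300L)

  # isoforms sharing a TSS collapse to one promoter
  two <- txset_from(stable_tx("i1", "chr1", "+", 10001L, span = 2000L),
                    stable_tx("i2", "chr1", "+", 10001L, span = 3000L))
  expect_equal(length(definePromoters(
    callStableTranscripts(two, "liver"))), 1L)
})

test_that("enhancer calling applies marks, bivalence and transcript rules", {
  dhs <- gr("chr1", 50001L, 51000L)
  k27 <- gr("chr1", 50501L, 51500L)
  k4me1 <- GenomicRanges::GRanges()
  far_k4me3 <- gr("chr1", 56001L, 57000L)  # 5 kb away
  tx_far <- txset_from(stable_tx("t", "chr1", "+", 80001L))
  cfg <- annotationConfig()

  e <- callEnhancers(dhs, k27, k4me1, far_k4me3, tx_far, config = cfg)
  expect_equal(length(e), 1L)
  expect_equal(e$provenance, "chromatin")

  # DHS without any mark overlap is not an enhancer
  expect_equal(length(callEnhancers(gr("chr1", 1L, 1000L), k27, k4me1,
                                    far_k4me3, tx_far, config = cfg)),
               0L)

  # gap of 999 nt to a K4me3 peak excludes ("closer than 1000")
  k4me3_999 <- gr("chr1", 52000L, 52999L)  # gap = 999
  expect_equal(length(callEnhancers(dhs, k27, k4me1, k4me3_999, tx_far,
                                    config = cfg)), 0L)
  # gap of exactly 1000 retains
  k4me3_1000 <- gr("chr1", 52001L, 53000L)
  expect_equal(length(callEnhancers(dhs, k27, k4me1, k4me3_1000, tx_far,
                                    config = cfg)), 1L)

  # overlap with an exon of an unstable transcript excludes
  tx_un <- make_txset(data.frame(tx_id = "u", gene_id = "g",
                                 chrom = "chr1", start = 50900L,
                                 end = 51400L, strand = "+"))
  expect_equal(length(callEnhancers(dhs, k27, k4me1, far_k4me3, tx_un,
                                    config = cfg)), 0L)

  # overlap with a TSS-upstream window (any transcript) excludes
  tx_up <- make_txset(data.frame(tx_id = "v", gene_id = "g",
                                 chrom = "chr1", start = 51500L,
                                 end = 53000L, strand = "+"))
  expect_equal(length(callEnhancers(dhs, k27, k4me1, far_k4me3, tx_up,
                                    config = cfg)), 0L)

  # CAGE enhancers pass the same filters with their own provenance
  cage <- gr("chr1", 60001L, 60400L)
  e2 <- callEnhancers(dhs, k27, k4me1, far_k4me3, tx_far, cage = cage,
                      config = cfg)
  expect_equal(sort(unique(e2$provenance)), c("CAGE", "chromatin"))

  # output is invariant to input ordering
  dhs2 <- gr("chr1", c(70001L, 50001L), c(71000L, 51000L))
  k27b <- gr("chr1", c(50501L, 70001L), c(51500L, 71000L))
  a <- callEnhancers(dhs2, k27b, k4me1, far_k4me3, tx_far, config = cfg)
  b <- callEnhancers(rev(dhs2), rev(k27b), k4me1, far_k4me3, tx_far,
                     config = cfg)
  expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))
})

test_that("inactive sampling respects exclusion distance and seed", {
  sl <- c(chr1 = 10000L)
  dhs <- gr("chr1", 4001L, 5000L)
  cfg <- annotationConfig()
  r1 <- sampleInactiveRegions(sl, dhs, GenomicRanges::GRanges(),
                              config = cfg, seed = 9, target = 50)
  # nothing within 1000 nt of the DHS: forbidden zone [3001, 6000]
  expect_false(any(IRanges::overlapsAny(r1, gr("chr1", 3001L, 6000L))))
  # non-overlapping 1000-nt intervals
  expect_true(all(GenomicRanges::width(r1) == 1000L))
  expect_equal(length(GenomicRanges::findOverlaps(r1, drop.self = TRUE)),
               0L)
  # determinism
  r2 <- sampleInactiveRegions(sl, dhs, GenomicRanges::GRanges(),
                              config = cfg, seed = 9, target = 50)
  expect_identical(GenomicRanges::start(r1), GenomicRanges::start(r2))
  # fully excluded genome -> empty with warning
  expect_warning(
    r3 <- sampleInactiveRegions(sl, gr("chr1", 1L, 10000L),
                                GenomicRanges::GRanges(), config = cfg,
                                seed = 9, target = 10),
    "no placeable")
  expect_equal(length(r3), 0L)
})

test_that("GC matching pairs nearest inactive regions below threshold", {
  enh <- gr("chr1", c(1L, 1001L, 2001L), c(1000L, 2000L, 3000L))
  enh$gc <- c(0.40, 0.47, 0.40)
  pool <- gr("chr2", seq(1L, 4001L, by = 1000L),
             seq(1000L, 5000L, by = 1000L))
  pool$gc <- c(0.39, 0.45, 0.38, 0.42, 0.30)
  m <- gcMatchedSubsample(enh, pool, annotationConfig(), seed = 1)
  # the 0.47 enhancer is excluded by the 0.46 threshold
  expect_equal(length(m$enhancers), 2L)
  # first 0.40 matches 0.39; second matches the tie at lower GC (0.38,
  # not 0.42, both at distance 0.02 once 0.39 is taken)
  expect_equal(m$inactive$gc, c(0.39, 0.38))
  # matched GC distributions are statistically similar
  set.seed(99)
  enh2 <- gr("chr1", seq(1, 200 * 1000, by = 1000),
             seq(1000, 200 * 1000 + 999, by = 1000))[1:200]
  enh2$gc <- runif(200, 0.30, 0.45)
  pool2 <- gr("chr2", seq(1, 2000 * 1000, by = 1000),
              seq(1000, 2000 * 1000 + 999, by = 1000))[1:2000]
  pool2$gc <- runif(2000, 0.25, 0.50)
  m2 <- gcMatchedSubsample(enh2, pool2, annotationConfig(), seed = 2)
  expect_gt(mannWhitneyU(m2$enhancers$gc, m2$inactive$gc)$p.value, 0.05)
  # pool smaller than the matched set errors
  expect_error(gcMatchedSubsample(enh2, pool2[1:10], annotationConfig(),
                                  seed = 1), "smaller")
})
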