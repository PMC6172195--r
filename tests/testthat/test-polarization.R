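# Outgroup state assignment, ancestral sets, turnover tables and the
# repurposing bias test.

test_that("outgroup states follow the rules with promoter precedence", {
  cfg <- annotationConfig()
  og_tx <- txset_from(stable_tx("ot", "chr1", "+", 50001L))
  og_stable <- callStableTranscripts(og_tx, "liver")
  k27 <- gr("chr1", c(10001L, 49501L), c(11000L, 50500L))
  k4me3 <- GenomicRanges::GRanges()

  # intergenic K27ac -> enhancer
  st <- assignOutgroupState(gr("chr1", 10001L, 11000L), k27, k4me3,
                            og_tx, og_stable, cfg)
  expect_equal(as.character(st), "enhancer")

  # overlap with a stable upstream window -> promoter, even though the
  # same interval also touches a K27ac peak (precedence)
  st2 <- assignOutgroupState(gr("chr1", 49501L, 50000L), k27, k4me3,
                             og_tx, og_stable, cfg)
  expect_equal(as.character(st2), "promoter")

  # K27ac disqualified by a K4me3 overlap -> none
  st3 <- assignOutgroupState(gr("chr1", 10001L, 11000L), k27,
                             gr("chr1", 10501L, 11500L), og_tx,
                             og_stable, cfg)
  expect_equal(as.character(st3), "none")

  # states partition every projected element
  sts <- assignOutgroupState(gr("chr1", c(10001L, 49501L, 90001L),
                                c(11000L, 50000L, 91000L)),
                             k27, k4me3, og_tx, og_stable, cfg)
  expect_false(any(is.na(sts)))
})

test_that("state fractions reproduce printed outgroup percentages", {
  primates <- factor(rep(c("promoter", "enhancer", "none"),
                         c(1, 27, 38)),
                     levels = c("promoter", "enhancer", "none"))
  f <- outgroupStateFractions(primates)
  expect_equal(f$n, 66L)
  expect_equal(f$enhancer_pct, 40.9, tolerance = 0.01)
  expect_equal(f$promoter_pct, 1.5, tolerance = 0.02)
  expect_equal(f$none_pct, 57.6, tolerance = 0.01)
  rodents <- factor(rep(c("promoter", "enhancer", "none"),
                        c(1, 17, 31)),
                    levels = c("promoter", "enhancer", "none"))
  f2 <- outgroupStateFractions(rodents)
  expect_equal(f2$enhancer_pct, 34.7, tolerance = 0.05)
  expect_equal(f2$none_pct, 63.3, tolerance = 0.05)
})

test_that("ancestral sets require clade alignment and outgroup activity", {
  cfg <- annotationConfig()
  m_ab <- identity_map(len = 200000L)
  og_tx <- txset_from(stable_tx("ot", "chr1", "+", 50001L))
  og_stable <- callStableTranscripts(og_tx, "liver")
  og_k27 <- gr("chr1", 10001L, 11000L)
  og_k4me3 <- GenomicRanges::GRanges()

  enh <- gr("chr1", c(10001L, 150001L, 30001L),
            c(11000L, 151000L, 31000L))
  prom <- gr("chr1", c(49501L, 120001L), c(50500L, 121000L))
  # outgroup map missing the region beyond 100 kb -> unaligned elements
  m_ao <- OrthologyMap(gr("chr1", 1L, 100000L), gr("chr1", 1L, 100000L),
                       sourceAssembly = "A", targetAssembly = "O")
  anc <- defineAncestralElements(prom, enh, m_ab, invertMap(m_ab), m_ao,
                                 og_k27, og_k4me3, og_tx, og_stable, cfg)
  # enhancer 1 has outgroup K27ac; enhancer 2 is unmapped in outgroup;
  # enhancer 3 maps but has no outgroup activity
  expect_equal(GenomicRanges::start(anc$enhancers), 10001L)
  # promoter 1 overlaps the outgroup stable 500-nt window; promoter 2
  # is unmapped
  expect_equal(GenomicRanges::start(anc$promoters), 49501L)
})

test_that("turnover tabulation classifies repurposed, lost, conserved", {
  anc <- list(enhancers = gr("chr1", c(1L, 1001L, 2001L),
                             c(1000L, 2000L, 3000L)),
              promoters = gr("chr1", c(5001L, 6001L), c(6000L, 7000L)))
  pe <- gr("chr1", 1L, 1000L)  # overlaps ancestral enhancer 1
  states <- factor("promoter", levels = c("promoter", "enhancer",
                                          "none"))
  tt <- tabulateTurnover(anc, pe, states,
                         enhConservedSister = c(FALSE, TRUE, FALSE),
                         promConservedSister = c(TRUE, FALSE))
  expect_equal(unname(tt$counts["ancestral_enhancer", ]), c(1L, 1L))
  expect_equal(unname(tt$counts["ancestral_promoter", ]), c(1L, 1L))
  expect_equal(unname(tt$totals), c(3L, 2L))
  # conserved = total - repurposed - lost >= 0
  expect_true(all(tt$totals - rowSums(tt$counts) >= 0))
  # empty ancestral sets give an all-zero table
  empty <- tabulateTurnover(list(enhancers = GenomicRanges::GRanges(),
                                 promoters = GenomicRanges::GRanges()),
                            GenomicRanges::GRanges(),
                            factor(character(),
                                   levels = c("promoter", "enhancer",
                                              "none")),
                            logical(0), logical(0))
  expect_true(all(empty$counts == 0))
})

test_that("bias test reproduces printed odds ratios and p-values", {
  primates <- turnoverTable(27, 2655, 1, 1342, ehTotal = 5260,
                            prTotal = 5110)
  r <- repurposingBiasTest(primates)
  expect_equal(r$odds_ratio, (27 * 1342) / (1 * 2655))
  expect_equal(r$odds_ratio, 13.65, tolerance = 0.001)
  expect_lt(r$p_value, 1e-3)
  expect_equal(100 * r$enhancer_loss_rate, 50.5, tolerance = 0.05)
  expect_equal(100 * r$promoter_loss_rate, 26.3, tolerance = 0.05)
  expect_equal(r$loss_rate_ratio, 1.92, tolerance = 0.005)
  expect_equal(r$repurposing_rate_ratio, 26.2, tolerance = 0.05)

  glires <- turnoverTable(17, 1157, 1, 417)
  r2 <- repurposingBiasTest(glires)
  expect_equal(r2$odds_ratio, (17 * 417) / (1 * 1157))
  expect_equal(round(r2$p_value, 3), 0.056)

  even <- repurposingBiasTest(turnoverTable(5, 5, 5, 5))
  expect_equal(even$odds_ratio, 1)
  expect_equal(even$p_value, 1)

  # zero denominator -> +Inf sentinel with a p-value still computed
  inf <- repurposingBiasTest(turnoverTable(5, 5, 0, 5))
  expect_equal(inf$odds_ratio, Inf)
  expect_true(inf$p_value >= 0 && inf$p_value <= 1)
})

test_that("odds ratio equals the cross product and inverts on row swap", {
  set.seed(47)
  for (i in 1:20) {
    a <- sample(1:20, 4)
    tt <- turnoverTable(a[1], a[2], a[3], a[4])
    sw <- turnoverTable(a[3], a[4], a[1], a[2])
    r <- repurposingBiasTest(tt)
    expect_equal(r$odds_ratio, (a[1] * a[4]) / (a[3] * a[2]))
    expect_equal(repurposingBiasTest(sw)$odds_ratio, 1 / r$odds_ratio)
    expect_equal(repurposingBiasTest(sw)$p_value, r$p_value)
  }
})
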