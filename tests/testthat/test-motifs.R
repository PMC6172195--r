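# Motif scanning and the TSS-anchored U1/PAS axis.

test_that("default matrices accept exactly their canonical variants", {
  all_hex <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")),
                                             6)))
  score_words <- function(m) {
    ok <- vapply(all_hex, function(w) {
      b <- strsplit(w, "")[[1]]
      s <- sum(vapply(1:6, function(i) m@matrix[b[i], i], numeric(1)))
      s >= m@threshold
    }, logical(1))
    sort(all_hex[ok])
  }
  expect_equal(score_words(u1Matrix()), c("GTAAGT", "GTGAGT"))
  expect_equal(score_words(pasMatrix()), c("AATAAA", "ATTAAA"))
  # so random-hexamer acceptance is 2/4096 << 1%
})

test_that("planted consensus words are found on both strands", {
  s <- paste0("AAAAAAA", "GTAAGT", "CCCCC", "ACTTAC", "GG")
  h <- scanMotif(s, u1Matrix())
  expect_equal(h$start, c(8L, 19L))
  expect_equal(h$strand, c("+", "-"))
  p <- scanMotif(paste0("TT", "AATAAA", "A", "TTTATT", "C"), pasMatrix())
  expect_equal(p$start[p$strand == "+"], 3L)
  expect_equal(p$start[p$strand == "-"], 10L)
})

test_that("scanner equals the brute-force all-offset scorer", {
  set.seed(71)
  for (i in 1:15) {
    s <- random_seq(2000, gc = runif(1, 0.3, 0.6))
    for (m in list(u1Matrix(), pasMatrix())) {
      a <- scanMotif(s, m)
      b <- brute_force_scan(s, m)
      expect_equal(a$start, b$start)
      expect_equal(a$strand, b$strand)
      expect_equal(a$score, b$score, tolerance = 1e-6)
    }
  }
})

test_that("motif matrix text files round trip", {
  p <- tempfile(fileext = ".pwm")
  writeMotifMatrix(u1Matrix(), p)
  m <- readMotifMatrix(p)
  expect_equal(m@name, "U1")
  expect_equal(m@matrix, u1Matrix()@matrix, tolerance = 1e-9)
  expect_equal(m@threshold, u1Matrix()@threshold, tolerance = 1e-9)
})

test_that("TSS density profiles count sense-oriented windows per kb", {
  hits <- data.frame(start = c(5100L, 5400L, 5900L),
                     end = c(5105L, 5405L, 5905L),
                     strand = "+", score = 1)
  prof <- tssDensityProfile(5000L, "+", hits)
  expect_equal(prof$down[prof$window == 1000], 3.0)
  expect_equal(prof$up[prof$window == 1000], 0.0)
  # window membership: a hit 100 nt downstream sits in both the 200-nt
  # and the 1000-nt window (densities per kb scale accordingly)
  one <- tssDensityProfile(5000L, "+", hits[1, ],
                           windows = c(200, 1000))
  expect_equal(one$down, c(5.0, 1.0))
  # minus-strand TSS mirrors the same counts (hits at -100/-400/-900,
  # anchored at the hit end read in the sense direction)
  hits_m <- data.frame(start = c(3895L, 4395L, 4695L),
                       end = c(3900L, 4400L, 4700L),
                       strand = "+", score = 1)
  prof_m <- tssDensityProfile(4800L, "-", hits_m)
  expect_equal(prof_m$down[prof_m$window == 1000], 3.0)
  expect_equal(prof_m$up[prof_m$window == 1000], 0.0)
  # contig-edge truncation uses the effective length
  tr <- tssDensityProfile(300L, "+", hits[0, ], windows = 1000,
                          contigLength = 800)
  expect_equal(tr$down, 0 / (501 / 1000))
  expect_equal(tr$up, 0)
})

test_that("window counts are additive over disjoint windows", {
  set.seed(77)
  hits <- data.frame(start = sample(1:10000, 60))
  hits$end <- hits$start + 5L
  for (tss in c(3000L, 7000L)) {
    prof <- tssDensityProfile(tss, "+", hits)
    counts <- prof$down * prof$window / 1000
    expect_equal(counts[5],
                 sum(hits$start >= tss & hits$start < tss + 1000))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("densities are invariant under reverse complement", {
  set.seed(79)
  s <- random_seq(4000)
  tss <- 2000L
  m <- u1Matrix()
  h <- scanMotif(s, m)
  prof_f <- tssDensityProfile(tss, "+", h, contigLength = 4000)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h_rc <- scanMotif(rc, m)
  prof_r <- tssDensityProfile(4000L - tss + 1L, "-", h_rc,
                              contigLength = 4000)
  expect_equal(prof_f$down, prof_r$down)
  expect_equal(prof_f$up, prof_r$up)
})

test_that("closest motif distance is side-aware with TSS inclusion", {
  hits <- data.frame(start = c(5120L, 4700L), end = c(5125L, 4705L))
  expect_equal(closestMotifDistance(5000L, "+", hits, "down"), 120)
  expect_equal(closestMotifDistance(5000L, "+", hits, "up"), 300)
  expect_true(is.na(closestMotifDistance(5000L, "+",
                                         hits[hits$start < 5000, ],
                                         "down")))
  at_tss <- data.frame(start = 5000L, end = 5005L)
  expect_equal(closestMotifDistance(5000L, "+", at_tss, "down"), 0)
})

test_that("U1-before-PAS ordering fraction follows its denominator rule", {
  u1 <- data.frame(seq_name = "c", start = c(1050L, 3200L),
                   end = c(1055L, 3205L), strand = "+", score = 1)
  pas <- data.frame(seq_name = "c", start = c(1200L, 3050L),
                    end = c(1205L, 3055L), strand = "+", score = 1)
  tss <- data.frame(seq_name = "c", pos = c(1000L, 3000L), strand = "+")
  r <- u1BeforePasFraction(tss, u1, pas)
  expect_equal(r$n_evaluated, 2L)
  expect_equal(r$fraction, 0.5)  # U1 first at 1000; PAS first at 3000
  # U1 but no PAS counts as success; neither -> excluded
  r2 <- u1BeforePasFraction(data.frame(seq_name = "c", pos = 1000L,
                                       strand = "+"),
                            u1, pas[0, ])
  expect_equal(r2$fraction, 1)
  r3 <- u1BeforePasFraction(data.frame(seq_name = "c", pos = 900000L,
                                       strand = "+"), u1, pas)
  expect_equal(r3$n_evaluated, 0L)
  expect_true(is.na(r3$fraction))
  # duplicating a hit never changes the fraction
  r4 <- u1BeforePasFraction(tss, rbind(u1, u1[1, ]), pas)
  expect_equal(r4$fraction, r$fraction)
})

test_that("species comparison tests each window with BH correction", {
  mk_prof <- function(vals) {
    data.frame(window = c(200, 400, 600, 800, 1000), up = vals,
               down = vals)
  }
  a <- list(e1 = mk_prof(rep(1, 5)), e2 = mk_prof(rep(2, 5)))
  same <- compareAxisBetweenSpecies(a, a, paired = TRUE)
  expect_true(all(same$p_adj == 1))
  expect_error(compareAxisBetweenSpecies(a, list(zz = a[[1]],
                                                 e1 = a[[2]]),
                                         paired = TRUE), "matching")
  expect_warning(compareAxisBetweenSpecies(a[1], a[1]), "skipped")
})

test_that("planted downstream asymmetry is detected, upstream is not", {
  set.seed(83)
  mk <- function(down_rate, up_rate) {
    data.frame(window = c(200, 400, 600, 800, 1000),
               up = rpois(5, up_rate) / c(0.2, 0.4, 0.6, 0.8, 1),
               down = rpois(5, down_rate * c(0.2, 0.4, 0.6, 0.8, 1)) /
                 c(0.2, 0.4, 0.6, 0.8, 1))
  }
  ids <- paste0("e", 1:100)
  pa <- setNames(lapply(1:100, function(i) mk(2.0, 1.0)), ids)
  pb <- setNames(lapply(1:100, function(i) mk(3.0, 1.0)), ids)
  r <- compareAxisBetweenSpecies(pa, pb, paired = TRUE)
  expect_true(all(r$p_adj[r$side == "down" & r$window >= 600] < 0.01))
  expect_true(all(r$p[r$side == "up"] > 0.05))
})
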