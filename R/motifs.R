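## U1 / PAS motif scanning and TSS-anchored density, distance and ordering
## analyses. Scanning runs both strands of the forward coordinate system;
## hit strand is ignored when counting around a TSS (the sense/antisense
## contrast comes from which side of the TSS is measured), matching the
## up/downstream framing of the density analyses.

.pwm_from_probs <- function(probs, name, accept) {
  lo <- log2(probs / 0.25)
  score1 <- function(word) {
    b <- strsplit(word, "")[[1]]
    sum(vapply(seq_along(b), function(i) lo[b[i], i], numeric(1)))
  }
  thr <- min(vapply(accept, score1, numeric(1)))
  new("MotifMatrix", name = name, matrix = lo, threshold = thr - 1e-9)
}

#' Default U1 splice-donor motif matrix
#'
#' Log2-odds matrix over the 6-mer donor core with the invariant GT at
#' positions 1-2 and standard flanking preferences; the threshold accepts
#' the canonical \code{GTAAGT} and its main \code{GTGAGT} variant and
#' rejects all other hexamers (2/4096 random acceptance).
#'
#' @return a \code{\linkS4class{MotifMatrix}}.
#' @export
u1Matrix <- function() {
  probs <- matrix(0.05, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("G", "T", "A", "A", "G", "T")
  for (i in 1:6) probs[cons[i], i] <- 0.85
  probs["A", 3] <- 0.45
  probs["G", 3] <- 0.45
  probs["C", 3] <- 0.05
  probs["T", 3] <- 0.05
  .pwm_from_probs(probs, "U1", c("GTAAGT", "GTGAGT"))
}

#' Default polyadenylation-signal motif matrix
#'
#' Centered on \code{AATAAA} with \code{ATTAAA} as the accepted main
#' variant; all other hexamers score below threshold.
#'
#' @return a \code{\linkS4class{MotifMatrix}}.
#' @export
pasMatrix <- function() {
  probs <- matrix(1 / 30, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- c("A", "A", "T", "A", "A", "A")
  for (i in 1:6) probs[cons[i], i] <- 0.9
  probs["A", 2] <- 0.55
  probs["T", 2] <- 0.40
  probs["C", 2] <- 0.025
  probs["G", 2] <- 0.025
  .pwm_from_probs(probs, "PAS", c("AATAAA", "ATTAAA"))
}

#' Read / write a position-weight matrix text file
#'
#' Format: a header line \code{# name=<name> threshold=<value>} followed by
#' four tab-separated rows (A, C, G, T) of per-position log2-odds weights.
#'
#' @param path file path.
#' @return a \code{\linkS4class{MotifMatrix}}.
#' @export
readMotifMatrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)][1]
  name <- sub(".*name=(\\S+).*", "\\1", hdr)
  thr <- as.numeric(sub(".*threshold=(\\S+).*", "\\1", hdr))
  rows <- lines[!grepl("^#", lines) & nzchar(lines)]
  stopifnot(length(rows) == 4)
  m <- do.call(rbind, lapply(rows, function(l)
    as.numeric(strsplit(l, "\t")[[1]])))
  rownames(m) <- c("A", "C", "G", "T")
  new("MotifMatrix", name = name, matrix = m, threshold = thr)
}

#' @rdname readMotifMatrix
#' @param m a \code{\linkS4class{MotifMatrix}} to write.
#' @export
writeMotifMatrix <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("# name=%s threshold=%.10g", m@name, m@threshold),
             con, sep = "\n")
  for (r in 1:4)
    writeLines(paste(sprintf("%.10g", m@matrix[r, ]), collapse = "\t"),
               con, sep = "\n")
  invisible(path)
}

.revcomp_matrix <- function(m) {
  out <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  out
}

.scan_one_strand <- function(subject, lo, threshold) {
  hits <- Biostrings::matchPWM(lo, subject, min.score = threshold,
                               with.score = TRUE)
  data.frame(start = BiocGenerics::start(hits),
             score = S4Vectors::mcols(hits)$score)
}

#' Scan a sequence with a motif matrix on both strands
#'
#' A hit is any window whose log2-odds score reaches the matrix threshold,
#' on either strand; positions are reported on the forward coordinate
#' system (1-based start of the window).
#'
#' @param sequence \code{DNAString} or single character string.
#' @param matrix a \code{\linkS4class{MotifMatrix}}.
#' @return data.frame with columns \code{start}, \code{strand},
#'   \code{score}, sorted by start.
#' @export
scanMotif <- function(sequence, matrix) {
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  stopifnot(length(sequence) >= ncol(matrix@matrix))
  fwd <- .scan_one_strand(sequence, matrix@matrix, matrix@threshold)
  rev <- .scan_one_strand(sequence, .revcomp_matrix(matrix@matrix),
                          matrix@threshold)
  L <- ncol(matrix@matrix)
  out <- rbind(
    if (nrow(fwd)) data.frame(start = fwd$start, end = fwd$start + L - 1L,
                              strand = "+", score = fwd$score) else NULL,
    if (nrow(rev)) data.frame(start = rev$start, end = rev$start + L - 1L,
                              strand = "-", score = rev$score) else NULL)
  if (is.null(out))
    out <- data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric())
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a genome (all contigs) with a motif matrix
#'
#' @param genome named \code{DNAStringSet}.
#' @param matrix a \code{\linkS4class{MotifMatrix}}.
#' @return data.frame with columns \code{seq_name}, \code{start},
#'   \code{strand}, \code{score}.
#' @export
scanMotifSet <- function(genome, matrix) {
  out <- lapply(names(genome), function(nm) {
    h <- scanMotif(genome[[nm]], matrix)
    if (nrow(h)) cbind(seq_name = nm, h) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(seq_name = character(), start = integer(),
                      strand = character(), score = numeric())
  rownames(out) <- NULL
  out
}

.signed_dist <- function(tssPos, tssStrand, hits) {
  # >= 0 downstream (sense direction), < 0 upstream; hit at TSS is
  # downstream at distance 0. The anchor is the first hit base read in
  # the sense direction (start on +, end on -), which makes densities
  # invariant under reverse-complementing the contig.
  if (tssStrand == "-") tssPos - hits$end else hits$start - tssPos
}

#' TSS-anchored motif density profile
#'
#' Counts motif hit starts in sense-oriented windows up- and downstream of
#' a TSS and converts them to densities per kb. Windows truncated by a
#' contig edge use the effective (truncated) length in the denominator.
#' Hit strand is ignored.
#'
#' @param tssPos 1-based TSS position.
#' @param tssStrand \code{"+"} or \code{"-"}.
#' @param hits data.frame from \code{\link{scanMotif}} /
#'   \code{\link{scanMotifSet}} restricted to the TSS's contig.
#' @param windows window lengths in nt (default 200/400/600/800/1000).
#' @param contigLength contig length for edge truncation (default
#'   \code{Inf}, no truncation).
#' @return data.frame with one row per window: \code{window}, \code{up},
#'   \code{down} (densities per kb).
#' @export
tssDensityProfile <- function(tssPos, tssStrand, hits,
                              windows = c(200, 400, 600, 800, 1000),
                              contigLength = Inf) {
  d <- .signed_dist(tssPos, tssStrand, hits)
  # genomic room available on each sense side
  down_room <- if (tssStrand == "-") tssPos else contigLength - tssPos + 1
  up_room <- if (tssStrand == "-") contigLength - tssPos else tssPos - 1
  out <- data.frame(window = windows, up = NA_real_, down = NA_real_)
  for (i in seq_along(windows)) {
    w <- windows[i]
    wd <- min(w, down_room)
    wu <- min(w, up_room)
    out$down[i] <- if (wd > 0) sum(d >= 0 & d < wd) / (wd / 1000) else NA
    out$up[i] <- if (wu > 0) sum(d < 0 & d >= -wu) / (wu / 1000) else NA
  }
  out
}

#' Distance from a TSS to the closest motif hit
#'
#' @param tssPos,tssStrand TSS position and strand.
#' @param hits data.frame of hits on the TSS's contig.
#' @param direction \code{"down"} (sense-downstream; a hit exactly at the
#'   TSS counts here at distance 0) or \code{"up"}.
#' @return non-negative distance in nt, or \code{NA} when no hit lies on
#'   that side.
#' @export
closestMotifDistance <- function(tssPos, tssStrand, hits,
                                 direction = c("down", "up")) {
  direction <- match.arg(direction)
  d <- .signed_dist(tssPos, tssStrand, hits)
  side <- if (direction == "down") d[d >= 0] else -d[d < 0]
  if (!length(side)) NA_real_ else min(side)
}

#' Fraction of TSSs whose first downstream U1 precedes the first PAS
#'
#' For each TSS with at least one downstream U1 or PAS hit within
#' \code{window}: success when a downstream U1 exists strictly closer than
#' any downstream PAS (a TSS with U1 but no PAS counts as success); TSSs
#' with neither motif are excluded from the denominator.
#'
#' @param tss data.frame with columns \code{seq_name}, \code{pos},
#'   \code{strand}.
#' @param u1Hits,pasHits hit tables from \code{\link{scanMotifSet}}.
#' @param window downstream window in nt (default 1000).
#' @return list with \code{fraction} (NA when nothing evaluated) and
#'   \code{n_evaluated}.
#' @export
u1BeforePasFraction <- function(tss, u1Hits, pasHits, window = 1000) {
  succ <- 0L
  n <- 0L
  for (i in seq_len(nrow(tss))) {
    u1 <- u1Hits[u1Hits$seq_name == tss$seq_name[i], , drop = FALSE]
    pas <- pasHits[pasHits$seq_name == tss$seq_name[i], , drop = FALSE]
    du <- closestMotifDistance(tss$pos[i], tss$strand[i], u1, "down")
    dp <- closestMotifDistance(tss$pos[i], tss$strand[i], pas, "down")
    if (!is.na(du) && du >= window) du <- NA
    if (!is.na(dp) && dp >= window) dp <- NA
    if (is.na(du) && is.na(dp)) next
    n <- n + 1L
    if (!is.na(du) && (is.na(dp) || du < dp)) succ <- succ + 1L
  }
  list(fraction = if (n > 0) succ / n else NA_real_, n_evaluated = n)
}

#' Compare TSS-anchored density profiles between species
#'
#' Per window and side, paired profiles are compared with a Wilcoxon
#' signed-rank test (unpaired with Mann-Whitney), Benjamini-Hochberg
#' corrected across the window family within each side (up- and
#' downstream regions are distinct hypotheses about different sequence,
#' so each side forms its own family of cumulative windows). Means and
#' normal 95% confidence half-widths of each species' cumulative curves
#' are reported.
#'
#' @param profilesA,profilesB named lists of per-element data.frames from
#'   \code{\link{tssDensityProfile}}; in paired mode the names (element
#'   ids) must match.
#' @param paired logical; paired comparison of orthologous elements.
#' @return data.frame: \code{side}, \code{window}, \code{mean_a},
#'   \code{mean_b}, \code{ci_a}, \code{ci_b}, \code{statistic}, \code{p},
#'   \code{p_adj}.
#' @export
compareAxisBetweenSpecies <- function(profilesA, profilesB,
                                      paired = TRUE) {
  if (paired) {
    if (!identical(sort(names(profilesA)), sort(names(profilesB))))
      stop("paired mode requires matching element ids")
    profilesB <- profilesB[names(profilesA)]
  }
  if (length(profilesA) < 2 || length(profilesB) < 2) {
    warning("fewer than 2 element(s); comparison skipped")
    return(data.frame())
  }
  windows <- profilesA[[1]]$window
  grid <- expand.grid(side = c("up", "down"), window = windows,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    wi <- match(grid$window[k], windows)
    va <- vapply(profilesA, function(p) p[[grid$side[k]]][wi], numeric(1))
    vb <- vapply(profilesB, function(p) p[[grid$side[k]]][wi], numeric(1))
    ok <- !is.na(va) & !is.na(vb)
    va <- va[ok]; vb <- vb[ok]
    tt <- if (paired) {
      if (all(vb - va == 0))
        suppressWarnings(wilcoxonSignedRank(vb - va))
      else wilcoxonSignedRank(vb - va)
    } else mannWhitneyU(va, vb)
    data.frame(side = grid$side[k], window = grid$window[k],
               mean_a = mean(va), mean_b = mean(vb),
               ci_a = 1.96 * stats::sd(va) / sqrt(length(va)),
               ci_b = 1.96 * stats::sd(vb) / sqrt(length(vb)),
               statistic = tt$statistic, p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  for (sd_ in unique(out$side))
    out$p_adj[out$side == sd_] <- bhAdjust(out$p[out$side == sd_])
  out
}
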