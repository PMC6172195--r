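## GC / CpG metrics and the orthologous-shift resampling test.
##
## GC content excludes N from the denominator. CpG frequency counts CG
## dinucleotides over dinucleotide positions (length - 1); windows
## containing N never count as CG, and a strict mode also removes
## N-containing windows from the denominator.

.as_char_seqs <- function(x) {
  if (is(x, "XStringSet") || is(x, "XString")) x <- as.character(x)
  toupper(x)
}

#' GC content of sequences
#'
#' \code{(#G + #C) / (#A + #C + #G + #T)}; N bases are excluded from the
#' denominator. Sequences with no informative bases give \code{NA}.
#'
#' @param x character vector, \code{DNAString} or \code{DNAStringSet}.
#' @return numeric vector in [0, 1] (or \code{NA}).
#' @examples
#' gcContent(c("GCGC", "ACGT", "ANGT"))
#' @export
gcContent <- function(x) {
  s <- Biostrings::DNAStringSet(.as_char_seqs(x))
  f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  inf <- rowSums(f)
  out <- unname((f[, "G"] + f[, "C"]) / inf)
  out[inf == 0] <- NA_real_
  out
}

#' CpG dinucleotide frequency
#'
#' Count of CG occurrences divided by the number of dinucleotide positions
#' (\code{length - 1}). With \code{strict = TRUE}, windows containing an N
#' are also removed from the denominator.
#'
#' @param x character vector, \code{DNAString} or \code{DNAStringSet}.
#' @param strict exclude N-containing dinucleotide windows from the
#'   denominator.
#' @return numeric vector; \code{NA} for sequences shorter than 2 (or with
#'   no informative windows in strict mode).
#' @examples
#' cpgFrequency(c("CGCG", "GCGC", "AAAA"))
#' @export
cpgFrequency <- function(x, strict = FALSE) {
  s <- Biostrings::DNAStringSet(.as_char_seqs(x))
  L <- Biostrings::width(s)
  cg <- Biostrings::vcountPattern("CG", s)
  den <- L - 1
  if (strict) {
    # windows containing N = (#N excluding last base) + (#N excluding
    # first base) - (#NN pairs)
    nn <- Biostrings::vcountPattern("NN", s)
    n_all <- Biostrings::letterFrequency(s, "N")[, 1]
    lastN <- as.integer(Biostrings::subseq(s, start = L, end = L) ==
                        Biostrings::DNAStringSet(rep("N", length(s))))
    firstN <- as.integer(Biostrings::subseq(s, start = 1, end = 1) ==
                         Biostrings::DNAStringSet(rep("N", length(s))))
    den <- den - ((n_all - lastN) + (n_all - firstN) - nn)
  }
  out <- unname(cg / den)
  out[L < 2 | den <= 0] <- NA_real_
  out
}

#' Extract element sequences from a genome
#'
#' @param genome named \code{DNAStringSet}.
#' @param gr \code{GRanges} on that genome.
#' @return \code{DNAStringSet} of the element sequences (forward strand).
#' @export
elementSequences <- function(genome, gr) {
  stopifnot(all(as.character(GenomicRanges::seqnames(gr)) %in%
                names(genome)))
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(
      genome[[as.character(GenomicRanges::seqnames(gr))[i]]],
      start = GenomicRanges::start(gr)[i],
      end = GenomicRanges::end(gr)[i]))
  }, character(1)))
  names(out) <- if (!is.null(names(gr))) names(gr) else
    paste0(GenomicRanges::seqnames(gr), ":",
           GenomicRanges::start(gr), "-", GenomicRanges::end(gr))
  out
}

#' Pairwise class comparison of a composition metric
#'
#' All pairwise two-sided Mann-Whitney tests between element classes, with
#' Benjamini-Hochberg correction across the pair family. Classes with
#' fewer than 2 values are skipped with a warning.
#'
#' @param valuesByClass named list of numeric vectors (e.g. GC or CpG per
#'   element, one vector per regulatory class).
#' @return data.frame with columns \code{class1, class2, U, p, p_adj}.
#' @export
compareCompositionClasses <- function(valuesByClass) {
  stopifnot(length(valuesByClass) >= 2, !is.null(names(valuesByClass)))
  valuesByClass <- lapply(valuesByClass, function(v) v[!is.na(v)])
  sizes <- lengths(valuesByClass)
  if (any(sizes < 2))
    warning("class(es) with < 2 records skipped: ",
            paste(names(valuesByClass)[sizes < 2], collapse = ", "))
  pairs <- utils::combn(names(valuesByClass), 2)
  keep <- sizes[pairs[1, ]] >= 2 & sizes[pairs[2, ]] >= 2
  pairs <- pairs[, keep, drop = FALSE]
  out <- data.frame(class1 = pairs[1, ], class2 = pairs[2, ],
                    U = NA_real_, p = NA_real_)
  for (k in seq_len(ncol(pairs))) {
    r <- mannWhitneyU(valuesByClass[[pairs[1, k]]],
                      valuesByClass[[pairs[2, k]]])
    out$U[k] <- r$statistic
    out$p[k] <- r$p.value
  }
  out$p_adj <- bhAdjust(out$p)
  out
}

#' Orthologous composition-shift resampling test
#'
#' Tests whether the mean cross-species composition change at P/E pairs
#' exceeds genome-wide drift, by resampling the same number of orthologous
#' inactive-region pairs and recomputing the mean difference. The empirical
#' p uses the add-one estimator \eqn{(1 + \#\{null \ge obs\}) / (n + 1)}
#' (one-sided "greater" by default), so it can never be exactly zero. A
#' Wilcoxon signed-rank test on the P/E differences is reported alongside.
#'
#' @param pePairs two-column matrix/data.frame of (a_value, b_value) per
#'   P/E element (a = enhancer species, b = promoter species).
#' @param inactivePairs same shape, for orthologous inactive regions; must
#'   have more rows than \code{pePairs}.
#' @param nResamples number of resamples (default 10000; fewer than 100
#'   warns).
#' @param seed integer seed for the resampler.
#' @param alternative \code{"greater"} (default), \code{"less"} or
#'   \code{"two.sided"} (doubled one-sided p, capped at 1).
#' @return list of class \code{shiftTestResult}: \code{observed_mean_diff},
#'   \code{null_means}, \code{empirical_p}, \code{wilcoxon}
#'   (\code{repTestResult}).
#' @export
orthologShiftResamplingTest <- function(pePairs, inactivePairs,
                                        nResamples = 10000, seed = 1,
                                        alternative = c("greater", "less",
                                                        "two.sided")) {
  alternative <- match.arg(alternative)
  pe <- as.matrix(pePairs)
  bg <- as.matrix(inactivePairs)
  stopifnot(ncol(pe) == 2, ncol(bg) == 2)
  if (nrow(bg) <= nrow(pe))
    stop("inactive pool must be larger than the P/E set")
  if (nResamples < 100) warning("fewer than 100 resamples")
  obs <- mean(pe[, 2] - pe[, 1])
  d_bg <- bg[, 2] - bg[, 1]
  set.seed(seed)
  null_means <- vapply(seq_len(nResamples), function(i)
    mean(d_bg[sample.int(length(d_bg), nrow(pe))]), numeric(1))
  p1_greater <- (1 + sum(null_means >= obs)) / (nResamples + 1)
  p1_less <- (1 + sum(null_means <= obs)) / (nResamples + 1)
  p <- switch(alternative,
              greater = p1_greater,
              less = p1_less,
              two.sided = min(1, 2 * min(p1_greater, p1_less)))
  structure(list(observed_mean_diff = obs,
                 null_means = null_means,
                 empirical_p = p,
                 alternative = alternative,
                 wilcoxon = wilcoxonSignedRank(pe[, 2] - pe[, 1])),
            class = "shiftTestResult")
}

#' @export
print.shiftTestResult <- function(x, ...) {
  cat("Orthologous composition-shift resampling test (",
      x$alternative, ")\n", sep = "")
  cat("  observed mean difference:", format(x$observed_mean_diff,
                                            digits = 4), "\n")
  cat("  null mean +/- sd: ", format(mean(x$null_means), digits = 4),
      " +/- ", format(stats::sd(x$null_means), digits = 4), "\n", sep = "")
  cat("  empirical p:", format(x$empirical_p, digits = 4), "\n")
  invisible(x)
}
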