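## Statistical kernel used throughout the pipeline. The heavy lifting is
## delegated to the classical base-R implementations (fisher.test,
## wilcox.test, p.adjust); this module fixes the conventions the analysis
## depends on: two-sided Fisher p by point-probability summation, the
## unconditional cross-product odds ratio, exact rank-test paths at small
## n without ties, and Wilcoxon zero-dropping.

.test_result <- function(statistic, p, method, n, ...) {
  structure(list(statistic = unname(statistic), p.value = unname(p),
                 method = method, n = n, ...),
            class = "repTestResult")
}

#' @export
print.repTestResult <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic, digits = 4),
      ", p = ", format(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The p-value is the sum of hypergeometric point probabilities at most as
#' large as the observed one (the conventional two-sided definition). The
#' odds ratio is the unconditional cross-product ratio
#' \eqn{(a d)/(b c)}, reported as \code{Inf} when a cross term is zero in
#' the denominator.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return a \code{repTestResult} with elements \code{odds.ratio},
#'   \code{p.value}.
#' @examples
#' fisherExact2x2(matrix(c(27, 1, 2655, 1342), nrow = 2))
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (sum(tab) == 0) stop("all-zero table")
  p <- stats::fisher.test(tab)$p.value
  den <- tab[1, 2] * tab[2, 1]
  or <- if (den == 0) Inf else (tab[1, 1] * tab[2, 2]) / den
  .test_result(or, p, "Fisher's exact test (two-sided)",
               n = sum(tab), odds.ratio = or)
}

#' Mann-Whitney U test
#'
#' Exact two-sided p by enumeration when \code{length(x) + length(y) <= 12}
#' and there are no ties; normal approximation with tie and continuity
#' correction otherwise. The statistic is the U of the first sample.
#'
#' @param x,y numeric samples.
#' @param alternative \code{"two.sided"} (default), \code{"less"} or
#'   \code{"greater"}.
#' @return a \code{repTestResult}.
#' @export
mannWhitneyU <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  res <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE))
  .test_result(res$statistic, res$p.value,
               if (exact) "Mann-Whitney U (exact)"
               else "Mann-Whitney U (normal approximation)",
               n = c(length(x), length(y)))
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (Wilcoxon's original treatment). Exact
#' two-sided p by sign enumeration when at most 12 non-zero differences and
#' no tied magnitudes; normal approximation with continuity correction
#' otherwise.
#'
#' @param diffs numeric vector of paired differences.
#' @param alternative test direction.
#' @return a \code{repTestResult}; all-zero input gives p = 1 with a
#'   warning.
#' @export
wilcoxonSignedRank <- function(diffs, alternative = "two.sided") {
  stopifnot(length(diffs) > 0)
  nz <- diffs[diffs != 0]
  if (!length(nz)) {
    warning("all differences are zero")
    return(.test_result(0, 1, "Wilcoxon signed-rank", n = length(diffs)))
  }
  ties <- anyDuplicated(abs(nz)) > 0
  exact <- length(nz) <= 12 && !ties
  res <- suppressWarnings(stats::wilcox.test(
    nz, alternative = alternative, exact = exact, correct = TRUE))
  .test_result(res$statistic, res$p.value,
               if (exact) "Wilcoxon signed-rank (exact)"
               else "Wilcoxon signed-rank (normal approximation)",
               n = length(nz))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, capped at 1, input order preserved.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Input-normalized signal comparison between element classes
#'
#' Per element, computes \code{log2((chip + pseudocount) /
#' (input + pseudocount))}; classes are then compared with all pairwise
#' two-sided Mann-Whitney tests, Benjamini-Hochberg corrected across the
#' pair family. This is the ChIP-vs-input contrast used to compare, e.g.,
#' H3K4me3 levels across promoter/enhancer/P/E classes.
#'
#' @param signalByClass named list; each element a two-column matrix or
#'   data.frame of (chip mean coverage, input mean coverage) per element.
#' @param pseudocount added to both numerator and denominator (default 1).
#' @return list with \code{ratios} (named list of per-element log2 ratios)
#'   and \code{tests} (data.frame: class1, class2, U, p, p_adj).
#' @export
normalizedSignalCompare <- function(signalByClass, pseudocount = 1) {
  stopifnot(length(signalByClass) >= 1, !is.null(names(signalByClass)))
  ratios <- lapply(signalByClass, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 2, all(m >= 0))
    log2((m[, 1] + pseudocount) / (m[, 2] + pseudocount))
  })
  cls <- names(ratios)
  tests <- NULL
  if (length(cls) >= 2) {
    pairs <- utils::combn(cls, 2)
    tests <- data.frame(class1 = pairs[1, ], class2 = pairs[2, ],
                        U = NA_real_, p = NA_real_)
    for (k in seq_len(ncol(pairs))) {
      r <- mannWhitneyU(ratios[[pairs[1, k]]], ratios[[pairs[2, k]]])
      tests$U[k] <- r$statistic
      tests$p[k] <- r$p.value
    }
    tests$p_adj <- bhAdjust(tests$p)
  }
  list(ratios = ratios, tests = tests)
}
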