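## Outgroup-based polarization of repurposing events: assign an ancestral
## regulatory state to each P/E ortholog, build ancestral element sets,
## and quantify repurposing vs loss in a 2x2 turnover table.
##
## Outgroup state rules (promoter takes precedence over enhancer):
##   promoter: overlap with the 1000 nt upstream of a stable transcript;
##   enhancer: overlap with an H3K27ac peak that itself overlaps no
##     H3K4me3 peak, no (stable or unstable) transcript upstream window,
##     and no exon;
##   none: otherwise.

#' Qualifying outgroup enhancer peaks
#'
#' H3K27ac peaks with no H3K4me3 overlap, no overlap with the 1000-nt
#' upstream window of any (stable or unstable) transcript, and no exon
#' overlap.
#'
#' @param k27ac,k4me3 \code{GRanges} of consensus peaks.
#' @param transcriptsAll \code{\linkS4class{TranscriptSet}} of all
#'   assembled transcripts.
#' @param config list from \code{\link{annotationConfig}}.
#' @return filtered H3K27ac \code{GRanges}.
#' @export
qualifyingEnhancerPeaks <- function(k27ac, k4me3, transcriptsAll,
                                    config = annotationConfig()) {
  up <- GenomicRanges::promoters(tssRanges(transcriptsAll),
                                 upstream = config$promoter_window,
                                 downstream = 0)
  GenomicRanges::start(up) <- pmax(GenomicRanges::start(up), 1L)
  ex <- unlist(transcriptsAll@exons)
  keep <- !.overlaps_any(k27ac, k4me3) &
    !.overlaps_any(k27ac, up) &
    !.overlaps_any(k27ac, ex)
  GenomicRanges::granges(k27ac)[keep]
}

#' Assign outgroup regulatory states
#'
#' For each projected P/E ortholog in the outgroup: \code{"promoter"} when
#' it overlaps the 1000-nt upstream window of a stable transcript (this
#' takes precedence), else \code{"enhancer"} when it overlaps a qualifying
#' H3K27ac peak (see \code{\link{qualifyingEnhancerPeaks}}), else
#' \code{"none"}.
#'
#' @param intervals projected \code{GRanges} in outgroup coordinates.
#' @param ogK27ac,ogK4me3 outgroup consensus peaks.
#' @param ogTranscriptsAll all outgroup transcripts.
#' @param ogStable stable outgroup transcripts.
#' @param config list from \code{\link{annotationConfig}}.
#' @return factor of states (\code{promoter}, \code{enhancer},
#'   \code{none}), parallel to \code{intervals}.
#' @export
assignOutgroupState <- function(intervals, ogK27ac, ogK4me3,
                                ogTranscriptsAll, ogStable,
                                config = annotationConfig()) {
  prom <- GenomicRanges::promoters(tssRanges(ogStable),
                                   upstream = config$promoter_window,
                                   downstream = 0)
  GenomicRanges::start(prom) <- pmax(GenomicRanges::start(prom), 1L)
  qk27 <- qualifyingEnhancerPeaks(ogK27ac, ogK4me3, ogTranscriptsAll,
                                  config)
  is_prom <- .overlaps_any(intervals, prom)
  is_enh <- !is_prom & .overlaps_any(intervals, qk27)
  factor(ifelse(is_prom, "promoter",
                ifelse(is_enh, "enhancer", "none")),
         levels = c("promoter", "enhancer", "none"))
}

#' Summarize outgroup state fractions
#'
#' @param states factor from \code{\link{assignOutgroupState}}.
#' @return list with \code{n}, per-state counts and percentages
#'   (\code{promoter_pct}, \code{enhancer_pct}, \code{none_pct}).
#' @export
outgroupStateFractions <- function(states) {
  n <- length(states)
  cnt <- table(factor(states, levels = c("promoter", "enhancer", "none")))
  list(n = n,
       promoter = unname(cnt["promoter"]),
       enhancer = unname(cnt["enhancer"]),
       none = unname(cnt["none"]),
       promoter_pct = unname(100 * cnt["promoter"] / n),
       enhancer_pct = unname(100 * cnt["enhancer"] / n),
       none_pct = unname(100 * cnt["none"] / n))
}

#' Define ancestral enhancer and promoter sets
#'
#' Reference (species A) elements are kept when they align to both the
#' sister and the outgroup (projection success at the sister and outgroup
#' minimum-match fractions; the reciprocal filter applies to the sister
#' leg only). An aligned promoter is \emph{ancestral} when its outgroup
#' ortholog overlaps the \code{ancestral_window} nt upstream of a stable
#' outgroup transcript; an aligned enhancer is ancestral when its outgroup
#' ortholog overlaps a qualifying H3K27ac peak and is not
#' promoter-associated in the outgroup.
#'
#' @param promoters,enhancers reference \code{GRanges} (organ-restricted,
#'   e.g. liver).
#' @param mapAB,mapBA sister maps; \code{mapAO} outgroup map.
#' @param ogK27ac,ogK4me3 outgroup consensus peaks.
#' @param ogTranscriptsAll,ogStable outgroup transcript sets.
#' @param config list from \code{\link{annotationConfig}}.
#' @param ancestralWindow upstream association window for the ancestral
#'   promoter call (default 500 nt).
#' @return list with \code{enhancers} and \code{promoters}: the ancestral
#'   subsets of the inputs, each with a metadata column
#'   \code{og_seqnames}/\code{og_start}/\code{og_end} of the outgroup
#'   ortholog.
#' @export
defineAncestralElements <- function(promoters, enhancers, mapAB,
                                    mapBA = invertMap(mapAB), mapAO,
                                    ogK27ac, ogK4me3, ogTranscriptsAll,
                                    ogStable,
                                    config = annotationConfig(),
                                    ancestralWindow = 500) {
  prom_win <- GenomicRanges::promoters(tssRanges(ogStable),
                                       upstream = ancestralWindow,
                                       downstream = 0)
  GenomicRanges::start(prom_win) <- pmax(GenomicRanges::start(prom_win), 1L)
  prom_win_full <- GenomicRanges::promoters(tssRanges(ogStable),
                                            upstream =
                                              config$promoter_window,
                                            downstream = 0)
  GenomicRanges::start(prom_win_full) <-
    pmax(GenomicRanges::start(prom_win_full), 1L)
  qk27 <- qualifyingEnhancerPeaks(ogK27ac, ogK4me3, ogTranscriptsAll,
                                  config)

  project_clade <- function(x) {
    sis <- reciprocalOrthologs(x, mapAB, mapBA,
                               minMatch = config$min_match_sister)
    og <- projectIntervals(x, mapAO,
                           minMatch = config$min_match_outgroup)
    keep <- sis$mapped & og$mapped
    list(keep = keep, og = og)
  }

  pick <- function(x, ogRule) {
    pc <- project_clade(x)
    idx <- which(pc$keep)
    if (!length(idx)) {
      out <- x[integer(0)]
    } else {
      og <- GenomicRanges::GRanges(pc$og$seqnames[idx],
        IRanges::IRanges(pc$og$start[idx], pc$og$end[idx]))
      anc <- ogRule(og)
      out <- x[idx[anc]]
      og <- og[anc]
      S4Vectors::mcols(out)$og_seqnames <-
        as.character(GenomicRanges::seqnames(og))
      S4Vectors::mcols(out)$og_start <- GenomicRanges::start(og)
      S4Vectors::mcols(out)$og_end <- GenomicRanges::end(og)
    }
    out
  }

  anc_prom <- pick(promoters, function(og) .overlaps_any(og, prom_win))
  anc_enh <- pick(enhancers, function(og) {
    .overlaps_any(og, qk27) &
      !.overlaps_any(og, prom_win_full) &
      !.overlaps_any(og, GenomicRanges::granges(ogK4me3))
  })
  list(enhancers = anc_enh, promoters = anc_prom)
}

#' Tabulate regulatory turnover
#'
#' Builds the 2x2 repurposed/lost table over ancestral enhancers and
#' promoters. An ancestral enhancer is \emph{repurposed} when it is a
#' member of the P/E set (matched by overlap on A coordinates) and
#' \emph{lost} when, not being repurposed, it is not conserved as an
#' enhancer in the sister species; conserved elements contribute to the
#' row totals only. The promoter row counts as repurposed the P/E elements
#' whose outgroup state is \code{promoter} (promoter-to-enhancer events),
#' and as lost the ancestral promoters not conserved as promoters in the
#' sister.
#'
#' @param ancestral list from \code{\link{defineAncestralElements}}.
#' @param pe P/E \code{GRanges} (A coordinates).
#' @param peOutgroupStates factor from \code{\link{assignOutgroupState}},
#'   parallel to \code{pe}.
#' @param enhConservedSister,promConservedSister logical vectors parallel
#'   to \code{ancestral$enhancers} / \code{ancestral$promoters}: is the
#'   element conserved (same activity) in the sister species?
#' @return list of class \code{turnoverTable}: \code{counts} (2x2 matrix,
#'   rows ancestral_enhancer/ancestral_promoter, columns repurposed/lost)
#'   and \code{totals}.
#' @export
tabulateTurnover <- function(ancestral, pe, peOutgroupStates,
                             enhConservedSister, promConservedSister) {
  anc_enh <- ancestral$enhancers
  anc_prom <- ancestral$promoters
  stopifnot(length(enhConservedSister) == length(anc_enh),
            length(promConservedSister) == length(anc_prom),
            length(peOutgroupStates) == length(pe))
  rep_enh_idx <- .overlaps_any(anc_enh, pe)
  eh_rep <- sum(rep_enh_idx)
  eh_lost <- sum(!rep_enh_idx & !enhConservedSister)
  pr_rep <- sum(peOutgroupStates == "promoter")
  pr_lost <- sum(!promConservedSister)
  counts <- matrix(c(eh_rep, eh_lost, pr_rep, pr_lost), nrow = 2,
                   byrow = TRUE,
                   dimnames = list(c("ancestral_enhancer",
                                     "ancestral_promoter"),
                                   c("repurposed", "lost")))
  structure(list(counts = counts,
                 totals = c(ancestral_enhancer = length(anc_enh),
                            ancestral_promoter = length(anc_prom))),
            class = "turnoverTable")
}

#' Construct a turnover table from counts
#'
#' @param ehRep,ehLost,prRep,prLost cell counts.
#' @param ehTotal,prTotal row totals (ancestral set sizes); default to
#'   repurposed + lost.
#' @return a \code{turnoverTable}.
#' @export
turnoverTable <- function(ehRep, ehLost, prRep, prLost,
                          ehTotal = ehRep + ehLost,
                          prTotal = prRep + prLost) {
  stopifnot(ehRep + ehLost <= ehTotal, prRep + prLost <= prTotal,
            all(c(ehRep, ehLost, prRep, prLost) >= 0))
  structure(list(counts = matrix(c(ehRep, ehLost, prRep, prLost),
                                 nrow = 2, byrow = TRUE,
                                 dimnames = list(c("ancestral_enhancer",
                                                   "ancestral_promoter"),
                                                 c("repurposed", "lost"))),
                 totals = c(ancestral_enhancer = ehTotal,
                            ancestral_promoter = prTotal)),
            class = "turnoverTable")
}

#' @export
print.turnoverTable <- function(x, ...) {
  cat("Turnover table (totals:",
      paste(names(x$totals), x$totals, collapse = ", "), ")\n")
  print(x$counts)
  invisible(x)
}

#' Test for biased repurposing of enhancers vs promoters
#'
#' Odds ratio is the cross product \code{(eh_rep * pr_lost) / (pr_rep *
#' eh_lost)} (reported as \code{Inf} on a zero denominator), with a
#' two-sided Fisher's exact p on the 2x2. Loss rates are lost/total per
#' row; the repurposing rate ratio is \code{(eh_rep/eh_total) /
#' (pr_rep/pr_total)}.
#'
#' @param table a \code{turnoverTable}.
#' @return list: \code{odds_ratio}, \code{p_value},
#'   \code{enhancer_loss_rate}, \code{promoter_loss_rate},
#'   \code{loss_rate_ratio}, \code{repurposing_rate_ratio}.
#' @examples
#' repurposingBiasTest(turnoverTable(27, 2655, 1, 1342,
#'                                   ehTotal = 5260, prTotal = 5110))
#' @export
repurposingBiasTest <- function(table) {
  ct <- table$counts
  den <- ct[2, 1] * ct[1, 2]
  or <- if (den == 0) Inf else (ct[1, 1] * ct[2, 2]) / den
  p <- fisherExact2x2(ct)$p.value
  eh_total <- table$totals["ancestral_enhancer"]
  pr_total <- table$totals["ancestral_promoter"]
  eh_loss <- unname(ct[1, 2] / eh_total)
  pr_loss <- unname(ct[2, 2] / pr_total)
  rep_ratio <- unname((ct[1, 1] / eh_total) / (ct[2, 1] / pr_total))
  list(odds_ratio = unname(or), p_value = p,
       enhancer_loss_rate = eh_loss, promoter_loss_rate = pr_loss,
       loss_rate_ratio = eh_loss / pr_loss,
       repurposing_rate_ratio = rep_ratio)
}
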