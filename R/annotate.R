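## Per-species annotation of promoters, enhancers and inactive control
## regions from harmonized peak sets, DHSs, transcript models and masks.
##
## Threshold semantics used throughout:
##   - "closer than 1000 nt" means inter-interval gap < 1000 (overlap = 0);
##   - overlap anywhere means >= 1 shared base;
##   - stability is strict: mean FPKM > 1 AND span > 1000 nt.

#' Default annotation configuration
#'
#' All thresholds of the annotation and detection steps, in one list:
#' stability (\code{fpkm_threshold}, strict >; \code{min_tx_length}, strict
#' >), the promoter window (1000 nt upstream of the TSS), the P/E
#' association window (500 nt upstream — deliberately distinct from the
#' promoter window), per-replicate peak caps (top 20,000 for H3K4me3, top
#' 80,000 for H3K4me1/H3K27ac), the 1000-nt harmonized peak size, the
#' bivalence exclusion distance, inactive-region sampling targets, the
#' projection minimum-match fractions (0.6 sister, 0.4 outgroup), and the
#' GC-matching threshold/cap.
#'
#' @param ... named overrides of any default.
#' @return a named list.
#' @export
annotationConfig <- function(...) {
  cfg <- list(
    fpkm_threshold = 1,
    min_tx_length = 1000,
    promoter_window = 1000,
    pe_overlap_window = 500,
    k4me3_top_n = 20000,
    k4me1_top_n = 80000,
    k27ac_top_n = 80000,
    peak_resize = 1000,
    bivalence_distance = 1000,
    inactive_target = 1500000,
    inactive_length = 1000,
    inactive_exclusion_distance = 1000,
    min_match_sister = 0.6,
    min_match_outgroup = 0.4,
    gc_match_threshold = 0.46,
    gc_match_max_n = 30000
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

.rank_peaks <- function(gr, topN) {
  # deterministic: descending score, ties by (seqname, start)
  o <- order(-S4Vectors::mcols(gr)$score,
             as.factor(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  gr[o][seq_len(min(topN, length(gr)))]
}

.resize_on_summit <- function(gr, size, seqlengths = NULL) {
  mc <- S4Vectors::mcols(gr)
  summit <- if ("summit_offset" %in% colnames(mc)) mc$summit_offset
            else rep(NA_integer_, length(gr))
  # summit base (1-based); midpoint when the summit is absent
  center <- ifelse(is.na(summit),
                   GenomicRanges::start(gr) +
                     GenomicRanges::width(gr) %/% 2L,
                   GenomicRanges::start(gr) + summit)
  half <- size %/% 2L
  st <- center - half
  en <- st + size - 1L
  st <- pmax(st, 1L)
  if (!is.null(seqlengths)) {
    lim <- seqlengths[as.character(GenomicRanges::seqnames(gr))]
    en <- pmin(en, lim)
  }
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(st, as.integer(en)))
  S4Vectors::mcols(out)$score <- if ("score" %in% colnames(mc)) mc$score
                                 else rep(0, length(gr))
  out
}

#' Harmonize peak replicates into consensus 1000-nt loci
#'
#' Per replicate, keeps the top \code{topN} peaks by descending score
#' (ties broken by position for determinism); then retains loci supported
#' by at least \code{minReplicates} replicates (default rule: 3 when three
#' or more replicates are given, both when exactly two, as-is for one
#' already-merged sample). Overlapping supported peaks are clustered and
#' each cluster is represented by its highest-score peak, resized to
#' \code{size} nt centered on that peak's summit (midpoint when no summit),
#' clipped at contig bounds.
#'
#' @param replicates list of \code{GRanges} (one per replicate) with
#'   \code{score} and optional \code{summit_offset} metadata columns.
#' @param topN per-replicate peak cap.
#' @param size harmonized interval length (default 1000).
#' @param minReplicates support requirement; \code{NULL} for the default
#'   rule.
#' @param seqlengths optional named contig lengths for edge clipping.
#' @return consensus \code{GRanges}, sorted.
#' @export
harmonizePeakReplicates <- function(replicates, topN, size = 1000,
                                    minReplicates = NULL,
                                    seqlengths = NULL) {
  stopifnot(length(replicates) >= 1)
  nrep <- length(replicates)
  if (is.null(minReplicates))
    minReplicates <- if (nrep >= 3) 3L else nrep
  kept <- lapply(replicates, .rank_peaks, topN = topN)
  all <- unlist(GenomicRanges::GRangesList(lapply(kept,
    GenomicRanges::granges)))
  rep_id <- rep(seq_len(nrep), lengths(kept))
  score <- unlist(lapply(kept, function(g) S4Vectors::mcols(g)$score))
  summit <- unlist(lapply(kept, function(g) {
    mc <- S4Vectors::mcols(g)
    if ("summit_offset" %in% colnames(mc)) mc$summit_offset
    else rep(NA_integer_, length(g))
  }))
  if (!length(all)) return(GenomicRanges::GRanges())
  # per peak, number of distinct replicates with an overlapping peak
  ov <- GenomicRanges::findOverlaps(all, ignore.strand = TRUE)
  support <- vapply(seq_along(all), function(i) 1L, integer(1))
  df <- data.frame(q = S4Vectors::queryHits(ov),
                   r = rep_id[S4Vectors::subjectHits(ov)])
  support <- tapply(df$r, df$q, function(r) length(unique(r)))
  supp_vec <- rep(1L, length(all))
  supp_vec[as.integer(names(support))] <- as.integer(support)
  ok <- supp_vec >= minReplicates
  if (!any(ok)) return(GenomicRanges::GRanges())
  cand <- all[ok]
  S4Vectors::mcols(cand)$score <- score[ok]
  S4Vectors::mcols(cand)$summit_offset <- summit[ok]
  # cluster overlapping supported peaks; anchor on the top-score member
  red <- GenomicRanges::reduce(cand, ignore.strand = TRUE)
  cl <- GenomicRanges::findOverlaps(cand, red, ignore.strand = TRUE)
  cl_id <- S4Vectors::subjectHits(cl)[order(S4Vectors::queryHits(cl))]
  o <- order(cl_id, -S4Vectors::mcols(cand)$score,
             as.factor(GenomicRanges::seqnames(cand)),
             GenomicRanges::start(cand))
  anchor <- cand[o][!duplicated(cl_id[o])]
  GenomicRanges::sort(.resize_on_summit(anchor, size, seqlengths))
}

#' Stable-transcript filter
#'
#' Retains transcripts with mean replicate FPKM strictly greater than the
#' threshold in \code{organ} AND genomic span (introns included) strictly
#' greater than the length threshold.
#'
#' @param x a \code{\linkS4class{TranscriptSet}}.
#' @param organ organ name.
#' @param config list from \code{\link{annotationConfig}}.
#' @return a \code{\linkS4class{TranscriptSet}} of the stable transcripts.
#' @export
callStableTranscripts <- function(x, organ, config = annotationConfig()) {
  mf <- meanFpkm(x, organ)
  if (all(is.na(mf)))
    warning("organ '", organ, "' absent from all transcripts")
  span <- GenomicRanges::width(transcriptSpans(x))
  keep <- !is.na(mf) & mf > config$fpkm_threshold &
    span > config$min_tx_length
  subsetTranscripts(x, names(x@exons)[keep])
}

#' Promoters of stable transcripts
#'
#' The \code{window} nt immediately upstream of each stable TSS (strand
#' aware), clipped at contig bounds; identical intervals from isoforms
#' sharing a TSS are merged.
#'
#' @param stable a \code{\linkS4class{TranscriptSet}} of stable
#'   transcripts (see \code{\link{callStableTranscripts}}).
#' @param window upstream window in nt (default 1000).
#' @param seqlengths optional named contig lengths for clipping.
#' @param organ optional organ label recorded in \code{organs_active}.
#' @return \code{GRanges} with metadata columns \code{element_class}
#'   (\code{"promoter"}), \code{transcript_id}, \code{organs_active}.
#' @export
definePromoters <- function(stable, window = 1000, seqlengths = NULL,
                            organ = NA_character_) {
  tss <- tssRanges(stable)
  pr <- GenomicRanges::promoters(tss, upstream = window, downstream = 0)
  st <- pmax(GenomicRanges::start(pr), 1L)
  en <- GenomicRanges::end(pr)
  if (!is.null(seqlengths)) {
    lim <- seqlengths[as.character(GenomicRanges::seqnames(pr))]
    en <- pmin(en, lim)
    st <- pmin(st, en)  # degenerate guard at contig edge
  }
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(pr),
                                IRanges::IRanges(st, en),
                                strand = GenomicRanges::strand(pr))
  S4Vectors::mcols(out)$transcript_id <- names(tss)
  keep <- !GenomicRanges::duplicated(GenomicRanges::granges(out))
  out <- out[keep]
  S4Vectors::mcols(out)$element_class <- "promoter"
  S4Vectors::mcols(out)$organs_active <- organ
  out
}

.gap_within <- function(x, subject, dist) {
  # TRUE where x is closer than `dist` to any subject (overlap = 0 gap)
  if (length(subject) == 0) return(rep(FALSE, length(x)))
  near <- GenomicRanges::distanceToNearest(x, subject,
                                           ignore.strand = TRUE)
  out <- rep(FALSE, length(x))
  out[S4Vectors::queryHits(near)] <-
    S4Vectors::mcols(near)$distance < dist
  out
}

.overlaps_any <- function(x, subject) {
  if (length(subject) == 0) return(rep(FALSE, length(x)))
  IRanges::overlapsAny(x, subject, ignore.strand = TRUE)
}

#' Call putative enhancers
#'
#' Chromatin enhancers are DHSs overlapping (>= 1 bp) an H3K27ac and/or an
#' H3K4me1 consensus peak, excluding loci closer than
#' \code{bivalence_distance} to any H3K4me3 peak from any tissue, and loci
#' overlapping the 1000-nt TSS-upstream window or the exons of any (stable
#' or unstable) transcript. CAGE-defined enhancers, when given, pass the
#' same exclusions and are appended with provenance \code{"CAGE"}.
#'
#' @param dhs DHS \code{GRanges}.
#' @param k27ac,k4me1 consensus mark \code{GRanges} (see
#'   \code{\link{harmonizePeakReplicates}}).
#' @param k4me3All union of H3K4me3 peaks across all organs/tissues.
#' @param transcriptsAll a \code{\linkS4class{TranscriptSet}} of all
#'   assembled transcripts, stable or not.
#' @param cage optional CAGE enhancer \code{GRanges}.
#' @param config list from \code{\link{annotationConfig}}.
#' @return \code{GRanges} with \code{element_class} (\code{"enhancer"}) and
#'   \code{provenance} (\code{"chromatin"}/\code{"CAGE"}) columns; output
#'   is sorted, so it is invariant to input ordering.
#' @export
callEnhancers <- function(dhs, k27ac, k4me1, k4me3All, transcriptsAll,
                          cage = NULL, config = annotationConfig()) {
  marks <- c(GenomicRanges::granges(k27ac), GenomicRanges::granges(k4me1))
  cand <- GenomicRanges::granges(dhs)[.overlaps_any(dhs, marks)]
  tx_up <- GenomicRanges::promoters(tssRanges(transcriptsAll),
                                    upstream = config$promoter_window,
                                    downstream = 0)
  GenomicRanges::start(tx_up) <- pmax(GenomicRanges::start(tx_up), 1L)
  exons <- unlist(transcriptsAll@exons)
  pass <- function(x) {
    !.gap_within(x, GenomicRanges::granges(k4me3All),
                 config$bivalence_distance) &
      !.overlaps_any(x, tx_up) &
      !.overlaps_any(x, exons)
  }
  out <- cand[pass(cand)]
  S4Vectors::mcols(out)$provenance <- rep("chromatin", length(out))
  if (!is.null(cage) && length(cage)) {
    cg <- GenomicRanges::granges(cage)
    cg <- cg[pass(cg)]
    S4Vectors::mcols(cg)$provenance <- rep("CAGE", length(cg))
    out <- c(out, cg)
  }
  S4Vectors::mcols(out)$element_class <- rep("enhancer", length(out))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Sample inactive control regions
#'
#' Rejection-samples non-overlapping \code{inactive_length}-nt loci
#' uniformly over the genome, discarding any proposal closer than
#' \code{inactive_exclusion_distance} to a peak/DHS, an exon, or a masked
#' (repeat / segmental-duplication) interval. Sampling stops at
#' \code{target} accepted loci or after 50x \code{target} proposals.
#'
#' @param seqlengths named contig lengths.
#' @param exclusionPeaks \code{GRanges} union of DHS and all mark peaks
#'   from all tissues.
#' @param exons \code{GRanges} of all exons (assembled or annotated).
#' @param masks \code{GRanges} of repeat/segmental-duplication masks.
#' @param config list from \code{\link{annotationConfig}}.
#' @param seed integer seed; identical seeds give identical output.
#' @param target maximum number of regions (default
#'   \code{config$inactive_target}).
#' @return \code{GRanges} with \code{element_class = "inactive"}, sorted.
#' @export
sampleInactiveRegions <- function(seqlengths, exclusionPeaks, exons,
                                  masks = GenomicRanges::GRanges(),
                                  config = annotationConfig(), seed = 1,
                                  target = config$inactive_target) {
  len <- config$inactive_length
  dist <- config$inactive_exclusion_distance
  avoid <- GenomicRanges::reduce(c(GenomicRanges::granges(exclusionPeaks),
                                   GenomicRanges::granges(exons),
                                   GenomicRanges::granges(masks)),
                                 ignore.strand = TRUE)
  chroms <- names(seqlengths)[seqlengths >= len]
  if (!length(chroms)) {
    warning("no contig can hold an inactive region")
    return(GenomicRanges::GRanges())
  }
  set.seed(seed)
  accepted <- GenomicRanges::GRanges()
  proposals <- 0L
  cap <- 50 * target
  batch <- max(1000L, min(target, 100000L))
  w <- (seqlengths[chroms] - len + 1)
  repeat {
    if (length(accepted) >= target || proposals >= cap) break
    n <- min(batch, cap - proposals)
    proposals <- proposals + n
    chr <- sample(chroms, n, replace = TRUE, prob = w / sum(w))
    st <- floor(stats::runif(n, min = 1,
                             max = seqlengths[chr] - len + 1))
    prop <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, st + len - 1))
    ok <- !.gap_within(prop, avoid, dist) &
      !.overlaps_any(prop, accepted)
    prop <- prop[ok]
    # also reject overlaps within the batch, keeping earlier proposals
    if (length(prop) > 1) {
      self <- GenomicRanges::findOverlaps(prop, ignore.strand = TRUE,
                                          drop.self = TRUE)
      drop <- unique(S4Vectors::queryHits(self)[
        S4Vectors::queryHits(self) > S4Vectors::subjectHits(self)])
      if (length(drop)) prop <- prop[-drop]
    }
    need <- target - length(accepted)
    if (length(prop) > need) prop <- prop[seq_len(need)]
    accepted <- c(accepted, prop)
  }
  if (!length(accepted)) {
    warning("no placeable inactive region")
    return(accepted)
  }
  out <- GenomicRanges::sort(accepted, ignore.strand = TRUE)
  S4Vectors::mcols(out)$element_class <- "inactive"
  out
}

#' GC-matched enhancer/inactive subsampling
#'
#' Drops enhancers with GC at or above the species threshold (0.46
#' human-like, 0.41 mouse-like), caps the enhancer set at
#' \code{gc_match_max_n} (deterministic subsample under \code{seed}), and
#' greedily matches each remaining enhancer without replacement to the
#' inactive region with the most similar GC (ties go to the lower GC).
#'
#' @param enhancers,inactive \code{GRanges} with a numeric \code{gc}
#'   metadata column.
#' @param config list from \code{\link{annotationConfig}}.
#' @param seed integer seed for the subsample.
#' @return list with \code{enhancers} and \code{inactive}, parallel
#'   \code{GRanges} (row i of each are a matched pair).
#' @export
gcMatchedSubsample <- function(enhancers, inactive,
                               config = annotationConfig(), seed = 1) {
  ge <- S4Vectors::mcols(enhancers)$gc
  gi <- S4Vectors::mcols(inactive)$gc
  stopifnot(!is.null(ge), !is.null(gi))
  keep <- which(!is.na(ge) & ge < config$gc_match_threshold)
  enh <- enhancers[keep]
  ge <- ge[keep]
  if (length(enh) > config$gc_match_max_n) {
    set.seed(seed)
    idx <- sort(sample.int(length(enh), config$gc_match_max_n))
    enh <- enh[idx]
    ge <- ge[idx]
  }
  if (length(inactive) < length(enh))
    stop("inactive pool smaller than the matched enhancer set")
  pool_idx <- order(gi, as.factor(GenomicRanges::seqnames(inactive)),
                    GenomicRanges::start(inactive))
  pool_gc <- gi[pool_idx]
  taken <- rep(FALSE, length(pool_idx))
  match_idx <- integer(length(enh))
  for (k in seq_along(enh)) {
    free <- which(!taken)
    dd <- abs(pool_gc[free] - ge[k])
    # epsilon-tolerant minimum; pool is sorted ascending by GC, so
    # equidistant candidates resolve to the lower GC
    j <- free[which(dd <= min(dd) + 1e-9)[1]]
    taken[j] <- TRUE
    match_idx[k] <- pool_idx[j]
  }
  list(enhancers = enh, inactive = inactive[match_idx])
}
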