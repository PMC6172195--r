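## P/E element detection: enhancers in species A whose reciprocal
## orthologs in sister species B overlap the 500-nt window upstream of a
## stable transcript's TSS; truncated-isoform artifact removal;
## novel/extended classification; enrichment against inactive controls.

#' Detect P/E elements
#'
#' Projects each A enhancer to B through the reciprocal (two-way) filter
#' and reports those whose B ortholog overlaps (>= 1 bp) the
#' \code{pe_overlap_window} nt upstream of a stable B transcript's TSS.
#' When several transcripts with distinct TSSs are overlapped, the one
#' whose TSS is nearest the projection midpoint is attached (ties to the
#' smallest TSS coordinate, then transcript id).
#'
#' @param aEnhancers enhancer \code{GRanges} in species A.
#' @param mapAB,mapBA \code{\linkS4class{OrthologyMap}}s between A and B.
#' @param bStable \code{\linkS4class{TranscriptSet}} of stable B
#'   transcripts.
#' @param config list from \code{\link{annotationConfig}}.
#' @param organ optional organ label stored on the elements.
#' @return \code{GRanges} on A coordinates with metadata columns
#'   \code{b_seqnames}, \code{b_start}, \code{b_end}, \code{b_strand},
#'   \code{b_transcript_id}, \code{category} (\code{NA} until
#'   \code{\link{classifyPEElements}}), \code{organs_active_b}.
#' @export
detectPEElements <- function(aEnhancers, mapAB, mapBA = invertMap(mapAB),
                             bStable, config = annotationConfig(),
                             organ = NA_character_) {
  empty <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      b_seqnames = character(), b_start = integer(), b_end = integer(),
      b_strand = character(), b_transcript_id = character(),
      category = character(), organs_active_b = character())
    gr
  }
  if (length(aEnhancers) == 0) return(empty())
  proj <- reciprocalOrthologs(aEnhancers, mapAB, mapBA,
                              minMatch = config$min_match_sister)
  tg <- projectionTargets(proj)
  if (length(tg) == 0) return(empty())
  tss <- tssRanges(bStable)
  win <- GenomicRanges::promoters(tss,
                                  upstream = config$pe_overlap_window,
                                  downstream = 0)
  GenomicRanges::start(win) <- pmax(GenomicRanges::start(win), 1L)
  ov <- GenomicRanges::findOverlaps(tg, win, ignore.strand = TRUE)
  if (length(ov) == 0) return(empty())
  qh <- S4Vectors::queryHits(ov)
  th <- S4Vectors::subjectHits(ov)
  mid <- (GenomicRanges::start(tg) + GenomicRanges::end(tg))[qh] / 2
  tss_pos <- GenomicRanges::start(tss)[th]
  o <- order(qh, abs(tss_pos - mid), tss_pos, names(tss)[th])
  pick <- !duplicated(qh[o])
  qh <- qh[o][pick]
  th <- th[o][pick]
  src <- S4Vectors::mcols(tg)$source_index[qh]
  out <- aEnhancers[src]
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    b_seqnames = as.character(GenomicRanges::seqnames(tg))[qh],
    b_start = GenomicRanges::start(tg)[qh],
    b_end = GenomicRanges::end(tg)[qh],
    b_strand = as.character(GenomicRanges::strand(tg))[qh],
    b_transcript_id = names(tss)[th],
    category = NA_character_,
    organs_active_b = organ)
  names(out) <- if (!is.null(names(aEnhancers))) names(aEnhancers)[src]
                else as.character(src)
  out
}

.tx_locus_ids <- function(txset) {
  # group transcripts into loci: connected components of >=1 bp exonic
  # overlap on the same strand
  ex <- unlist(txset@exons)
  tx_of_exon <- rep(seq_along(txset@exons),
                    S4Vectors::elementNROWS(txset@exons))
  red <- GenomicRanges::reduce(ex, ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(ex, red, ignore.strand = FALSE)
  # union-find over transcripts sharing a reduced exonic chunk
  parent <- seq_len(length(txset@exons))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  chunk_tx <- split(tx_of_exon[S4Vectors::queryHits(ov)],
                    S4Vectors::subjectHits(ov))
  for (txs in chunk_tx) {
    txs <- unique(txs)
    if (length(txs) > 1) {
      r <- find(txs[1])
      for (t in txs[-1]) parent[find(t)] <- r
    }
  }
  vapply(seq_along(parent), find, integer(1))
}

#' Remove truncated-isoform artifacts
#'
#' Drops a P/E element when its B transcript's locus (stable transcripts
#' sharing >= 1 bp exonic overlap on the same strand) contains another
#' stable transcript whose TSS lies strictly upstream (strand-aware) —
#' i.e. the P/E transcript is a shorter isoform of a locus with an
#' alternative, upstream promoter. Only stable transcripts define
#' alternative promoters.
#'
#' @param pe \code{GRanges} from \code{\link{detectPEElements}}.
#' @param bStable \code{\linkS4class{TranscriptSet}} of stable B
#'   transcripts.
#' @return the filtered \code{GRanges}.
#' @export
filterTruncatedIsoforms <- function(pe, bStable) {
  if (length(pe) == 0 || length(bStable) == 0) return(pe)
  locus <- .tx_locus_ids(bStable)
  tss <- tssRanges(bStable)
  tss_pos <- GenomicRanges::start(tss)
  strand <- as.character(GenomicRanges::strand(tss))
  ids <- names(bStable@exons)
  has_upstream <- vapply(seq_along(ids), function(i) {
    sib <- which(locus == locus[i])
    sib <- sib[sib != i]
    if (!length(sib)) return(FALSE)
    if (strand[i] == "-") any(tss_pos[sib] > tss_pos[i])
    else any(tss_pos[sib] < tss_pos[i])
  }, logical(1))
  bad_ids <- ids[has_upstream]
  pe[!S4Vectors::mcols(pe)$b_transcript_id %in% bad_ids]
}

#' Classify P/E elements as novel or extended
#'
#' Projects each element's B transcript exons to A (sister minimum-match)
#' and labels the element \emph{extended} when any projected exon overlaps
#' (>= 1 bp, strand-ignored) any A transcript span, \emph{novel} when none
#' does or the transcript is unprojectable.
#'
#' @param pe \code{GRanges} from \code{\link{detectPEElements}}.
#' @param mapBA B-to-A \code{\linkS4class{OrthologyMap}}.
#' @param bTranscripts \code{\linkS4class{TranscriptSet}} containing the
#'   P/E transcripts.
#' @param aTranscriptsAll \code{\linkS4class{TranscriptSet}} of all
#'   assembled or annotated A transcripts.
#' @param config list from \code{\link{annotationConfig}}.
#' @return \code{pe} with the \code{category} column filled.
#' @export
classifyPEElements <- function(pe, mapBA, bTranscripts, aTranscriptsAll,
                               config = annotationConfig()) {
  if (length(pe) == 0) return(pe)
  a_span <- transcriptSpans(aTranscriptsAll)
  cats <- vapply(seq_along(pe), function(i) {
    txid <- S4Vectors::mcols(pe)$b_transcript_id[i]
    if (!txid %in% names(bTranscripts@exons)) return("novel")
    ex <- bTranscripts@exons[[txid]]
    proj <- projectIntervals(ex, mapBA,
                             minMatch = config$min_match_sister)
    tg <- projectionTargets(proj)
    if (length(tg) && length(a_span) &&
        any(IRanges::overlapsAny(tg, a_span, ignore.strand = TRUE)))
      "extended" else "novel"
  }, character(1))
  S4Vectors::mcols(pe)$category <- cats
  pe
}

#' P/E enrichment against inactive controls
#'
#' Compares the P/E rate among tested enhancers with the rate of
#' promoter-orthologous loci among tested inactive regions:
#' \code{rate_ratio = (pe/enh) / (ctrl/ctrlTested)}, with a two-sided
#' Fisher's exact test on the corresponding 2x2 table.
#'
#' @param peCount,enhTested P/E elements and enhancers tested.
#' @param ctrlCount,ctrlTested control positives and controls tested.
#' @return list: \code{pe_count}, \code{enh_tested}, \code{ctrl_count},
#'   \code{ctrl_tested}, \code{rate_ratio}, \code{p_value}.
#' @examples
#' peVsInactiveEnrichment(184, 97405, 79, 181688)
#' @export
peVsInactiveEnrichment <- function(peCount, enhTested, ctrlCount,
                                   ctrlTested) {
  stopifnot(peCount >= 0, ctrlCount >= 0, enhTested > 0, ctrlTested > 0,
            peCount <= enhTested, ctrlCount <= ctrlTested)
  rr <- if (ctrlCount > 0)
    (peCount / enhTested) / (ctrlCount / ctrlTested) else Inf
  if (peCount == 0) rr <- 0
  ft <- fisherExact2x2(matrix(c(peCount, enhTested - peCount,
                                ctrlCount, ctrlTested - ctrlCount),
                              nrow = 2, byrow = TRUE))
  list(pe_count = peCount, enh_tested = enhTested,
       ctrl_count = ctrlCount, ctrl_tested = ctrlTested,
       rate_ratio = rr, p_value = ft$p.value)
}
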