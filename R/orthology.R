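## Coordinate projection through co-linear block maps.
##
## Mirrors the liftOver contract used for cross-species conversion:
## an interval maps iff at least minMatch of its bases fall inside blocks,
## the target span is taken from the first to the last mapped base
## (orientation-aware), multi-chromosome or mixed-orientation coverage
## fails, and a reciprocal (two-way) filter rejects paralogy-induced
## ambiguity.

#' Swap source and target of an OrthologyMap
#'
#' Because blocks are gapless and equal-length, a map is exactly invertible;
#' inverted blocks stay inverted.
#'
#' @param map an \code{\linkS4class{OrthologyMap}}.
#' @return the target-to-source \code{\linkS4class{OrthologyMap}}.
#' @export
invertMap <- function(map) {
  OrthologyMap(map@tgt, map@src, orientation = map@orientation,
               sourceAssembly = map@targetAssembly,
               targetAssembly = map@sourceAssembly)
}

#' Project intervals through an orthology map
#'
#' For each query interval the mapped fraction is the proportion of its
#' bases covered by map blocks. When the fraction reaches \code{minMatch}
#' the target is the span from the first to the last mapped base on the
#' target assembly (orientation-aware); the projection fails when mapped
#' bases hit more than one target chromosome, mix block orientations, or
#' when the bridged target span exceeds \code{maxSpanFactor} times the
#' source width (a guard against rearrangement-driven absurd spans).
#' Stranded queries flip strand through inverted blocks.
#'
#' @param x query \code{GRanges}.
#' @param map an \code{\linkS4class{OrthologyMap}}.
#' @param minMatch minimum mapped fraction in (0, 1]; 0.6 is the
#'   sister-species default, 0.4 the outgroup default.
#' @param maxSpanFactor maximum ratio of target span to source width.
#' @return a \code{data.frame} with one row per query: \code{seqnames},
#'   \code{start}, \code{end}, \code{strand} of the target (\code{NA} when
#'   unmapped), \code{fraction} mapped, and logical \code{mapped}.
#' @seealso \code{\link{reciprocalOrthologs}}
#' @export
projectIntervals <- function(x, map, minMatch = 0.6, maxSpanFactor = 10) {
  stopifnot(minMatch > 0, minMatch <= 1)
  n <- length(x)
  out <- data.frame(seqnames = rep(NA_character_, n),
                    start = rep(NA_integer_, n),
                    end = rep(NA_integer_, n),
                    strand = rep(NA_character_, n),
                    fraction = numeric(n),
                    mapped = logical(n))
  if (n == 0) return(out)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(x, map@src, ignore.strand = TRUE))
  if (length(hits) == 0) return(out)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # per-hit intersection of query with block, in source coordinates
  is <- pmax(GenomicRanges::start(x)[qh], GenomicRanges::start(map@src)[sh])
  ie <- pmin(GenomicRanges::end(x)[qh], GenomicRanges::end(map@src)[sh])
  # translate the intersected segment to target coordinates
  s1 <- GenomicRanges::start(map@src)[sh]
  t1 <- GenomicRanges::start(map@tgt)[sh]
  t2 <- GenomicRanges::end(map@tgt)[sh]
  ori <- map@orientation[sh]
  ts <- ifelse(ori == "+", t1 + (is - s1), t2 - (ie - s1))
  te <- ifelse(ori == "+", t1 + (ie - s1), t2 - (is - s1))
  tchr <- as.character(GenomicRanges::seqnames(map@tgt))[sh]
  mapped_bases <- tapply(ie - is + 1L, qh, sum)
  idx <- as.integer(names(mapped_bases))
  out$fraction[idx] <- as.numeric(mapped_bases) /
    GenomicRanges::width(x)[idx]
  ok <- idx[out$fraction[idx] >= minMatch]
  for (i in ok) {
    sel <- qh == i
    if (length(unique(tchr[sel])) != 1L ||
        length(unique(ori[sel])) != 1L) next
    span_s <- min(ts[sel])
    span_e <- max(te[sel])
    if ((span_e - span_s + 1L) >
        maxSpanFactor * GenomicRanges::width(x)[i]) next
    qstrand <- as.character(GenomicRanges::strand(x))[i]
    if (qstrand != "*" && ori[sel][1] == "-")
      qstrand <- if (qstrand == "+") "-" else "+"
    out$seqnames[i] <- tchr[sel][1]
    out$start[i] <- span_s
    out$end[i] <- span_e
    out$strand[i] <- qstrand
    out$mapped[i] <- TRUE
  }
  out
}

#' Extract mapped projections as GRanges
#'
#' @param proj result of \code{\link{projectIntervals}}.
#' @return \code{GRanges} of the mapped rows, with metadata column
#'   \code{source_index} giving the query row each target came from.
#' @export
projectionTargets <- function(proj) {
  keep <- which(proj$mapped)
  if (!length(keep)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$source_index <- integer()
    return(gr)
  }
  strand <- proj$strand[keep]
  strand[is.na(strand)] <- "*"
  GenomicRanges::GRanges(proj$seqnames[keep],
    IRanges::IRanges(proj$start[keep], proj$end[keep]),
    strand = strand, source_index = keep)
}

#' Reciprocal (two-way) orthologs
#'
#' Projects A intervals to B, back-projects the B targets to A, and keeps a
#' projection only when the round trip overlaps the original interval by at
#' least one base on the same chromosome — the two-way conversion used to
#' reject ambiguous orthology from duplications.
#'
#' @param x query \code{GRanges} on the A assembly.
#' @param mapAB,mapBA \code{\linkS4class{OrthologyMap}}s between the same
#'   assembly pair (B-to-A may be \code{invertMap(mapAB)}).
#' @param minMatch minimum mapped fraction used in both directions.
#' @param maxSpanFactor passed to \code{\link{projectIntervals}}.
#' @return as \code{\link{projectIntervals}}: the B-side coordinates, with
#'   \code{mapped} TRUE only for reciprocally consistent projections.
#' @export
reciprocalOrthologs <- function(x, mapAB, mapBA = invertMap(mapAB),
                                minMatch = 0.6, maxSpanFactor = 10) {
  fwd <- projectIntervals(x, mapAB, minMatch, maxSpanFactor)
  tg <- projectionTargets(fwd)
  if (length(tg)) {
    back <- projectIntervals(tg, mapBA, minMatch, maxSpanFactor)
    src_idx <- S4Vectors::mcols(tg)$source_index
    consistent <- back$mapped &
      back$seqnames == as.character(GenomicRanges::seqnames(x))[src_idx] &
      back$start <= GenomicRanges::end(x)[src_idx] &
      back$end >= GenomicRanges::start(x)[src_idx]
    consistent[is.na(consistent)] <- FALSE
    drop <- src_idx[!consistent]
    fwd$mapped[drop] <- FALSE
    fwd$seqnames[drop] <- NA_character_
    fwd$start[drop] <- NA_integer_
    fwd$end[drop] <- NA_integer_
    fwd$strand[drop] <- NA_character_
  }
  fwd
}
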