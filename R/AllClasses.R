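#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom S4Vectors DataFrame
NULL

#' Co-linear orthology block map between two assemblies
#'
#' An \code{OrthologyMap} pairs gapless, equal-length blocks of two genome
#' assemblies. Indels between the assemblies live \emph{between} blocks;
#' within a block the alignment is one base to one base, either in the same
#' orientation or inverted. It is the substrate for coordinate projection
#' (\code{\link{projectIntervals}}), playing the role that chain files play
#' for liftOver-style tools, but with a deliberately simple TSV dialect.
#'
#' @slot sourceAssembly,targetAssembly single strings naming the assemblies.
#' @slot src,tgt parallel \code{GRanges}; \code{src} blocks are disjoint and
#'   sorted, and \code{width(src) == width(tgt)} element-wise.
#' @slot orientation character vector of \code{"+"}/\code{"-"} per block;
#'   \code{"-"} means the block aligns to the reverse strand of the target.
#'
#' @seealso \code{\link{readOrthologyMap}}, \code{\link{projectIntervals}},
#'   \code{\link{invertMap}}
#' @export
setClass("OrthologyMap",
  representation(
    sourceAssembly = "character",
    targetAssembly = "character",
    src = "GRanges",
    tgt = "GRanges",
    orientation = "character"
  )
)

setValidity("OrthologyMap", function(object) {
  msgs <- character()
  n <- length(object@src)
  if (length(object@tgt) != n || length(object@orientation) != n)
    msgs <- c(msgs, "src, tgt and orientation must have equal length")
  if (length(object@tgt) == n && n > 0) {
    if (!all(GenomicRanges::width(object@src) ==
             GenomicRanges::width(object@tgt)))
      msgs <- c(msgs, "blocks must pair equal source and target lengths")
    if (!all(object@orientation %in% c("+", "-")))
      msgs <- c(msgs, "orientation must be '+' or '-'")
    self <- GenomicRanges::findOverlaps(object@src, drop.self = TRUE,
                                        ignore.strand = TRUE)
    if (length(self) > 0)
      msgs <- c(msgs, "source blocks must be non-overlapping")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn OrthologyMap number of blocks
#' @param x an \code{OrthologyMap}
#' @export
setMethod("length", "OrthologyMap", function(x) length(x@src))

setMethod("show", "OrthologyMap", function(object) {
  cat("OrthologyMap: ", object@sourceAssembly, " -> ",
      object@targetAssembly, "\n", sep = "")
  cat("  ", length(object), " block(s), ",
      sum(GenomicRanges::width(object@src)), " mapped bases, ",
      sum(object@orientation == "-"), " inverted\n", sep = "")
})

#' Construct an OrthologyMap
#'
#' @param src,tgt parallel \code{GRanges} of equal-width blocks.
#' @param orientation \code{"+"}/\code{"-"} per block (recycled).
#' @param sourceAssembly,targetAssembly assembly names.
#' @return a validated \code{\linkS4class{OrthologyMap}} with blocks sorted
#'   by source position.
#' @export
OrthologyMap <- function(src, tgt, orientation = "+",
                         sourceAssembly = "source",
                         targetAssembly = "target") {
  orientation <- rep(orientation, length.out = length(src))
  o <- order(as.factor(GenomicRanges::seqnames(src)),
             GenomicRanges::start(src))
  new("OrthologyMap",
      sourceAssembly = sourceAssembly, targetAssembly = targetAssembly,
      src = src[o], tgt = tgt[o], orientation = orientation[o])
}

#' Transcript models with per-organ replicate expression
#'
#' Container for assembled transcript models: an exon chain per transcript
#' plus an FPKM long table keyed by (transcript, organ, replicate). The TSS
#' of a transcript is the first transcribed base: the smallest exon start on
#' \code{+}, the largest exon end on \code{-}.
#'
#' @slot exons \code{GRangesList}, one element per transcript (named by
#'   transcript id); exons are disjoint, sorted, single-seqname,
#'   single-strand.
#' @slot txData \code{DataFrame} with columns \code{transcript_id},
#'   \code{gene_id}.
#' @slot fpkm \code{data.frame} with columns \code{transcript_id},
#'   \code{organ}, \code{replicate}, \code{fpkm}.
#' @seealso \code{\link{readTranscriptModels}}, \code{\link{transcriptSpans}},
#'   \code{\link{tssRanges}}, \code{\link{callStableTranscripts}}
#' @export
setClass("TranscriptSet",
  representation(
    exons = "CompressedGRangesList",
    txData = "DataFrame",
    fpkm = "data.frame"
  )
)

setValidity("TranscriptSet", function(object) {
  msgs <- character()
  if (length(object@exons) != nrow(object@txData))
    msgs <- c(msgs, "exons and txData must be parallel")
  if (!identical(names(object@exons), as.character(object@txData$transcript_id)))
    msgs <- c(msgs, "exons must be named by transcript_id")
  need <- c("transcript_id", "organ", "replicate", "fpkm")
  if (!all(need %in% colnames(object@fpkm)))
    msgs <- c(msgs, "fpkm table must have transcript_id/organ/replicate/fpkm")
  if (length(object@exons)) {
    ns <- S4Vectors::elementNROWS(unique(
      GenomicRanges::seqnames(object@exons)))
    st <- S4Vectors::elementNROWS(unique(GenomicRanges::strand(object@exons)))
    if (any(ns != 1) || any(st != 1))
      msgs <- c(msgs, "each transcript's exons must share seqname and strand")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("length", "TranscriptSet", function(x) length(x@exons))

setMethod("show", "TranscriptSet", function(object) {
  cat("TranscriptSet with ", length(object), " transcript(s), ",
      length(unique(object@fpkm$organ)), " organ(s)\n", sep = "")
})

#' Position weight matrix with an acceptance threshold
#'
#' Log2-odds weights against a uniform background, plus the absolute score
#' threshold above which a window counts as a motif hit.
#'
#' @slot name motif name (e.g. \code{"U1"}, \code{"PAS"}).
#' @slot matrix 4 x L numeric, rows \code{A,C,G,T}, log2-odds vs 0.25.
#' @slot threshold minimum window score for a hit.
#' @seealso \code{\link{u1Matrix}}, \code{\link{pasMatrix}},
#'   \code{\link{scanMotif}}
#' @export
setClass("MotifMatrix",
  representation(name = "character", matrix = "matrix",
                 threshold = "numeric")
)

setValidity("MotifMatrix", function(object) {
  msgs <- character()
  if (!identical(rownames(object@matrix), c("A", "C", "G", "T")))
    msgs <- c(msgs, "matrix rows must be A,C,G,T")
  if (ncol(object@matrix) < 4)
    msgs <- c(msgs, "motif must have at least 4 positions")
  if (object@threshold > sum(apply(object@matrix, 2, max)) + 1e-9)
    msgs <- c(msgs, "threshold exceeds the maximum achievable score")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MotifMatrix", function(object) {
  cat("MotifMatrix '", object@name, "': ", ncol(object@matrix),
      " positions, threshold ", format(object@threshold, digits = 4),
      ", consensus ",
      paste(rownames(object@matrix)[apply(object@matrix, 2, which.max)],
            collapse = ""), "\n", sep = "")
})

#' @describeIn MotifMatrix motif length in positions
#' @param x a \code{MotifMatrix}
#' @export
setMethod("ncol", "MotifMatrix", function(x) ncol(x@matrix))
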