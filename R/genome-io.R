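## On-disk formats -> in-memory Bioconductor objects.
##
## Internal convention: all intervals are GRanges, i.e. 1-based closed
## coordinates. BED and narrowPeak are 0-based half-open on disk and are
## converted at this boundary (start + 1); GTF is 1-based closed already.
## Writers invert the conversion so read(write(x)) is the identity.
## All readers skip lines starting with '#' (used for seed provenance).

.read_tab <- function(path, n_min_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines)) &
    !grepl("^(track|browser)\\b", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(list(fields = list(), lineno = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < n_min_cols))
    stop(what, " parse error at line ", lineno[which(nf < n_min_cols)[1]],
         ": expected at least ", n_min_cols, " tab-separated columns")
  list(fields = fields, lineno = lineno)
}

.col <- function(fields, i) vapply(fields, `[[`, character(1), i)

.int_col <- function(fields, i, lineno, what) {
  raw <- .col(fields, i)
  val <- suppressWarnings(as.integer(raw))
  if (anyNA(val))
    stop(what, " parse error at line ", lineno[which(is.na(val))[1]],
         ": non-integer coordinate '", raw[which(is.na(val))[1]], "'")
  val
}

#' Read genomic intervals from BED or narrowPeak
#'
#' BED/narrowPeak coordinates (0-based half-open) are converted to GRanges
#' (1-based closed). For narrowPeak the 10th column becomes the
#' \code{summit_offset} metadata column (offset of the summit from the
#' interval start; \code{-1} on disk, meaning absent, becomes \code{NA}).
#' Strand \code{"."} becomes \code{"*"}.
#'
#' @param path file path.
#' @param format \code{"BED"} or \code{"narrowPeak"}.
#' @return \code{GRanges} with metadata columns \code{name}, \code{score}
#'   and, for narrowPeak, \code{summit_offset}.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t1000\tE1\t500\t+", p)
#' readIntervals(p)
#' @export
readIntervals <- function(path, format = c("BED", "narrowPeak")) {
  format <- match.arg(format)
  n_min <- if (format == "narrowPeak") 10L else 3L
  tb <- .read_tab(path, n_min, format)
  if (!length(tb$fields)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$name <- character()
    S4Vectors::mcols(gr)$score <- numeric()
    if (format == "narrowPeak")
      S4Vectors::mcols(gr)$summit_offset <- integer()
    return(gr)
  }
  f <- tb$fields
  start0 <- .int_col(f, 2, tb$lineno, format)
  end0 <- .int_col(f, 3, tb$lineno, format)
  bad <- start0 >= end0
  if (any(bad))
    stop(format, " parse error at line ", tb$lineno[which(bad)[1]],
         ": start >= end")
  nf <- lengths(f)
  name <- ifelse(nf >= 4, vapply(f, function(x)
    if (length(x) >= 4) x[[4]] else ".", character(1)), ".")
  score <- ifelse(nf >= 5, suppressWarnings(as.numeric(vapply(f, function(x)
    if (length(x) >= 5) x[[5]] else "0", character(1)))), 0)
  strand <- ifelse(nf >= 6, vapply(f, function(x)
    if (length(x) >= 6) x[[6]] else ".", character(1)), ".")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = .col(f, 1),
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand, name = name, score = score)
  if (format == "narrowPeak") {
    summit <- .int_col(f, 10, tb$lineno, format)
    summit[summit < 0] <- NA_integer_
    bad <- !is.na(summit) & summit >= GenomicRanges::width(gr)
    if (any(bad))
      stop("narrowPeak parse error at line ", tb$lineno[which(bad)[1]],
           ": summit offset outside peak")
    S4Vectors::mcols(gr)$summit_offset <- summit
  }
  gr
}

#' Write intervals as BED6 (or narrowPeak)
#'
#' The inverse of \code{\link{readIntervals}}: GRanges 1-based closed
#' coordinates are written 0-based half-open, in input order. An optional
#' \code{comment} line (prefixed \code{#}) records provenance such as the
#' generating seed.
#'
#' @param x \code{GRanges}; metadata columns \code{name}/\code{score}
#'   (\code{summit_offset} for narrowPeak) are used when present.
#' @param path output path.
#' @param format \code{"BED"} or \code{"narrowPeak"}.
#' @param comment optional comment string written as a \code{#} header.
#' @return invisibly, \code{path}.
#' @export
writeIntervals <- function(x, path, format = c("BED", "narrowPeak"),
                           comment = NULL) {
  format <- match.arg(format)
  mc <- S4Vectors::mcols(x)
  name <- if ("name" %in% colnames(mc)) as.character(mc$name)
          else rep(".", length(x))
  score <- if ("score" %in% colnames(mc)) mc$score else rep(0, length(x))
  strand <- as.character(GenomicRanges::strand(x))
  strand[strand == "*"] <- "."
  lines <- if (length(x) == 0) character(0) else
           paste(as.character(GenomicRanges::seqnames(x)),
                 format(GenomicRanges::start(x) - 1L, scientific = FALSE,
                        trim = TRUE),
                 format(GenomicRanges::end(x), scientific = FALSE,
                        trim = TRUE),
                 name,
                 format(score, scientific = FALSE, trim = TRUE),
                 strand, sep = "\t")
  if (format == "narrowPeak" && length(x) > 0) {
    summit <- if ("summit_offset" %in% colnames(mc)) mc$summit_offset
              else rep(NA_integer_, length(x))
    summit[is.na(summit)] <- -1L
    lines <- paste(lines, format(score, scientific = FALSE, trim = TRUE),
                   "-1", "-1",
                   format(summit, scientific = FALSE, trim = TRUE),
                   sep = "\t")
  }
  con <- file(path, "wb")  # binary: fixed '\n', byte-deterministic
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con, sep = "\n")
  if (length(lines)) writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read transcript models (GTF) with replicate expression (TSV)
#'
#' Exon features are taken from the GTF (1-based closed, the GRanges
#' convention, so no coordinate shift); expression is a long TSV with header
#' \code{transcript_id, organ, replicate, fpkm}. Transcripts without
#' expression rows get an empty FPKM mapping; expression rows for unknown
#' transcripts are dropped with a warning.
#'
#' @param path GTF file with \code{exon} features carrying
#'   \code{transcript_id} and \code{gene_id} attributes.
#' @param expressionPath TSV of per-replicate FPKM, or \code{NULL} for none.
#' @return a \code{\linkS4class{TranscriptSet}}.
#' @export
readTranscriptModels <- function(path, expressionPath = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("GTF exons must carry transcript_id attributes")
  gene <- if (!is.null(gr$gene_id)) gr$gene_id else gr$transcript_id
  strand_by_tx <- split(as.character(GenomicRanges::strand(gr)),
                        gr$transcript_id)
  ninc <- vapply(strand_by_tx, function(s) length(unique(s)), integer(1))
  if (any(ninc != 1))
    stop("strand-inconsistent exons for transcript ",
         names(strand_by_tx)[which(ninc != 1)[1]])
  keep <- S4Vectors::mcols(gr)[, c("transcript_id"), drop = FALSE]
  gr2 <- GenomicRanges::granges(gr)
  exons <- GenomicRanges::sort(
    GenomicRanges::split(gr2, keep$transcript_id))
  gene_by_tx <- vapply(split(as.character(gene), gr$transcript_id),
                       `[[`, character(1), 1)
  txData <- S4Vectors::DataFrame(
    transcript_id = names(exons),
    gene_id = unname(gene_by_tx[names(exons)]))
  fpkm <- data.frame(transcript_id = character(), organ = character(),
                     replicate = character(), fpkm = numeric())
  if (!is.null(expressionPath)) {
    fpkm <- utils::read.delim(expressionPath, header = TRUE,
                              comment.char = "#",
                              colClasses = c(transcript_id = "character",
                                             organ = "character",
                                             replicate = "character",
                                             fpkm = "numeric"))
    need <- c("transcript_id", "organ", "replicate", "fpkm")
    if (!all(need %in% colnames(fpkm)))
      stop("expression table must have columns ",
           paste(need, collapse = ", "))
    unknown <- !fpkm$transcript_id %in% names(exons)
    if (any(unknown)) {
      warning(sum(unknown), " expression row(s) for unknown transcripts ",
              "ignored")
      fpkm <- fpkm[!unknown, , drop = FALSE]
    }
  }
  new("TranscriptSet", exons = exons, txData = txData, fpkm = fpkm)
}

#' Read a FASTA file
#'
#' @param path FASTA path.
#' @return an uppercased \code{DNAStringSet}; duplicate record names are an
#'   error.
#' @export
readSequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA record name: ",
         names(seqs)[anyDuplicated(names(seqs))])
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Read an orthology block map from TSV
#'
#' Expected header columns: \code{src_chrom, src_start, src_end, tgt_chrom,
#' tgt_start, tgt_end, orientation}. Coordinates on disk are 0-based
#' half-open (BED-like) and converted to GRanges. Blocks must pair equal
#' lengths and be non-overlapping on the source.
#'
#' @param path TSV path.
#' @param sourceAssembly,targetAssembly optional assembly names (default:
#'   taken from the file name).
#' @return an \code{\linkS4class{OrthologyMap}}.
#' @export
readOrthologyMap <- function(path, sourceAssembly = "source",
                             targetAssembly = "target") {
  d <- utils::read.delim(path, header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("src_chrom", "src_start", "src_end",
            "tgt_chrom", "tgt_start", "tgt_end", "orientation")
  if (!all(need %in% colnames(d)))
    stop("orthology map must have columns ", paste(need, collapse = ", "))
  if (any((d$src_end - d$src_start) != (d$tgt_end - d$tgt_start)))
    stop("orthology map validation error: unequal block lengths")
  src <- GenomicRanges::GRanges(d$src_chrom,
    IRanges::IRanges(d$src_start + 1L, d$src_end))
  tgt <- GenomicRanges::GRanges(d$tgt_chrom,
    IRanges::IRanges(d$tgt_start + 1L, d$tgt_end))
  OrthologyMap(src, tgt, orientation = as.character(d$orientation),
               sourceAssembly = sourceAssembly,
               targetAssembly = targetAssembly)
}

#' Write an orthology block map as TSV
#'
#' Inverse of \code{\link{readOrthologyMap}} (coordinates written 0-based
#' half-open).
#'
#' @param map an \code{\linkS4class{OrthologyMap}}.
#' @param path output path.
#' @param comment optional \code{#} header comment.
#' @return invisibly, \code{path}.
#' @export
writeOrthologyMap <- function(map, path, comment = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con, sep = "\n")
  writeLines(paste(c("src_chrom", "src_start", "src_end", "tgt_chrom",
                     "tgt_start", "tgt_end", "orientation"),
                   collapse = "\t"), con, sep = "\n")
  if (length(map))
    writeLines(paste(as.character(GenomicRanges::seqnames(map@src)),
                     GenomicRanges::start(map@src) - 1L,
                     GenomicRanges::end(map@src),
                     as.character(GenomicRanges::seqnames(map@tgt)),
                     GenomicRanges::start(map@tgt) - 1L,
                     GenomicRanges::end(map@tgt),
                     map@orientation, sep = "\t"), con, sep = "\n")
  invisible(path)
}

#' Transcript genomic spans
#'
#' @param x a \code{\linkS4class{TranscriptSet}}.
#' @return \code{GRanges} named by transcript id covering each transcript
#'   from first exon start to last exon end (introns included).
#' @export
transcriptSpans <- function(x) {
  gr <- unlist(range(x@exons))
  S4Vectors::mcols(gr)$transcript_id <- names(gr)
  gr
}

#' Transcription start sites
#'
#' TSS is the first transcribed base: smallest exon start on \code{+},
#' largest exon end on \code{-}.
#'
#' @param x a \code{\linkS4class{TranscriptSet}}.
#' @return width-1 \code{GRanges} named by transcript id.
#' @export
tssRanges <- function(x) {
  sp <- transcriptSpans(x)
  GenomicRanges::resize(sp, width = 1L, fix = "start")
}

#' Mean FPKM per transcript in one organ
#'
#' @param x a \code{\linkS4class{TranscriptSet}}.
#' @param organ organ name.
#' @return named numeric vector over all transcripts; transcripts without
#'   expression rows in that organ get \code{NA}.
#' @export
meanFpkm <- function(x, organ) {
  out <- stats::setNames(rep(NA_real_, length(x)), names(x@exons))
  sub <- x@fpkm[x@fpkm$organ == organ, , drop = FALSE]
  if (nrow(sub)) {
    m <- tapply(sub$fpkm, sub$transcript_id, mean)
    out[names(m)] <- as.numeric(m)
  }
  out
}

#' Subset a TranscriptSet by transcript id
#'
#' @param x a \code{\linkS4class{TranscriptSet}}.
#' @param ids transcript ids to keep.
#' @return a \code{\linkS4class{TranscriptSet}}.
#' @export
subsetTranscripts <- function(x, ids) {
  keep <- names(x@exons) %in% ids
  new("TranscriptSet",
      exons = x@exons[keep],
      txData = x@txData[keep, , drop = FALSE],
      fpkm = x@fpkm[x@fpkm$transcript_id %in% ids, , drop = FALSE])
}
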