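# Shared fixture builders. Everything is generated in code; coordinates in
# comments are 1-based closed (the GRanges convention) unless marked BED.

gr <- function(chrom, start, end, strand = "*", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         strand = strand, ...)
}

peaks_gr <- function(chrom, start, end, score = 100,
                     summit_offset = NA_integer_, name = ".") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         name = name, score = score,
                         summit_offset = summit_offset)
}

# identity map over one or more chromosomes
identity_map <- function(chroms = "chr1", len = 100000L) {
  g <- gr(chroms, 1L, len)
  OrthologyMap(g, g, orientation = "+",
               sourceAssembly = "A", targetAssembly = "B")
}

# build a TranscriptSet by writing a tiny GTF + expression TSV and reading
# them back (also exercises the I/O layer).
# exons: data.frame(tx_id, gene_id, chrom, start, end, strand)
# fpkm:  data.frame(transcript_id, organ, replicate, fpkm) or NULL
make_txset <- function(exons, fpkm = NULL) {
  gtf <- tempfile(fileext = ".gtf")
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                   exons$gene_id, exons$tx_id)
  writeLines(paste(exons$chrom, "test", "exon", exons$start, exons$end,
                   ".", exons$strand, ".", attrs, sep = "\t"), gtf)
  expr <- NULL
  if (!is.null(fpkm)) {
    expr <- tempfile(fileext = ".tsv")
    utils::write.table(fpkm, expr, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  readTranscriptModels(gtf, expr)
}

# single stable transcript helper: one exon, given TSS geometry
stable_tx <- function(tx_id, chrom, strand, tss, span = 2000L,
                      organ = "liver", fpkm = 10) {
  if (strand == "+") {
    ex <- data.frame(tx_id = tx_id, gene_id = paste0("g_", tx_id),
                     chrom = chrom, start = tss, end = tss + span - 1L,
                     strand = strand)
  } else {
    ex <- data.frame(tx_id = tx_id, gene_id = paste0("g_", tx_id),
                     chrom = chrom, start = tss - span + 1L, end = tss,
                     strand = strand)
  }
  list(exons = ex,
       fpkm = data.frame(transcript_id = tx_id, organ = organ,
                         replicate = c("r1", "r2"), fpkm = fpkm))
}

txset_from <- function(...) {
  parts <- list(...)
  make_txset(do.call(rbind, lapply(parts, `[[`, "exons")),
             do.call(rbind, lapply(parts, `[[`, "fpkm")))
}

# small synthetic clade shared by generator/pipeline tests (~45 tiles)
small_clade_config <- function(seed = 11L, ...) {
  syntheticConfig(seed = seed, n_chromosomes = 1L,
                  chrom_length = 400000L, n_promoters = 8L,
                  n_enhancers = 16L, n_inactive = 6L, n_planted_pe = 12L,
                  n_bivalent_decoys = 2L, n_unstable = 2L, ...)
}

# independent brute-force motif scanner (oracle): scores every offset on
# both strands with plain arithmetic
brute_force_scan <- function(sequence, motif) {
  ch <- strsplit(toupper(as.character(sequence)), "")[[1]]
  L <- length(ch)
  m <- motif@matrix
  k <- ncol(m)
  rc <- m[c("T", "G", "C", "A"), rev(seq_len(k)), drop = FALSE]
  rownames(rc) <- c("A", "C", "G", "T")
  idx <- match(ch, c("A", "C", "G", "T"))
  offs <- seq_len(L - k + 1)
  score_all <- function(mm) {
    s <- rep(0, length(offs))
    for (i in seq_len(k)) s <- s + mm[cbind(idx[offs + i - 1L], i)]
    s
  }
  sf <- score_all(m)
  sr <- score_all(rc)
  fw <- which(!is.na(sf) & sf >= motif@threshold)
  rv <- which(!is.na(sr) & sr >= motif@threshold)
  out <- rbind(
    if (length(fw)) data.frame(start = fw, strand = "+",
                               score = sf[fw]) else NULL,
    if (length(rv)) data.frame(start = rv, strand = "-",
                               score = sr[rv]) else NULL)
  if (is.null(out))
    return(data.frame(start = integer(), strand = character(),
                      score = numeric()))
  out[order(out$start, out$strand), , drop = FALSE]
}

# exact two-sided Fisher p by hypergeometric point-probability summation
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
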