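## Synthetic three-species clade generator.
##
## Species A and B are sisters; O is the outgroup. Genomes are i.i.d.
## background sequence at a configurable GC; B and O start as copies of A
## and receive composition-preserving substitutions, so orthologous
## composition differences are centred on zero before planting. Elements
## occupy disjoint 8-kb tiles so that the 1000-nt exclusion rules of the
## annotation step cannot couple neighbouring plantings. Orthology maps
## default to one identity block per chromosome (noise-free regime);
## mutateMap() introduces block breaks and deletions.
##
## Planted element classes (tile types):
##   pe                  A enhancer chromatin; B stable transcript whose
##                       TSS-upstream 500 nt overlap the site; outgroup
##                       state enhancer/promoter/none per config; CpG
##                       planted on the B site; U1/PAS planted downstream
##                       of both TSS copies at class-specific rates.
##   enh_conserved       enhancer chromatin in A, B and O.
##   enh_lost            enhancer chromatin in A and O only.
##   enh_private         enhancer chromatin in A only.
##   prom_conserved      stable transcript (+H3K4me3, DHS) in A, B and O.
##   prom_lost           stable transcript in A and O only.
##   prom_private        stable transcript in A only.
##   bivalent_decoy      A enhancer chromatin with H3K4me3 within 1000 nt
##                       (must be excluded by the enhancer caller).
##   unstable            transcripts failing the stability rule (low FPKM
##                       in A, short span in B).

.TILE <- 8000L
.SITE_OFF <- 3500L  # element site occupies [tile+3501, tile+4500]

#' Synthetic clade configuration
#'
#' Defaults define the simulated study conditions: 50 planted P/E events
#' among 70 species-A enhancers, a +0.02 CpG-frequency shift on the
#' promoter side, downstream U1 densities of 3.0/kb (promoter side) vs
#' 2.0/kb (enhancer side) and PAS densities of 1.45 vs 1.70/kb, outgroup
#' ancestral states drawn as 41\% enhancer / 1.5\% promoter / 57.5\% none,
#' and noise-free orthology maps.
#'
#' @param ... named overrides of any default.
#' @return a named list (validated).
#' @export
syntheticConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    n_chromosomes = 2L,
    chrom_length = 1200000L,
    n_promoters = 40L,
    n_enhancers = 70L,
    n_inactive = 40L,
    n_planted_pe = 50L,
    pe_extended_fraction = 0.4,
    pe_cpg_shift = 0.02,
    u1_downstream_rate_promoter = 3.0,
    u1_downstream_rate_enhancer = 2.0,
    pas_rate_promoter = 1.45,
    pas_rate_enhancer = 1.70,
    ancestral_state_probs = c(promoter = 0.015, enhancer = 0.41,
                              none = 0.575),
    substitution_rate = 0.05,
    block_break_rate = 0,
    fpkm_meanlog = 2.0,
    fpkm_sdlog = 0.4,
    organs = "liver",
    n_replicates = 3L,
    gc_background = 0.41,
    n_bivalent_decoys = 5L,
    n_unstable = 5L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  rates <- c(cfg$u1_downstream_rate_promoter,
             cfg$u1_downstream_rate_enhancer,
             cfg$pas_rate_promoter, cfg$pas_rate_enhancer,
             cfg$substitution_rate, cfg$block_break_rate)
  stopifnot(all(rates >= 0), cfg$n_planted_pe > 0,
            cfg$n_planted_pe <= cfg$n_enhancers,
            cfg$pe_extended_fraction >= 0, cfg$pe_extended_fraction <= 1,
            cfg$gc_background > 0, cfg$gc_background < 1)
  cfg
}

.random_genome <- function(n_chrom, len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- vapply(seq_len(n_chrom), function(i)
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
    character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  seqs
}

.substitute <- function(seqs, rate, gc) {
  # composition-preserving: substituted bases are redrawn from the
  # background distribution, so expected GC/CpG drift is ~zero
  if (rate <= 0) return(seqs)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seqs, function(s) {
    L <- nchar(s)
    n <- stats::rbinom(1, L, rate)
    if (n == 0) return(s)
    pos <- sample.int(L, n)
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- sample(names(p), n, replace = TRUE, prob = p)
    paste(ch, collapse = "")
  }, character(1))
}

.plant_string <- function(seqs, chrom, start, what) {
  s <- seqs[[chrom]]
  substr(s, start, start + nchar(what) - 1L) <- what
  seqs[[chrom]] <- s
  seqs
}

.plant_cpg <- function(seqs, chrom, start, end, add_freq) {
  # raise the CG dinucleotide frequency of [start, end] by add_freq via
  # targeted substitutions; returns list(seqs, added)
  L <- end - start + 1L
  need <- round(add_freq * (L - 1L))
  if (need <= 0) return(list(seqs = seqs, added = 0L))
  region <- substr(seqs[[chrom]], start, end)
  ch <- strsplit(region, "")[[1]]
  is_cg <- function(i) i >= 1 && i <= L - 1 && ch[i] == "C" &&
    ch[i + 1] == "G"
  # positions covered by U1/PAS word occurrences (either strand) are
  # off-limits so that composition planting never shifts motif counts
  motif_cover <- rep(FALSE, L)
  for (w in c("GTAAGT", "ACTTAC", "AATAAA", "TTTATT")) {
    m <- gregexpr(w, region, fixed = TRUE)[[1]]
    if (m[1] != -1)
      for (p in m) motif_cover[p:min(L, p + 5L)] <- TRUE
  }
  # candidate offsets where writing CG neither overlaps an existing CG
  # nor destroys one in the 3-window neighbourhood, nor touches a motif
  cand <- which(vapply(seq_len(L - 1L), function(i)
    !is_cg(i) && !is_cg(i - 1L) && !is_cg(i + 1L) &&
      !motif_cover[i] && !motif_cover[i + 1L], logical(1)))
  cand <- sample(cand)
  placed <- integer(0)
  for (i in cand) {
    if (length(placed) >= need) break
    if (any(abs(placed - i) < 3L)) next
    placed <- c(placed, i)
  }
  for (i in placed) {
    ch[i] <- "C"
    ch[i + 1L] <- "G"
  }
  seqs[[chrom]] <- paste0(substr(seqs[[chrom]], 1, start - 1L),
                          paste(ch, collapse = ""),
                          substr(seqs[[chrom]], end + 1L,
                                 nchar(seqs[[chrom]])))
  list(seqs = seqs, added = length(placed))
}

.plant_motifs <- function(seqs, chrom, start, end, strand, n_u1, n_pas) {
  # plant exact consensus strings at non-overlapping positions inside
  # [start, end]; reverse-complemented on '-' so the sense strand reads
  # the consensus. Returns list(seqs, n_u1, n_pas) actually placed.
  u1 <- if (strand == "-") "ACTTAC" else "GTAAGT"
  pas <- if (strand == "-") "TTTATT" else "AATAAA"
  width <- 6L
  total <- n_u1 + n_pas
  if (total == 0) return(list(seqs = seqs, n_u1 = 0L, n_pas = 0L))
  slots <- start:(end - width + 1L)
  placed <- integer(0)
  kinds <- sample(rep(c("u1", "pas"), c(n_u1, n_pas)))
  got_u1 <- 0L
  got_pas <- 0L
  for (k in kinds) {
    ok <- slots[vapply(slots, function(p)
      !length(placed) || all(abs(placed - p) >= width), logical(1))]
    if (!length(ok)) break
    p <- if (length(ok) == 1) ok else sample(ok, 1)
    placed <- c(placed, p)
    seqs <- .plant_string(seqs, chrom, p, if (k == "u1") u1 else pas)
    if (k == "u1") got_u1 <- got_u1 + 1L else got_pas <- got_pas + 1L
  }
  list(seqs = seqs, n_u1 = got_u1, n_pas = got_pas)
}

.peak <- function(chrom, start, end, name, score) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                         name = name, score = score,
                         summit_offset = (end - start + 1L) %/% 2L)
}

#' Split and erode an orthology map
#'
#' Introduces Poisson-distributed block breaks (expected
#' \code{blockBreakRate} breaks per source base); each break deletes a
#' short geometric stretch (mean 50 nt) from the source coverage, so the
#' total mapped source length never increases. Rate 0 returns the map
#' unchanged.
#'
#' @param map an \code{\linkS4class{OrthologyMap}}.
#' @param blockBreakRate expected breaks per source base.
#' @param seed integer seed.
#' @return an \code{\linkS4class{OrthologyMap}}.
#' @export
mutateMap <- function(map, blockBreakRate, seed = 1) {
  if (blockBreakRate <= 0) return(map)
  set.seed(seed)
  rows <- list()
  for (b in seq_along(map@src)) {
    s1 <- GenomicRanges::start(map@src)[b]
    s2 <- GenomicRanges::end(map@src)[b]
    t1 <- GenomicRanges::start(map@tgt)[b]
    t2 <- GenomicRanges::end(map@tgt)[b]
    ori <- map@orientation[b]
    schr <- as.character(GenomicRanges::seqnames(map@src))[b]
    tchr <- as.character(GenomicRanges::seqnames(map@tgt))[b]
    w <- s2 - s1 + 1L
    nb <- stats::rpois(1, blockBreakRate * w)
    nb <- min(nb, w - 1L)
    if (nb <= 0) {
      rows <- c(rows, list(data.frame(schr = schr, ss = s1, se = s2,
                                      tchr = tchr, ts = t1, te = t2,
                                      ori = ori)))
      next
    }
    cuts <- sort(sample.int(w - 1L, nb))
    bounds <- c(0L, cuts, w)  # segment k covers offsets
                              # [bounds[k], bounds[k+1]-1]
    dels <- 1L + stats::rgeom(nb, 1 / 50)
    for (k in seq_len(length(bounds) - 1L)) {
      off1 <- bounds[k]
      off2 <- bounds[k + 1L] - 1L
      if (k > 1L) off1 <- off1 + dels[k - 1L]  # erode after each break
      if (off1 > off2) next
      ss <- s1 + off1
      se <- s1 + off2
      if (ori == "+") {
        ts <- t1 + off1
        te <- t1 + off2
      } else {
        ts <- t2 - off2
        te <- t2 - off1
      }
      rows <- c(rows, list(data.frame(schr = schr, ss = ss, se = se,
                                      tchr = tchr, ts = ts, te = te,
                                      ori = ori)))
    }
  }
  d <- do.call(rbind, rows)
  OrthologyMap(
    GenomicRanges::GRanges(d$schr, IRanges::IRanges(d$ss, d$se)),
    GenomicRanges::GRanges(d$tchr, IRanges::IRanges(d$ts, d$te)),
    orientation = d$ori,
    sourceAssembly = map@sourceAssembly,
    targetAssembly = map@targetAssembly)
}

.write_gtf <- function(tx_exons, path, comment) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("#!", comment), con, sep = "\n")
  if (nrow(tx_exons)) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx_exons$gene_id, tx_exons$tx_id)
    writeLines(paste(tx_exons$chrom, "synth", "exon",
                     tx_exons$start, tx_exons$end, ".",
                     tx_exons$strand, ".", attrs, sep = "\t"),
               con, sep = "\n")
  }
  invisible(path)
}

.write_tsv <- function(df, path, comment) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con, sep = "\n")
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    rows <- do.call(paste, c(lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col))
        sprintf("%.6g", col)
      else as.character(col)
    }), sep = "\t"))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}

.species_state <- function() {
  list(peaks = list(dhs = list(), k27ac = list(), k4me1 = list(),
                    k4me3 = list()),
       exons = list(),   # data.frames: tx_id gene_id chrom start end strand
       fpkm_class = list())  # tx_id -> "stable"/"low"/"short_stable"
}

.add_peak <- function(st, mark, chrom, start, end, name, score) {
  st$peaks[[mark]] <- c(st$peaks[[mark]],
                        list(data.frame(chrom = chrom, start = start,
                                        end = end, name = name,
                                        score = score)))
  st
}

.add_tx <- function(st, tx_id, gene_id, chrom, strand, exon_starts,
                    exon_ends, fclass) {
  st$exons <- c(st$exons,
                list(data.frame(tx_id = tx_id, gene_id = gene_id,
                                chrom = chrom, start = exon_starts,
                                end = exon_ends, strand = strand)))
  st$fpkm_class[[tx_id]] <- fclass
  st
}

#' Generate a synthetic three-species clade with planted repurposing
#'
#' Emits, per species (A and B sisters, O outgroup): a FASTA genome, a GTF
#' of transcript exons, a per-replicate FPKM table, replicate narrowPeak
#' files for DHS/H3K27ac/H3K4me1/H3K4me3, and a (possibly empty) mask BED;
#' plus pairwise orthology maps (A-B, B-A, A-O, B-O), a ground-truth
#' ledger (\code{truth.tsv}) and a file manifest with MD5 digests
#' (\code{manifest.tsv}). Identical seeds give byte-identical output.
#'
#' @param config list from \code{\link{syntheticConfig}}.
#' @param outDir output directory (created).
#' @return invisibly, a list with \code{dir}, \code{truth} (data.frame,
#'   1-based inclusive coordinates), \code{config}, and the per-species
#'   subdirectory paths.
#' @export
generateCladeDataset <- function(config = syntheticConfig(),
                                 outDir = tempfile("clade")) {
  cfg <- config
  set.seed(cfg$seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (sp in c("speciesA", "speciesB", "speciesO"))
    dir.create(file.path(outDir, sp), showWarnings = FALSE)

  ## genomes: B and O are substituted copies of A
  genA <- .random_genome(cfg$n_chromosomes, cfg$chrom_length,
                         cfg$gc_background)
  genB <- .substitute(genA, cfg$substitution_rate, cfg$gc_background)
  genO <- .substitute(genA, cfg$substitution_rate, cfg$gc_background)

  ## tile allocation
  per_chrom <- (cfg$chrom_length - .TILE) %/% .TILE  # keep 1 tile margin
  tiles <- do.call(rbind, lapply(seq_len(cfg$n_chromosomes), function(i)
    data.frame(chrom = paste0("chr", i),
               t0 = (seq_len(per_chrom) - 1L) * .TILE + 1L)))
  n_enh_rest <- cfg$n_enhancers - cfg$n_planted_pe
  counts <- c(pe = cfg$n_planted_pe,
              enh_conserved = round(0.4 * n_enh_rest),
              enh_lost = round(0.4 * n_enh_rest))
  counts["enh_private"] <- n_enh_rest - counts["enh_conserved"] -
    counts["enh_lost"]
  counts <- c(counts,
              prom_conserved = round(0.5 * cfg$n_promoters),
              prom_lost = round(0.3 * cfg$n_promoters))
  counts["prom_private"] <- cfg$n_promoters - counts["prom_conserved"] -
    counts["prom_lost"]
  counts <- c(counts, inactive = cfg$n_inactive,
              bivalent_decoy = cfg$n_bivalent_decoys,
              unstable = cfg$n_unstable)
  if (sum(counts) > nrow(tiles))
    stop("cannot place ", sum(counts), " elements in ", nrow(tiles),
         " tiles; increase chrom_length or n_chromosomes")
  tile_idx <- sample.int(nrow(tiles), sum(counts))
  classes <- rep(names(counts), counts)
  layout <- tiles[tile_idx, ]
  layout$class <- classes
  layout$strand <- sample(c("+", "-"), nrow(layout), replace = TRUE)

  ## PE event attributes
  pe_rows <- which(layout$class == "pe")
  n_pe <- length(pe_rows)
  n_ext <- round(cfg$pe_extended_fraction * n_pe)
  pe_category <- sample(rep(c("extended", "novel"),
                            c(n_ext, n_pe - n_ext)))
  pr <- cfg$ancestral_state_probs
  n_anc_pro <- round(pr[["promoter"]] * n_pe)
  n_anc_enh <- round(pr[["enhancer"]] * n_pe)
  pe_ancestral <- sample(rep(c("promoter", "enhancer", "none"),
                             c(n_anc_pro, n_anc_enh,
                               n_pe - n_anc_pro - n_anc_enh)))

  A <- .species_state()
  B <- .species_state()
  O <- .species_state()
  truth <- list()
  pe_i <- 0L

  for (r in seq_len(nrow(layout))) {
    cls <- layout$class[r]
    chrom <- layout$chrom[r]
    t0 <- layout$t0[r]
    sg <- layout$strand[r]
    s <- t0 + .SITE_OFF  # site = [s, s + 999]
    se <- s + 999L
    eid <- sprintf("%s_%03d", cls, r)
    score <- 1000 - r  # unique, deterministic ranking
    tr <- list(element_id = eid, class = cls, category = NA,
               strand = sg, chrom = chrom,
               a_start = NA, a_end = NA, b_start = NA, b_end = NA,
               o_start = NA, o_end = NA, b_tss = NA, a_tss = NA,
               ancestral_state = NA, b_transcript_id = NA,
               delta_cpg = NA, u1_down_b = NA, u1_down_a = NA,
               pas_down_b = NA, pas_down_a = NA)

    plant_enh_marks <- function(st, with_k4me1) {
      st <- .add_peak(st, "dhs", chrom, s, se, eid, score)
      st <- .add_peak(st, "k27ac", chrom, s, se, eid, score)
      if (with_k4me1) st <- .add_peak(st, "k4me1", chrom, s, se, eid,
                                      score)
      st
    }
    plant_prom <- function(st, t, tx_id, fclass = "stable") {
      if (sg == "+") {
        st <- .add_tx(st, tx_id, paste0("g_", tx_id), chrom, "+",
                      t, t + 1999L, fclass)
        win <- c(t - 1000L, t - 1L)
      } else {
        st <- .add_tx(st, tx_id, paste0("g_", tx_id), chrom, "-",
                      t - 1999L, t, fclass)
        win <- c(t + 1L, t + 1000L)
      }
      st <- .add_peak(st, "k4me3", chrom, win[1], win[2], tx_id, score)
      st <- .add_peak(st, "dhs", chrom, win[1], win[2], tx_id, score)
      st
    }

    if (cls == "pe") {
      pe_i <- pe_i + 1L
      cat_i <- pe_category[pe_i]
      anc_i <- pe_ancestral[pe_i]
      t <- if (sg == "+") se + 1L else s - 1L
      A <- plant_enh_marks(A, with_k4me1 = (r %% 2 == 0))
      txid <- paste0("txB_", eid)
      if (sg == "+") {
        B <- .add_tx(B, txid, paste0("g_", txid), chrom, "+",
                     t, t + 1999L, "stable")
      } else {
        B <- .add_tx(B, txid, paste0("g_", txid), chrom, "-",
                     t - 1999L, t, "stable")
      }
      if (cat_i == "extended") {
        shid_a <- paste0("txA_sh_", eid)
        shid_b <- paste0("txB_sh_", eid)
        if (sg == "+") {
          A <- .add_tx(A, shid_a, paste0("g_sh_", eid), chrom, "+",
                       t + 1200L, t + 2999L, "stable")
          B <- .add_tx(B, shid_b, paste0("g_sh_", eid), chrom, "+",
                       t + 1200L, t + 2999L, "stable")
        } else {
          A <- .add_tx(A, shid_a, paste0("g_sh_", eid), chrom, "-",
                       t - 2999L, t - 1200L, "stable")
          B <- .add_tx(B, shid_b, paste0("g_sh_", eid), chrom, "-",
                       t - 2999L, t - 1200L, "stable")
        }
      }
      if (anc_i == "enhancer") {
        O <- .add_peak(O, "k27ac", chrom, s, se, eid, score)
        tr$o_start <- s; tr$o_end <- se
      } else if (anc_i == "promoter") {
        O <- plant_prom(O, t, paste0("txO_", eid))
        tr$o_start <- s; tr$o_end <- se
      }
      ## composition shift on the promoter-side (B) site
      pc <- .plant_cpg(genB, chrom, s, se, cfg$pe_cpg_shift)
      genB <- pc$seqs
      tr$delta_cpg <- pc$added / 999
      ## U1/PAS downstream of both TSS copies
      dwin <- if (sg == "+") c(t, t + 999L) else c(t - 999L, t)
      mb <- .plant_motifs(genB, chrom, dwin[1], dwin[2], sg,
                          stats::rpois(1, cfg$u1_downstream_rate_promoter),
                          stats::rpois(1, cfg$pas_rate_promoter))
      genB <- mb$seqs
      ma <- .plant_motifs(genA, chrom, dwin[1], dwin[2], sg,
                          stats::rpois(1, cfg$u1_downstream_rate_enhancer),
                          stats::rpois(1, cfg$pas_rate_enhancer))
      genA <- ma$seqs
      tr$category <- cat_i
      tr$ancestral_state <- anc_i
      tr$a_start <- s; tr$a_end <- se
      tr$b_start <- s; tr$b_end <- se
      tr$b_tss <- t; tr$a_tss <- t
      tr$b_transcript_id <- txid
      tr$u1_down_b <- mb$n_u1; tr$u1_down_a <- ma$n_u1
      tr$pas_down_b <- mb$n_pas; tr$pas_down_a <- ma$n_pas
    } else if (cls %in% c("enh_conserved", "enh_lost", "enh_private")) {
      A <- plant_enh_marks(A, with_k4me1 = (r %% 2 == 0))
      tr$a_start <- s; tr$a_end <- se
      if (cls == "enh_conserved") {
        B <- .add_peak(B, "dhs", chrom, s, se, eid, score)
        B <- .add_peak(B, "k27ac", chrom, s, se, eid, score)
        tr$b_start <- s; tr$b_end <- se
      }
      if (cls %in% c("enh_conserved", "enh_lost")) {
        O <- .add_peak(O, "k27ac", chrom, s, se, eid, score)
        tr$o_start <- s; tr$o_end <- se
        tr$ancestral_state <- "enhancer"
      }
    } else if (cls %in% c("prom_conserved", "prom_lost",
                          "prom_private")) {
      t <- t0 + 4500L
      A <- plant_prom(A, t, paste0("txA_", eid))
      tr$a_tss <- t
      if (sg == "+") { tr$a_start <- t - 1000L; tr$a_end <- t - 1L }
      else { tr$a_start <- t + 1L; tr$a_end <- t + 1000L }
      if (cls == "prom_conserved") {
        B <- plant_prom(B, t, paste0("txB_", eid))
        tr$b_tss <- t
      }
      if (cls %in% c("prom_conserved", "prom_lost")) {
        O <- plant_prom(O, t, paste0("txO_", eid))
        tr$ancestral_state <- "promoter"
        tr$o_start <- tr$a_start; tr$o_end <- tr$a_end
      }
    } else if (cls == "bivalent_decoy") {
      A <- plant_enh_marks(A, with_k4me1 = TRUE)
      A <- .add_peak(A, "k4me3", chrom, se + 201L, se + 1200L, eid,
                     score)
      tr$a_start <- s; tr$a_end <- se
    } else if (cls == "unstable") {
      t <- t0 + 4500L
      if (sg == "+") {
        A <- .add_tx(A, paste0("txA_", eid), paste0("gA_", eid), chrom,
                     "+", t, t + 1999L, "low")
        B <- .add_tx(B, paste0("txB_", eid), paste0("gB_", eid), chrom,
                     "+", t, t + 799L, "short_stable")
      } else {
        A <- .add_tx(A, paste0("txA_", eid), paste0("gA_", eid), chrom,
                     "-", t - 1999L, t, "low")
        B <- .add_tx(B, paste0("txB_", eid), paste0("gB_", eid), chrom,
                     "-", t - 799L, t, "short_stable")
      }
      tr$a_tss <- t
    }
    truth <- c(truth, list(tr))
  }

  truth <- do.call(rbind, lapply(truth, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))

  ## expression tables
  make_expr <- function(st) {
    ids <- names(st$fpkm_class)
    rows <- list()
    for (id in ids) {
      fclass <- st$fpkm_class[[id]]
      mu <- switch(fclass,
                   stable = exp(stats::rnorm(1, cfg$fpkm_meanlog,
                                             cfg$fpkm_sdlog)),
                   short_stable = exp(stats::rnorm(1, cfg$fpkm_meanlog,
                                                   cfg$fpkm_sdlog)),
                   low = 0.3)
      for (org in cfg$organs) {
        reps <- mu * exp(stats::rnorm(cfg$n_replicates, 0,
                                      cfg$fpkm_sdlog) -
                         cfg$fpkm_sdlog^2 / 2)
        m <- mean(reps)
        if (fclass %in% c("stable", "short_stable") && m < 2)
          reps <- reps * (2 / m)      # planted stability is exact
        if (fclass == "low" && m > 0.5)
          reps <- reps * (0.5 / m)    # planted instability is exact
        rows <- c(rows, list(data.frame(
          transcript_id = id, organ = org,
          replicate = paste0("r", seq_len(cfg$n_replicates)),
          fpkm = reps)))
      }
    }
    if (!length(rows))
      return(data.frame(transcript_id = character(), organ = character(),
                        replicate = character(), fpkm = numeric()))
    do.call(rbind, rows)
  }

  seed_note <- paste0("seed=", cfg$seed)
  write_species <- function(st, gen, dir) {
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(unlist(gen)),
      file.path(dir, "genome.fa"), width = 80)
    ex <- if (length(st$exons)) do.call(rbind, st$exons) else
      data.frame(tx_id = character(), gene_id = character(),
                 chrom = character(), start = integer(), end = integer(),
                 strand = character())
    colnames(ex)[colnames(ex) == "tx_id"] <- "tx_id"
    ex <- ex[order(ex$chrom, ex$start), , drop = FALSE]
    names(ex)[names(ex) == "gene_id"] <- "gene_id"
    .write_gtf(data.frame(tx_id = ex$tx_id, gene_id = ex$gene_id,
                          chrom = ex$chrom, start = ex$start,
                          end = ex$end, strand = ex$strand),
               file.path(dir, "transcripts.gtf"), seed_note)
    .write_tsv(make_expr(st), file.path(dir, "expression.tsv"), seed_note)
    for (mark in names(st$peaks)) {
      pk <- st$peaks[[mark]]
      gr <- if (length(pk)) {
        d <- do.call(rbind, pk)
        d <- d[order(d$chrom, d$start), , drop = FALSE]
        GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start, d$end),
                               name = d$name, score = d$score,
                               summit_offset = 500L)
      } else GenomicRanges::GRanges()
      for (rep in seq_len(cfg$n_replicates))
        writeIntervals(gr,
                       file.path(dir, sprintf("%s_rep%d.narrowPeak",
                                              mark, rep)),
                       format = "narrowPeak", comment = seed_note)
    }
    writeIntervals(GenomicRanges::GRanges(),
                   file.path(dir, "masks.bed"), comment = seed_note)
  }
  write_species(A, genA, file.path(outDir, "speciesA"))
  write_species(B, genB, file.path(outDir, "speciesB"))
  write_species(O, genO, file.path(outDir, "speciesO"))

  ## orthology maps: identity blocks, optionally eroded
  ident <- function(srcA, tgtA) {
    gr <- GenomicRanges::GRanges(
      paste0("chr", seq_len(cfg$n_chromosomes)),
      IRanges::IRanges(1L, cfg$chrom_length))
    OrthologyMap(gr, gr, orientation = "+",
                 sourceAssembly = srcA, targetAssembly = tgtA)
  }
  map_ab <- ident("speciesA", "speciesB")
  map_ao <- ident("speciesA", "speciesO")
  map_bo <- ident("speciesB", "speciesO")
  if (cfg$block_break_rate > 0) {
    map_ab <- mutateMap(map_ab, cfg$block_break_rate,
                        seed = (cfg$seed * 7 + 1) %% 2147483647)
    map_ao <- mutateMap(map_ao, cfg$block_break_rate,
                        seed = (cfg$seed * 7 + 2) %% 2147483647)
    map_bo <- mutateMap(map_bo, cfg$block_break_rate,
                        seed = (cfg$seed * 7 + 3) %% 2147483647)
  }
  writeOrthologyMap(map_ab, file.path(outDir, "map_A_B.tsv"), seed_note)
  writeOrthologyMap(invertMap(map_ab), file.path(outDir, "map_B_A.tsv"),
                    seed_note)
  writeOrthologyMap(map_ao, file.path(outDir, "map_A_O.tsv"), seed_note)
  writeOrthologyMap(map_bo, file.path(outDir, "map_B_O.tsv"), seed_note)

  .write_tsv(truth, file.path(outDir, "truth.tsv"),
             paste0(seed_note, " coordinates are 1-based inclusive"))

  ## manifest with digests and config hash
  cfg_file <- tempfile()
  writeLines(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 12), collapse = ","), character(1)),
    sep = "="), cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  files <- sort(setdiff(list.files(outDir, recursive = TRUE),
                        "manifest.tsv"))
  man <- data.frame(file = files,
                    md5 = unname(tools::md5sum(file.path(outDir, files))),
                    seed = cfg$seed, config_hash = cfg_hash)
  .write_tsv(man, file.path(outDir, "manifest.tsv"), NULL)

  invisible(list(dir = outDir, truth = truth, config = cfg,
                 species_dirs = file.path(outDir,
                   c("speciesA", "speciesB", "speciesO"))))
}
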