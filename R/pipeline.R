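## End-to-end orchestration: load (or simulate) a clade bundle, annotate
## each species, detect and classify P/E elements, polarize against the
## outgroup, run the composition and motif-axis analyses, and write a
## count-auditable report. Every stage is a pure function of (inputs,
## config, seed); the manifest digests make determinism checkable.

#' Load one species' file bundle
#'
#' @param dir species directory as written by
#'   \code{\link{generateCladeDataset}} (genome.fa, transcripts.gtf,
#'   expression.tsv, \code{<mark>_rep<k>.narrowPeak}, masks.bed).
#' @return list: \code{genome} (DNAStringSet), \code{seqlengths},
#'   \code{transcripts} (\code{\linkS4class{TranscriptSet}}),
#'   \code{peaks} (list of per-mark lists of replicate \code{GRanges}),
#'   \code{masks}.
#' @export
loadSpeciesData <- function(dir) {
  genome <- readSequences(file.path(dir, "genome.fa"))
  seqlengths <- stats::setNames(Biostrings::width(genome), names(genome))
  tx <- readTranscriptModels(file.path(dir, "transcripts.gtf"),
                             file.path(dir, "expression.tsv"))
  marks <- c("dhs", "k27ac", "k4me1", "k4me3")
  peaks <- lapply(marks, function(mark) {
    files <- sort(list.files(dir, pattern = paste0("^", mark,
                                                   "_rep\\d+\\.narrowPeak$"),
                             full.names = TRUE))
    lapply(files, readIntervals, format = "narrowPeak")
  })
  names(peaks) <- marks
  masks <- if (file.exists(file.path(dir, "masks.bed")))
    readIntervals(file.path(dir, "masks.bed")) else
    GenomicRanges::GRanges()
  list(genome = genome, seqlengths = seqlengths, transcripts = tx,
       peaks = peaks, masks = masks)
}

.harmonize_species <- function(sp, config) {
  list(
    dhs = harmonizePeakReplicates(sp$peaks$dhs, topN = 10000000,
                                  size = config$peak_resize,
                                  seqlengths = sp$seqlengths),
    k27ac = harmonizePeakReplicates(sp$peaks$k27ac,
                                    topN = config$k27ac_top_n,
                                    size = config$peak_resize,
                                    seqlengths = sp$seqlengths),
    k4me1 = harmonizePeakReplicates(sp$peaks$k4me1,
                                    topN = config$k4me1_top_n,
                                    size = config$peak_resize,
                                    seqlengths = sp$seqlengths),
    k4me3 = harmonizePeakReplicates(sp$peaks$k4me3,
                                    topN = config$k4me3_top_n,
                                    size = config$peak_resize,
                                    seqlengths = sp$seqlengths))
}

.map_tss_position <- function(map, chrom, pos, tolerance = 50L) {
  # project a single TSS base; when the exact base is unmapped, use the
  # nearest mapped base within `tolerance` nt, else NA
  src <- map@src
  on_chr <- which(as.character(GenomicRanges::seqnames(src)) == chrom)
  if (!length(on_chr)) return(NULL)
  s1 <- GenomicRanges::start(src)[on_chr]
  s2 <- GenomicRanges::end(src)[on_chr]
  inside <- which(s1 <= pos & pos <= s2)
  use_pos <- pos
  if (!length(inside)) {
    d_left <- pos - s2
    d_right <- s1 - pos
    d <- pmin(ifelse(d_left > 0, d_left, Inf),
              ifelse(d_right > 0, d_right, Inf))
    j <- which.min(d)
    if (d[j] > tolerance) return(NULL)
    use_pos <- if (d_left[j] > 0) s2[j] else s1[j]
    inside <- j
  }
  b <- on_chr[inside[1]]
  off <- use_pos - GenomicRanges::start(src)[b]
  if (map@orientation[b] == "+")
    list(chrom = as.character(GenomicRanges::seqnames(map@tgt))[b],
         pos = GenomicRanges::start(map@tgt)[b] + off, flip = FALSE)
  else
    list(chrom = as.character(GenomicRanges::seqnames(map@tgt))[b],
         pos = GenomicRanges::end(map@tgt)[b] - off, flip = TRUE)
}

#' Validate a pipeline configuration
#'
#' @param config nested list with components \code{synthetic} (see
#'   \code{\link{syntheticConfig}}), \code{annotation} (see
#'   \code{\link{annotationConfig}}), \code{seed}, \code{n_resamples},
#'   \code{inactive_target}.
#' @return character vector of problems (empty when valid).
#' @export
validateConfig <- function(config) {
  probs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) probs <<- c(probs, msg)
  known <- c("synthetic", "annotation", "seed", "n_resamples",
             "inactive_target", "organ")
  chk(all(names(config) %in% known),
      paste("unknown top-level key(s):",
            paste(setdiff(names(config), known), collapse = ", ")))
  ann <- config$annotation
  if (!is.null(ann)) {
    res <- tryCatch(do.call(annotationConfig, ann), error = function(e)
      conditionMessage(e))
    if (is.character(res)) {
      probs <- c(probs, res)
    } else {
      chk(res$fpkm_threshold >= 0, "fpkm_threshold must be >= 0")
      chk(res$promoter_window > 0, "promoter_window must be > 0")
      chk(res$pe_overlap_window > 0, "pe_overlap_window must be > 0")
      chk(res$min_match_sister > 0 && res$min_match_sister <= 1,
          "min_match_sister must be in (0, 1]")
      chk(res$min_match_outgroup > 0 && res$min_match_outgroup <= 1,
          "min_match_outgroup must be in (0, 1]")
    }
  }
  syn <- config$synthetic
  if (!is.null(syn)) {
    res <- tryCatch(do.call(syntheticConfig, syn), error = function(e)
      conditionMessage(e))
    if (is.character(res)) probs <- c(probs, res)
  }
  if (!is.null(config$organ)) chk(is.character(config$organ),
                                  "organ must be a character string")
  if (!is.null(config$n_resamples))
    chk(config$n_resamples >= 1, "n_resamples must be >= 1")
  probs
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring the \code{\link{validateConfig}}
#'   structure.
#' @return the validated nested list (problems raise an error).
#' @export
readPipelineConfig <- function(path) {
  config <- yaml::read_yaml(path)
  probs <- validateConfig(config)
  if (length(probs)) stop("invalid config: ",
                          paste(probs, collapse = "; "))
  config
}

#' Run the full repurposing analysis
#'
#' Stages: (optional) simulate a clade bundle; annotate species A
#' (enhancers), B (stable transcripts, promoters) and O (outgroup peaks);
#' detect P/E elements (reciprocal projection, 500-nt upstream overlap),
#' remove truncated-isoform artifacts and classify novel/extended; sample
#' inactive controls and test P/E enrichment; polarize against the
#' outgroup and tabulate turnover; run the GC/CpG orthologous-shift
#' resampling test; and compare TSS-anchored U1/PAS density profiles
#' between species for novel P/E elements.
#'
#' @param dataDir clade bundle directory (see
#'   \code{\link{generateCladeDataset}}); when \code{simulate = TRUE} the
#'   bundle is generated there first.
#' @param outDir report output directory (default: \code{dataDir}).
#' @param config nested configuration list (see
#'   \code{\link{validateConfig}}).
#' @param simulate generate the bundle before analysing it.
#' @return a list with all stage results (see Details) plus
#'   \code{report}, a data.frame of headline counts and statistics that is
#'   also written to \code{report.tsv}.
#' @export
runPipeline <- function(dataDir,
                        outDir = dataDir,
                        config = list(),
                        simulate = FALSE) {
  probs <- validateConfig(config)
  if (length(probs)) stop("invalid config: ",
                          paste(probs, collapse = "; "))
  syn_cfg <- do.call(syntheticConfig,
                     if (is.null(config$synthetic)) list()
                     else config$synthetic)
  ann <- do.call(annotationConfig,
                 if (is.null(config$annotation)) list()
                 else config$annotation)
  seed <- if (is.null(config$seed)) syn_cfg$seed else config$seed
  n_resamples <- if (is.null(config$n_resamples)) 10000
                 else config$n_resamples
  inactive_target <- if (is.null(config$inactive_target)) 400
                     else config$inactive_target
  organ <- if (is.null(config$organ)) syn_cfg$organs[1] else config$organ

  if (simulate)
    generateCladeDataset(syn_cfg, dataDir)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  ## ---- load ----
  spA <- loadSpeciesData(file.path(dataDir, "speciesA"))
  spB <- loadSpeciesData(file.path(dataDir, "speciesB"))
  spO <- loadSpeciesData(file.path(dataDir, "speciesO"))
  map_ab <- readOrthologyMap(file.path(dataDir, "map_A_B.tsv"),
                             "speciesA", "speciesB")
  map_ba <- readOrthologyMap(file.path(dataDir, "map_B_A.tsv"),
                             "speciesB", "speciesA")
  map_ao <- readOrthologyMap(file.path(dataDir, "map_A_O.tsv"),
                             "speciesA", "speciesO")

  ## ---- annotate ----
  hA <- .harmonize_species(spA, ann)
  hB <- .harmonize_species(spB, ann)
  hO <- .harmonize_species(spO, ann)
  stableA <- callStableTranscripts(spA$transcripts, organ, ann)
  stableB <- callStableTranscripts(spB$transcripts, organ, ann)
  stableO <- callStableTranscripts(spO$transcripts, organ, ann)
  promA <- definePromoters(stableA, ann$promoter_window, spA$seqlengths,
                           organ)
  promB <- definePromoters(stableB, ann$promoter_window, spB$seqlengths,
                           organ)
  enhA <- callEnhancers(hA$dhs, hA$k27ac, hA$k4me1, hA$k4me3,
                        spA$transcripts, config = ann)
  names(enhA) <- paste0("enhA_", seq_along(enhA))

  ## ---- detect ----
  pe_raw <- detectPEElements(enhA, map_ab, map_ba, stableB, ann, organ)
  pe_filt <- filterTruncatedIsoforms(pe_raw, stableB)
  pe <- classifyPEElements(pe_filt, map_ba, stableB, spA$transcripts,
                           ann)

  ## ---- inactive controls & enrichment ----
  excl <- c(unlist(GenomicRanges::GRangesList(
    lapply(spA$peaks, function(reps) {
      if (length(reps))
        unlist(GenomicRanges::GRangesList(lapply(reps,
          GenomicRanges::granges)))
      else GenomicRanges::GRanges()
    }))))
  inactiveA <- sampleInactiveRegions(spA$seqlengths, excl,
                                     unlist(spA$transcripts@exons),
                                     spA$masks, ann,
                                     seed = seed + 101,
                                     target = inactive_target)
  inact_proj <- reciprocalOrthologs(inactiveA, map_ab, map_ba,
                                    minMatch = ann$min_match_sister)
  inact_tg <- projectionTargets(inact_proj)
  b_win <- GenomicRanges::promoters(tssRanges(stableB),
                                    upstream = ann$pe_overlap_window,
                                    downstream = 0)
  GenomicRanges::start(b_win) <- pmax(GenomicRanges::start(b_win), 1L)
  ctrl_pos <- sum(IRanges::overlapsAny(inact_tg, b_win,
                                       ignore.strand = TRUE))
  enh_proj <- reciprocalOrthologs(enhA, map_ab, map_ba,
                                  minMatch = ann$min_match_sister)
  enrich <- peVsInactiveEnrichment(length(pe), max(1, sum(enh_proj$mapped)),
                                   ctrl_pos, max(1, length(inact_tg)))

  ## ---- polarize ----
  pe_og_proj <- projectIntervals(pe, map_ao,
                                 minMatch = ann$min_match_outgroup)
  pe_og_tg <- projectionTargets(pe_og_proj)
  og_states_mapped <- assignOutgroupState(pe_og_tg, hO$k27ac, hO$k4me3,
                                          spO$transcripts, stableO, ann)
  og_states <- factor(rep("none", length(pe)),
                      levels = c("promoter", "enhancer", "none"))
  og_states[S4Vectors::mcols(pe_og_tg)$source_index] <- og_states_mapped
  ancestral <- defineAncestralElements(promA, enhA, map_ab, map_ba,
                                       map_ao, hO$k27ac, hO$k4me3,
                                       spO$transcripts, stableO, ann)
  ## sister conservation of ancestral elements
  qkB <- qualifyingEnhancerPeaks(hB$k27ac, hB$k4me3, spB$transcripts,
                                 ann)
  conserved_in_sister <- function(x, rule) {
    if (!length(x)) return(logical(0))
    pr <- reciprocalOrthologs(x, map_ab, map_ba,
                              minMatch = ann$min_match_sister)
    tg <- projectionTargets(pr)
    out <- rep(FALSE, length(x))
    if (length(tg))
      out[S4Vectors::mcols(tg)$source_index] <- rule(tg)
    out
  }
  b_win500 <- b_win
  enh_cons <- conserved_in_sister(ancestral$enhancers, function(tg)
    IRanges::overlapsAny(tg, qkB, ignore.strand = TRUE))
  prom_cons <- conserved_in_sister(ancestral$promoters, function(tg)
    IRanges::overlapsAny(tg, b_win500, ignore.strand = TRUE))
  turnover <- tabulateTurnover(ancestral, pe, og_states, enh_cons,
                               prom_cons)
  bias <- repurposingBiasTest(turnover)

  ## ---- composition ----
  pe_pairsA <- GenomicRanges::granges(pe)
  pe_pairsB <- GenomicRanges::GRanges(S4Vectors::mcols(pe)$b_seqnames,
    IRanges::IRanges(S4Vectors::mcols(pe)$b_start,
                     S4Vectors::mcols(pe)$b_end))
  inact_keep <- S4Vectors::mcols(inact_tg)$source_index
  comp <- NULL
  if (length(pe) >= 2 && length(inact_tg) > length(pe)) {
    pe_cpg <- cbind(cpgFrequency(elementSequences(spA$genome, pe_pairsA)),
                    cpgFrequency(elementSequences(spB$genome, pe_pairsB)))
    in_cpg <- cbind(
      cpgFrequency(elementSequences(spA$genome, inactiveA[inact_keep])),
      cpgFrequency(elementSequences(spB$genome, inact_tg)))
    pe_gc <- cbind(gcContent(elementSequences(spA$genome, pe_pairsA)),
                   gcContent(elementSequences(spB$genome, pe_pairsB)))
    in_gc <- cbind(
      gcContent(elementSequences(spA$genome, inactiveA[inact_keep])),
      gcContent(elementSequences(spB$genome, inact_tg)))
    comp <- list(
      cpg = orthologShiftResamplingTest(pe_cpg, in_cpg, n_resamples,
                                        seed = seed + 202),
      gc = orthologShiftResamplingTest(pe_gc, in_gc, n_resamples,
                                       seed = seed + 203))
  }

  ## ---- motif axis (novel P/E only) ----
  axis <- NULL
  novel <- pe[S4Vectors::mcols(pe)$category %in% "novel"]
  if (length(novel) >= 2) {
    u1 <- u1Matrix()
    pas <- pasMatrix()
    u1A <- scanMotifSet(spA$genome, u1)
    u1B <- scanMotifSet(spB$genome, u1)
    pasA <- scanMotifSet(spA$genome, pas)
    pasB <- scanMotifSet(spB$genome, pas)
    tssB_all <- tssRanges(stableB)
    ids <- S4Vectors::mcols(novel)$b_transcript_id
    profA <- list()
    profB <- list()
    tssA_tab <- list()
    tssB_tab <- list()
    for (i in seq_along(novel)) {
      tssb <- tssB_all[ids[i]]
      bchrom <- as.character(GenomicRanges::seqnames(tssb))
      bpos <- GenomicRanges::start(tssb)
      bstr <- as.character(GenomicRanges::strand(tssb))
      mapped <- .map_tss_position(map_ba, bchrom, bpos)
      if (is.null(mapped)) next
      astr <- if (mapped$flip) setdiff(c("+", "-"), bstr) else bstr
      eid <- names(novel)[i]
      profB[[eid]] <- tssDensityProfile(bpos, bstr,
        u1B[u1B$seq_name == bchrom, ],
        contigLength = Biostrings::width(spB$genome)[
          match(bchrom, names(spB$genome))])
      profA[[eid]] <- tssDensityProfile(mapped$pos, astr,
        u1A[u1A$seq_name == mapped$chrom, ],
        contigLength = Biostrings::width(spA$genome)[
          match(mapped$chrom, names(spA$genome))])
      tssB_tab[[eid]] <- data.frame(seq_name = bchrom, pos = bpos,
                                    strand = bstr)
      tssA_tab[[eid]] <- data.frame(seq_name = mapped$chrom,
                                    pos = mapped$pos, strand = astr)
    }
    if (length(profA) >= 2) {
      tssA_df <- do.call(rbind, tssA_tab)
      tssB_df <- do.call(rbind, tssB_tab)
      axis <- list(
        u1_tests = compareAxisBetweenSpecies(profA, profB,
                                             paired = TRUE),
        u1_before_pas_b = u1BeforePasFraction(tssB_df, u1B, pasB),
        u1_before_pas_a = u1BeforePasFraction(tssA_df, u1A, pasA),
        profiles_a = profA, profiles_b = profB)
    }
  }

  ## ---- report ----
  cat_tab <- table(factor(S4Vectors::mcols(pe)$category,
                          levels = c("novel", "extended")))
  report <- data.frame(
    metric = c("enhancers_a", "stable_transcripts_b", "promoters_a",
               "pe_detected_raw", "pe_after_isoform_filter", "pe_novel",
               "pe_extended", "inactive_sampled", "inactive_orthologous",
               "control_positives", "enrichment_rate_ratio",
               "enrichment_p", "outgroup_promoter", "outgroup_enhancer",
               "outgroup_none", "ancestral_enhancers",
               "ancestral_promoters", "turnover_eh_repurposed",
               "turnover_eh_lost", "turnover_pr_repurposed",
               "turnover_pr_lost", "turnover_odds_ratio", "turnover_p",
               "cpg_shift_observed", "cpg_shift_p"),
    value = c(length(enhA), length(stableB), length(promA),
              length(pe_raw), length(pe), unname(cat_tab["novel"]),
              unname(cat_tab["extended"]), length(inactiveA),
              length(inact_tg), ctrl_pos, enrich$rate_ratio,
              enrich$p_value, sum(og_states == "promoter"),
              sum(og_states == "enhancer"), sum(og_states == "none"),
              length(ancestral$enhancers), length(ancestral$promoters),
              turnover$counts[1, 1], turnover$counts[1, 2],
              turnover$counts[2, 1], turnover$counts[2, 2],
              bias$odds_ratio, bias$p_value,
              if (is.null(comp)) NA else comp$cpg$observed_mean_diff,
              if (is.null(comp)) NA else comp$cpg$empirical_p))
  .write_tsv(report, file.path(outDir, "report.tsv"),
             paste0("seed=", seed))

  invisible(list(
    config = list(synthetic = syn_cfg, annotation = ann, seed = seed),
    enhancers_a = enhA, promoters_a = promA, promoters_b = promB,
    stable_b = stableB, pe_raw = pe_raw, pe = pe,
    inactive_a = inactiveA, enrichment = enrich,
    outgroup_states = og_states, ancestral = ancestral,
    turnover = turnover, bias = bias, composition = comp, axis = axis,
    report = report))
}

#' Compare detected P/E elements with a planted ground truth
#'
#' @param pe detected P/E \code{GRanges} (A coordinates).
#' @param truth truth data.frame from \code{\link{generateCladeDataset}}.
#' @return list: \code{sensitivity}, \code{precision}, \code{n_detected},
#'   \code{n_planted}, \code{category_accuracy} (fraction of matched
#'   elements with the planted category).
#' @export
evaluateRecovery <- function(pe, truth) {
  planted <- truth[truth$class == "pe", , drop = FALSE]
  if (!nrow(planted))
    return(list(sensitivity = NA, precision = NA,
                n_detected = length(pe), n_planted = 0,
                category_accuracy = NA))
  pl <- GenomicRanges::GRanges(planted$chrom,
    IRanges::IRanges(planted$a_start, planted$a_end))
  hits <- GenomicRanges::findOverlaps(pl, pe, ignore.strand = TRUE)
  matched_planted <- unique(S4Vectors::queryHits(hits))
  matched_det <- unique(S4Vectors::subjectHits(hits))
  cat_ok <- NA
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    cat_ok <- mean(planted$category[qh] ==
                   S4Vectors::mcols(pe)$category[sh])
  }
  list(sensitivity = length(matched_planted) / nrow(planted),
       precision = if (length(pe)) length(matched_det) / length(pe)
                   else NA,
       n_detected = length(pe), n_planted = nrow(planted),
       category_accuracy = cat_ok)
}
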