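# repurposeR

Comparative regulatory genomics in R: detect orthologous loci that act
as **enhancers in one species and promoters in its sister species**
(P/E elements), polarize the direction of the switch with an outgroup,
and characterize the sequence changes that accompany it.

## The problem

Promoters drive stable, processed transcripts; enhancers produce
unstable bidirectional transcription. Comparative epigenomics shows
these roles can interconvert over tens of millions of years: a locus
with enhancer chromatin (DNase hypersensitivity + H3K27ac/H3K4me1, no
H3K4me3) in species A can overlap the transcription start site of a
stable transcript in sister species B. `repurposeR` implements the full
analysis for anyone studying regulatory element evolution across
species with matched transcriptome and chromatin data:

* **Annotation** — stable transcripts (mean FPKM > 1, span > 1000 nt),
  promoters (1000 nt upstream of a stable TSS), enhancers (DHS ∩
  H3K27ac/H3K4me1, bivalence- and transcript-filtered), and
  rejection-sampled inactive control regions, from harmonized replicate
  peak sets (top-N by score, ≥3-replicate consensus, 1000 nt
  summit-centred).
* **Detection** — reciprocal (two-way) projection through co-linear
  orthology block maps with a liftOver-style minimum-match fraction
  (0.6 sister / 0.4 outgroup); a P/E element is an enhancer whose B
  ortholog overlaps the 500 nt upstream of a stable B TSS, after a
  truncated-isoform artifact filter, classified *novel* (new
  transcribed locus) or *extended* (new 5′ isoform of a shared locus).
* **Polarization** — outgroup states with promoter precedence, ancestral
  enhancer/promoter sets, and a 2×2 repurposed/lost turnover table
  tested with Fisher's exact test. The headline statistic is the odds
  ratio OR = (E_rep · P_lost) / (P_rep · E_lost).
* **Composition** — GC and CpG (CG count / dinucleotide positions), with
  a 10,000-draw resampling null over orthologous inactive pairs for the
  cross-species shift, p = (1 + #{null ≥ obs}) / (n + 1).
* **U1–PAS axis** — PWM scanning of U1 splice-donor and PAS hexamers on
  both strands, TSS-anchored density profiles over 200–1000 nt windows,
  closest-site distances, and the U1-before-PAS ordering fraction,
  compared between species with paired Wilcoxon tests (BH-corrected per
  window family).
* **Synthetic clade generator** — a deterministic three-species bundle
  (FASTA/GTF/TSV/narrowPeak) with planted repurposing events, CpG
  shifts, motif-density asymmetries and a ground-truth ledger, used by
  the test suite for end-to-end validation.

## Worked example

Simulate a small clade and run the whole pipeline:

```r
library(repurposeR)

cfg <- syntheticConfig(seed = 1L, n_chromosomes = 1L,
                       chrom_length = 400000L, n_promoters = 8L,
                       n_enhancers = 16L, n_inactive = 6L,
                       n_planted_pe = 12L, n_bivalent_decoys = 2L,
                       n_unstable = 2L)
dir <- tempfile("clade")
gen <- generateCladeDataset(cfg, dir)
res <- runPipeline(dir, config = list(n_resamples = 2000))
head(res$report, 8)
#>                   metric value
#>              enhancers_a    16
#>     stable_transcripts_b    21
#>              promoters_a    13
#>          pe_detected_raw    12
#>  pe_after_isoform_filter    12
#>                 pe_novel     7
#>              pe_extended     5
#>         inactive_sampled   200
```

All 12 planted repurposing events are recovered (and none of the 200
inactive controls is promoter-orthologous, hence the strong enrichment
p in the full report). The planted +0.02 CpG shift on the promoter side
is recovered against the inactive-pair null:

```r
res$composition$cpg
#> Orthologous composition-shift resampling test (greater)
#>   observed mean difference: 0.02052
#>   null mean +/- sd: 0.0002129 +/- 0.000754
#>   empirical p: 0.0004998
```

The same functions reproduce published turnover statistics directly
from count tables — e.g. a primate-like table of 27 repurposed / 2655
lost of 5260 ancestral enhancers against 1 / 1342 of 5110 ancestral
promoters:

```r
repurposingBiasTest(turnoverTable(27, 2655, 1, 1342,
                                  ehTotal = 5260, prTotal = 5110))
#> $odds_ratio              13.65
#> $p_value                 0.000358
#> $enhancer_loss_rate      0.505
#> $promoter_loss_rate      0.263
#> $loss_rate_ratio         1.92
#> $repurposing_rate_ratio  26.2
```

That is: enhancers are lost about twice as often as promoters, but
repurposed ~26 times more often — a ~13.6-fold enrichment of
enhancer-to-promoter conversion after accounting for loss rates.

A thin CLI over the same functions lives at
`inst/scripts/regswitch.R` (`simulate`, `run`, `project` subcommands),
and `vignettes/methods.Rmd` documents the models, thresholds, and the
generator's assumptions.

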