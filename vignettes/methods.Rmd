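---
title: "Detecting enhancer-to-promoter repurposing: models and methods"
author: "repurposeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting enhancer-to-promoter repurposing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repurposeR)
```

## The question

Gene-regulatory elements are not fixed in their roles. An enhancer in one
species can, over a few tens of millions of years, come to drive stable
transcription in a close relative — that is, act as a promoter — at the
orthologous position. `repurposeR` implements a comparative pipeline for
finding such **P/E elements** (promoter-in-one-species /
enhancer-in-the-sister), deciding with an outgroup which activity is
ancestral, and asking what changed in the underlying sequence: CpG/GC
composition, and the arrangement of U1 splice-donor and polyadenylation
(PAS) motifs around the new transcription start site — the **U1–PAS
axis** that separates stable from unstable transcription.

## Element definitions

Per species the pipeline consumes transcript models with per-replicate
FPKM, replicate peak sets (DNase, H3K27ac, H3K4me1, H3K4me3), and
orthology block maps; all intervals are `GRanges` (1-based closed), with
BED/narrowPeak converted at the I/O boundary.

* **Stable transcript** — mean replicate FPKM strictly greater than 1 in
  an organ and genomic span strictly greater than 1000 nt. Both
  inequalities are strict; a transcript at exactly FPKM 1 or 1000 nt is
  excluded.
* **Promoter** — the 1000 nt immediately upstream of a stable TSS,
  strand-aware, clipped at contig edges; identical intervals from
  isoforms sharing a TSS are merged.
* **Peak harmonization** — per replicate, the top 20,000 (H3K4me3) or
  80,000 (H3K4me1/H3K27ac) peaks by score; loci supported by at least 3
  replicates (both when only two exist; as-is for single merged samples)
  are resized to 1000 nt centred on the summit of the highest-scoring
  supporting peak (midpoint when no summit is recorded). Score ties
  break by genomic position so the output is deterministic.
* **Enhancer** — a DHS overlapping (≥ 1 bp) an H3K27ac and/or H3K4me1
  consensus peak, excluding anything with an inter-interval gap under
  1000 nt to any H3K4me3 peak from any tissue (overlap counts as gap 0),
  or overlapping the TSS-upstream kilobase or an exon of *any*
  transcript, stable or not. CAGE-defined enhancers pass the same
  filters and are appended with their own provenance label.
* **Inactive region** — 1000-nt loci rejection-sampled uniformly,
  discarded within 1000 nt of any peak, exon, or repeat/segmental
  duplication mask, non-overlapping, deterministic under a seed, with a
  proposal cap of 50 times the target to bound runtime.

## Detection and classification

A-species enhancers are projected to the sister B through gapless
co-linear block maps. The projection contract mirrors liftOver: an
interval maps when at least `min_match` of its bases fall in blocks (0.6
between sisters, 0.4 to the outgroup), the target is the span from first
to last mapped base, multi-chromosome or mixed-orientation coverage
fails, and a bridged target span more than 10 times the source width
fails. A **two-way filter** keeps only projections whose back-projection
overlaps the original interval by at least one base, rejecting
paralogy-induced ambiguity.

A P/E element is an enhancer whose reciprocal B ortholog overlaps (≥ 1
bp) the **500-nt** window upstream of a stable B TSS — deliberately
narrower than the 1000-nt promoter definition; the two windows are
separate configuration fields. When several windows are hit, the
transcript whose TSS is nearest the projection midpoint is attached
(ties to the smaller coordinate). Two artifact controls follow:

* **Truncated-isoform filter** — elements attached to a shorter isoform
  of a locus that has another *stable* transcript with a strictly
  upstream TSS (strand-aware) are removed; unstable isoforms do not
  define alternative promoters.
* **Classification** — the B transcript's exons are projected back to A;
  any overlap with an A transcript makes the element *extended* (a new
  5′ isoform of a shared locus), otherwise *novel*; unprojectable
  transcripts default to novel, since the absence of an A ortholog is
  the operational meaning of a newly transcribed locus.

Enrichment over chance is tested by running the identical projection on
inactive regions and comparing promoter-overlap rates with a two-sided
Fisher's exact test; a GC-matched variant subsamples enhancers below a
GC threshold (0.46 human-like, 0.41 mouse-like) and greedily pairs each
with the inactive region of most similar GC (epsilon-tolerant ties going
to the lower GC), without replacement.

## Polarization

P/E elements are projected to the outgroup (min-match 0.4, single
direction) and assigned a state with promoter precedence: *promoter* if
overlapping the kilobase upstream of a stable outgroup transcript, else
*enhancer* if overlapping an H3K27ac peak that itself overlaps no
H3K4me3, no transcript-upstream window and no exon, else *none*.
Precedence follows from the enhancer definition, which explicitly
excludes promoter-overlapping peaks.

Ancestral sets condition on alignment to both the sister and the
outgroup (reciprocal filtering on the sister leg only, matching the
single-direction outgroup description). The turnover table counts, per
ancestral class, elements *repurposed* (P/E members; for the promoter
row, P/E elements whose outgroup state is promoter) and *lost* (not
conserved in the sister); conserved elements appear in the totals only.
The bias test reports the unconditional cross-product odds ratio with a
two-sided Fisher p computed by hypergeometric point-probability
summation — the convention that reproduces the published borderline
p-value of the rodent table (0.056) to three decimals — plus per-row
loss rates and the repurposing rate ratio.

## Composition and the resampling null

GC content excludes N bases from the denominator; CpG frequency is CG
count over dinucleotide positions (length − 1). The normalization is a
package choice — the counting unit is the dinucleotide window, which
makes `k/(2k-1)` the exact value of a pure CG repeat — and a strict mode
that also removes N-containing windows from the denominator is
available.

Whether the cross-species composition change at P/E elements exceeds
genome-wide drift is decided by resampling: the observed statistic is
the mean (B − A) difference over orthologous P/E pairs; 10,000 resamples
draw the same number of orthologous *inactive* pairs (computed through
the same reciprocal-ortholog machinery, so the null carries any
genome-wide composition skew) and the empirical p is the add-one
estimator (1 + #{null ≥ observed})/(n + 1) — never exactly zero, one
sided by default because the question is directional, with a two-sided
doubling option.

## The U1–PAS axis

U1 and PAS sites are located with log2-odds position-weight matrices
scanned on both strands; hits are reported on forward coordinates. The
shipped matrices encode the canonical donor core (accepting `GTAAGT` and
`GTGAGT`) and the PAS hexamer (accepting `AATAAA` and `ATTAAA`); their
thresholds sit exactly at the weaker accepted variant, so 2 of 4096
random hexamers pass. Published matrices for these motifs are not
reproducible exactly, so absolute densities are threshold-dependent;
every reported contrast is therefore a within-run difference or
asymmetry, never an absolute density comparison across studies. User
matrices are accepted in a plain-text format.

Densities are counted in sense-oriented windows (200–1000 nt) around the
TSS — for minus-strand TSSs the anchor is the first hit base read in the
sense direction, which makes the profiles exactly invariant under
reverse-complementing the contig. Hit strand is ignored; the
sense/antisense contrast comes from which side of the TSS is measured.
Only *novel* P/E elements enter cross-species comparisons (extended
elements share downstream exons that conflate the signal), and the B TSS
is placed in A by projecting the TSS base through the block map, taking
the nearest mapped base within 50 nt when the exact base falls in a gap.
Paired profiles are compared per window with Wilcoxon signed-rank tests,
Benjamini–Hochberg corrected across the window family *within each
side*: up- and downstream regions are distinct hypotheses about
different sequence, so each side forms its own five-window family. The
ordering statistic (fraction of TSSs whose closest downstream U1
precedes the closest downstream PAS) counts a TSS with a U1 but no PAS
as a success and excludes TSSs with neither motif.

## The synthetic clade

Real genome-scale inputs are multi-terabyte; the generator replaces them
with a three-species clade (sisters A and B, outgroup O) whose planted
structure makes every pipeline claim checkable against a ground-truth
ledger. Design choices, and what they do and do not emulate:

* Background sequence is i.i.d. at a configurable GC (default 0.41,
  mammal-like); B and O are substituted copies of A (default 5% of
  sites, redrawn from the background composition so expected GC/CpG
  drift is zero). There is no substitution model, no rate heterogeneity,
  no indel realism — orthology maps default to one identity block per
  chromosome, with `mutateMap()` providing Poisson block breaks and
  geometric deletions (mean 50 nt) when map noise is wanted.
* Elements occupy disjoint 8-kb tiles so the kilobase exclusion rules
  cannot couple neighbours. Planted classes cover every branch of the
  analysis: P/E events (enhancer chromatin in A; a stable B transcript
  whose TSS-upstream 500 nt sit inside the site; outgroup state drawn as
  41% enhancer / 1.5% promoter / 57.5% none, the published proportions),
  conserved/lost/private enhancers and promoters, bivalent decoys
  (H3K4me3 within 1000 nt, which the enhancer caller must exclude), and
  always at least one unstable transcript of each failure mode (low
  FPKM; short span) so the stability filters are exercised.
* The promoter-side CpG shift (default +0.02 in frequency, a value
  chosen for testability — the source data are distributional only) is
  planted by targeted CG substitutions that avoid existing CGs and any
  U1/PAS word occurrence, so composition planting never moves motif
  counts. U1/PAS sites are planted as exact consensus strings at
  Poisson-distributed non-overlapping positions (defaults 3.0 vs 2.0 U1
  sites/kb and 1.45 vs 1.70 PAS sites/kb downstream of the promoter- and
  enhancer-side TSS copies), making scan recovery exact and separating
  generator correctness from scanner thresholds.
* FPKM replicates are lognormal around a transcript mean; planted
  stability is then enforced exactly (replicates are rescaled when
  sampling noise would cross the threshold), because the generator's
  contract is that a planted stable transcript *is* stable.
* All randomness flows from one seed in a fixed order; identical seeds
  give byte-identical files, and every text output records the seed in a
  `#` header (FASTA, which has no comment syntax, is covered by the
  manifest digests).

Passing on this clade demonstrates that the rules, projections,
statistics and bookkeeping are implemented correctly — not that the
thresholds are optimal for real chromatin, where peak noise, partial
synteny, and assembly artifacts dominate.

## Numerical and degenerate-input choices

Exact rank tests switch to normal approximations (with tie and
continuity corrections) above 12 observations; zero differences are
dropped from the signed-rank test. Odds ratios report `Inf` on a zero
denominator rather than erroring, with the p-value still computed.
Empty peak sets, empty transcript sets, unmappable intervals, contigs
shorter than a window, and all-zero tables all return well-defined empty
or flagged results. Windows truncated by a contig edge use the
effective length as the density denominator. The signal normalizer adds
a pseudocount of 1 to both ChIP and input coverage so zero-input regions
stay finite.

## Problem sizes and reproducibility

The shipped validation runs use two chromosomes of 1.2 Mb (about 300
element tiles), 50 planted P/E events for detection/composition checks
and 100 novel-only events for the motif-axis checks, with 10,000
composition resamples — sizes chosen so the ledgered claims (exact
recovery; CpG shift recovered within 20%; downstream U1 asymmetry
significant, upstream not) are sharply testable on a laptop.
`scripts/acceptance.R` re-runs all of it from scratch under any seed and
writes the resulting quantities as JSON.

## Known limitations

Chain/net alignment files are not parsed (block maps are a deliberate
simplification); no probabilistic ancestral-state reconstruction (single
outgroup, rule-based polarization); CpG-island calling, conservation
scoring and core-promoter motif enrichment are out of scope; and the
synthetic clade's noise model is far milder than real comparative
chromatin data, as discussed above.
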