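---
title: "Charting acetylation-domain dynamics across the oocyte-to-embryo transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charting acetylation-domain dynamics across the oocyte-to-embryo transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetydyn)
```

## The analysis problem

During the mouse maternal-to-zygotic transition (MZT), H3K27 acetylation is
reorganized through three rapid global waves: germinal-vesicle (GV) oocytes
carry noncanonical, multi-10-kb hyperacetylated *broad domains*; MII oocytes
are almost bare; zygotes re-establish broad domains — larger and stronger on
the paternal allele — and from the early 2-cell stage onward the mark
resolves into canonical narrow peaks at promoters and enhancers. Profiling
this with ultra-low-input CUT&RUN poses several analysis problems that this
package solves as a reusable, testable pipeline:

1. **Cross-stage comparability.** FPKM-scale coverage is not comparable
   between a stage whose signal is spread over megabases and one whose
   signal sits in sharp peaks. We anchor all stages on the promoters with
   the strongest signal: the per-stage scale factor is
   `median(top-n promoter signal in the reference) / median(top-n promoter
   signal in the stage)`, with embryonic stem cells (ESC) as the reference
   (factor exactly 1) and `n = 3000`. Scaled FPKM is used everywhere
   downstream.
2. **Domain calling across regimes.** Acetylation domains are maximal runs
   of bins whose scaled FPKM is at least 3, merged when their end-to-end gap
   is at most twice the bin size; 1-kb bins for the broad regimes (oocytes,
   zygotes), 500-bp bins for the narrow regimes (2-cell, morula, ESC).
3. **Allele-specific signal.** Fragments carrying strain-distinguishing SNP
   evidence are assigned maternal/paternal; fragments at least 140 bp with
   mapping quality at least 30 and no duplicate flag are retained.
4. **Structure around genes.** Domain-transition clustering (k-means),
   metagene and TSS profiles, gene-density correlations, and ATAC-style
   peak classification (promoter < 1 kb, distal > 2.5 kb from a TSS).
5. **Regulatory wiring.** Aggregate Hi-C pile-up between distal elements
   and gene promoters at 10-kb resolution, normalized by shifted controls
   that preserve each pair's genomic separation.
6. **Expression context.** Gene classes — zygotic genome activation (ZGA)
   waves, maternal decay, Polycomb (PcG) targets — derived from
   differential-expression tables by fixed published-style cutoffs, and
   repeat-family expression quantified on a concatenated pseudo-genome.

## The synthetic study

Real data for this biology requires scarce embryonic material; the package
therefore ships a first-class generator that plants every structure the
analysis is designed to detect, together with a ground-truth ledger, so the
entire pipeline is testable end to end.

```{r genome}
genome <- generate_genome(seed = 1)
genome
```

The default genome is a deliberate desk-scale stand-in: 2 chromosomes of
5 Mb, 200 non-overlapping genes, three retrotransposon-like repeat
families, 17 maternal and 4 paternal imprinting control regions (matching
the counts of the murine region sets these analyses are usually run
against), and SNPs at a mean spacing of 1 kb — roughly the density that
separates distantly related mouse strains and makes a usable fraction of
140–500-bp fragments SNP-informative. These sizes keep the complete study
under a minute of compute while leaving every module with enough events to
measure (dozens of domains, hundreds of bins per domain, thousands of
informative fragments).

Per-stage parameters encode the three waves:

```{r params}
unclass(stage_params("GV"))[c("domain_mode", "n_domains", "length_range",
                              "bin_size", "plateau", "background",
                              "noise_sd", "asymmetry")]
```

* **GV / zygote** (`broad`): 25 / 20 domains of 20–80 kb / 20–60 kb,
  plateau 8 (scaled FPKM), background 0.5, bin noise SD 0.5.
* **MII** (`sparse`): 6 narrow domains of 2–6 kb.
* **early/late 2-cell, morula, ESC** (`canonical`): 50–80 peaks of
  0.5–3 kb, plateau 10.
* **Allelic asymmetry** (zygote only): factor 2, applied to *both* the
  paternal plateau level and the planted domain width, so the paternal
  allele is broader and higher — the property the allelic analyses must
  detect — and "paternal exceeds maternal domain bases in zygotes only" is
  a planted truth rather than an artifact of noise.

The plateau values sit comfortably above the calling threshold of 3 and the
background well below it because the threshold is a published constant, not
a fitted one: the generator's job is to emulate the regime in which that
constant is meaningful (signal-to-background around 16:1, as in scaled
embryo CUT&RUN tracks), not to stress it. Tests that probe boundary
behaviour lower the plateau explicitly (e.g. plateau 5 with noise SD 0.5).

What the generator deliberately does **not** emulate: read-level sequencing
error, GC and mappability bias, fragment-length dependence of signal,
replicate structure, and Hi-C matrix bias needing balancing. Passing tests
therefore demonstrate the *correctness of the computations* on data with
the assumed statistical shape, not robustness to every artifact of real
sequencing.

### Determinism

Every generator draws from a named RNG substream derived from
`(seed, output type)`, so adding one output never perturbs another and the
whole study is byte-reproducible for a fixed seed. `run_pipeline()` run
twice with the same seed produces identical reports.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere (BED convention); GTF
  input is converted on read. Chromosomes sort naturally
  (chr1 < chr2 < chr10).
* **bedGraph binning** distributes record values over bins by
  length-weighted mean, preserving per-base FPKM semantics for records that
  do not align to the grid.
* **Promoter window**: TSS ± 2 kb. The window is not printed alongside the
  scaling method in the literature; ± 2 kb matches the promoter windows
  used by the companion analyses (PcG-target promoters, allelic promoter
  comparisons), so one width is used throughout.
* **Top-n promoter selection** is recomputed per track rather than fixed
  from the reference: ranking is part of the procedure, and ties are broken
  by gene id for determinism. When a genome has fewer than `n` genes, all
  are used with a warning.
* **The FPKM ≥ 3 domain threshold is applied to scaled FPKM.** The scaled
  values are the ones used "in all downstream analyses"; applying the
  threshold pre-scaling would make domain calls incomparable across stages,
  defeating the point of the scaling.
* **"Within 2 × bin size" merging is inclusive** (gap ≤ 2 bins): a gap of
  exactly two bins merges. The merge gap is exposed as a parameter, and the
  caller's `mean_signal` is recomputed over the merged interval including
  sub-threshold gap bins, so merged domains can have mean below threshold.
* **k-means determinism**: rows are clustered in canonical (lexicographic)
  order with 10 restarts under a fixed seed, and labels are reassigned by
  descending first-layer mean — so the labeling is invariant to row order,
  and "cluster 1" always means the strongest signal. Inputs with fewer
  distinct rows than k collapse onto duplicate centroids rather than
  erroring. Feature construction (± 10 kb around the domain center, 100
  bins per stage, stages concatenated) is configurable; no published
  setting exists for it.
* **Correlations drop doubly-zero bins** by default: sparse embryo tracks
  are otherwise dominated by tied zeros. Exposed as a flag.
* **Allelic conventions**: positive log2 ratio = maternal-high; pseudocount
  0.5; fragments with conflicting SNP evidence are excluded from both
  allelic tracks (the same behaviour as the standard SNP-splitting tools).
  Region comparisons use a **paired** t-test by default — the regions are
  matched between alleles — with Welch unpaired available; the p-value is
  computed from first principles so the zero-variance limit is analytic
  (identical signals give t = 0 and one-sided p = 0.5, flagged
  `degenerate`) instead of an error.
* **Peak response thresholds** (ratio ≤ 0.5 lost, ≥ 2 enhanced) are package
  defaults for the inhibition-response classification, not literature
  constants; they are parameters.
* **Repeat pseudo-genome**: instances are concatenated in genomic order,
  minus-strand instances reverse-complemented, with 200-N spacers *between*
  instances only (no flanking spacers). Quantification places error-free
  reads by exact substring match on either strand; a read matching k
  families counts 1/k to each (no published rule exists for multi-family
  reads in the original STAR/RSEM setting; the fractional split mirrors
  expectation-style counting). Reads containing N never match.
* **Pile-up controls**: one shifted control per pair (configurable),
  uniformly placed along the chromosome with the pair's bin separation
  preserved exactly; each pair's control placement is seeded from the
  pair's own coordinates so results are invariant to pair order. Raw
  counts are used without matrix balancing — the synthetic matrices are
  unbiased by construction and the shifted control supplies the
  distance normalization.
* **Gene-set cutoffs**: fold changes are compared on the log2 scale against
  exact `log2(cutoff)`; "mean FPKM ≥ 1" is read as *either group's* mean
  reaching 1 (keeping genes expressed in only one condition — the natural
  reading for on/off genes such as ZGA targets); PcG targets require
  strictly `FPKM < 0.1` in every stage. Minor-ZGA orientation: the
  transcription-inhibited (DRB) sample is compared against control and
  *down*-regulated genes are kept, since inhibiting transcription removes
  exactly the zygotically transcribed component.

## Running the study

```{r pipeline}
result <- run_pipeline(seed = 1)
result
```

The report carries, per stage: domain counts, size quartiles, total domain
bases (combined and per allele), genomic composition, and exact-boundary
recovery against the ledger; plus scale factors, allelic summaries
(assignment concordance, bias quartiles, ICR comparison), repeat counts
versus truth, gene-set sizes with ledger recovery flags, pile-up center
ratios for ZGA-promoter anchors versus PcG-promoter controls, and the
three-wave summary:

```{r waves}
str(result$report$three_waves)
```

Problem sizes used by the shipped tests and the acceptance script are the
defaults above (10 Mb genome, 20,000 fragments, 1,000 repeat reads,
~250-pair pile-ups, 100-replicate t-test calibrations) — chosen as the
smallest sizes at which every planted effect is detectable with wide
margins.

## Known limitations

* The domain caller is a thresholding scanner, not a statistical
  (HMM/broad-peak) caller; it has no replicate awareness and inherits the
  bin grid's resolution.
* DE estimation is out of scope: tables arrive with fold changes and
  adjusted p-values already computed (synthetic tables plant them), so the
  gene-set module tests filters, not inference.
* The exact-substring repeat quantifier assumes error-free reads; it is a
  toy stand-in for a spliced aligner plus EM quantifier, adequate because
  the pseudo-genome construction — not alignment — is the step under test.
* Pile-ups are cis-only and unbalanced; expected-by-distance (Toeplitz)
  normalization is not implemented.
* The synthetic fragment model plants SNP evidence without sequencing
  error, so assignment concordance is an upper bound, not an error-rate
  estimate.
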