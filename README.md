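# acetydyn

Analysis toolkit for **histone-acetylation domain dynamics across the mouse
maternal-to-zygotic transition (MZT)**, for epigenomics analysts working
with stage- and allele-resolved coverage tracks (CUT&RUN/ChIP-style) from
oocytes and early embryos.

During the MZT, H3K27ac is reorganized in three global waves: broad
multi-10-kb hyperacetylated domains in germinal-vesicle oocytes, near-bare
MII oocytes, re-established broad domains in zygotes (broader and higher on
the paternal allele), then canonical narrow peaks from the 2-cell stage on.
Comparing stages across such different signal regimes, and alleles within a
stage, requires a specific chain of computations that this package
implements as tested, reusable functions:

* **Cross-stage scaling** — the per-stage factor is

  `s(stage) = median(top-3000 promoter signal, reference) / median(top-3000 promoter signal, stage)`

  with ESC as reference, so `s(ESC) = 1`; tracks are multiplied by `s` and
  the scaled FPKM used downstream (`compute_scale_factor`, `apply_scale`).
* **Domain calling** — bins (1 kb broad regimes, 500 bp narrow regimes)
  with scaled FPKM ≥ 3 form seed domains; seeds within 2 × bin end-to-end
  are merged (`call_domains`, `domain_size_stats`,
  `annotate_domain_bases`).
* **Dynamics** — k-means domain-transition clustering, 5-kb track
  correlations, metagene/TSS profiles, gene-density correlation, and peak
  classification: promoter < 1 kb, distal > 2.5 kb from a TSS
  (`cluster_domain_transitions`, `correlate_tracks`, `metagene_profile`,
  `classify_peaks_by_tss`, `classify_peak_response`).
* **Allelic analysis** — fragments ≥ 140 bp with MAPQ ≥ 30, deduplicated,
  assigned maternal/paternal by SNP evidence; per-bin log2(M/P) bias and
  paired t-tests over region sets such as imprinting control regions
  (`filter_fragments`, `assign_alleles`, `allelic_bias`,
  `compare_allelic_regions`).
* **Repeat expression** — pseudo-genome with one chromosome per repeat
  family, instances joined by 200-N spacers; family-level counts by
  exact-substring read placement (`build_pseudo_genome`,
  `quantify_repeat_reads`).
* **Gene sets** — minor/major ZGA, maternal decay and PcG targets from DE
  tables at fold-change/padj cutoffs 2/0.05 and 4/0.01, mean FPKM ≥ 1, PcG
  FPKM < 0.1 (`define_major_zga`, `define_minor_zga`,
  `define_maternal_decay`, `define_pcg_targets`).
* **Hi-C pile-up** — aggregate contact enrichment between distal elements
  and promoters at 10 kb resolution with distance-preserving shifted
  controls (`enumerate_anchor_pairs`, `pileup`).
* **Synthetic data** — a first-class generator plants all of the above
  (domains, allelic asymmetry, SNP-bearing fragments, loops, expression
  classes) with a ground-truth ledger, so every stage is testable without
  external data (`generate_genome`, `generate_stage_tracks`, ...).

## Worked example

```r
library(acetydyn)
result <- run_pipeline(seed = 1)
result
```

```
Synthetic acetylation-dynamics study (seed 1)
Scale factors:
   stage scale_factor
      GV    0.5911700
     MII    1.5401170
  zygote    0.5888706
 early2C    0.6050661
  late2C    0.6217772
  morula    1.0344082
     ESC    1.0000000
Domains per stage (n, median bp, total bases):
  GV       n=  25  median=   57000  total= 1.338e+06
  MII      n=   6  median=    4000  total=     24000
  zygote   n=  20  median=   88000  total= 1.775e+06
  early2C  n=  60  median=    2000  total=    120500
  late2C   n=  60  median=    2000  total=    117500
  morula   n=  50  median=    1000  total=     60500
  ESC      n=  80  median=    1000  total=     93500
Allelic: 17195/20000 fragments kept; concordance 100.0%
Pile-up center ratio: ZGA 6.42, control 1.00
```

Reading the output: the scale factors make each stage's top-promoter median
match the ESC reference (ESC pinned at exactly 1; broad stages such as GV
and zygote scale *down* because their signal is spread wide). The domain
table shows the three waves — GV's 1.34 Mb of broad domain (median 57 kb)
collapsing to 24 kb total in MII, re-established in zygotes (1.78 Mb,
median 88 kb, with the paternal allele contributing twice the maternal
bases), then resolving to ~2 kb peaks from the early 2-cell stage. Of
20,000 simulated fragments, 17,195 survive the length/MAPQ/duplicate
filters, and every SNP-assigned fragment matches its true allele. The Hi-C
pile-up centered on distal-element–ZGA-promoter pairs is 6.4-fold enriched
over distance-matched shifted controls, while PcG-promoter control anchors
show no enrichment (1.00).

`result$report` holds the same numbers machine-readably (plus per-stage
recovery metrics against the generator's ground-truth ledger);
`run_pipeline(..., outdir = "out")` writes domain BEDs, scale-factor and
gene-set TSVs, the report JSON and the ledger.

## Documentation

The methods vignette (`vignettes/acetylation-dynamics.Rmd`) documents the
model assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, and the package's
numerical conventions (coordinate system, tie-breaking, degenerate-input
behaviour).
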