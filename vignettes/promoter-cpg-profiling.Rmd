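---
title: "Profiling CpG dinucleotide density in promoter domains"
author: "promoterCpG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling CpG dinucleotide density in promoter domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promoterCpG)
```

## The question the package addresses

In animals with active cytosine methylation, the CpG dinucleotide is the
methylation substrate, and its density around transcriptional start sites
(TSSs) carries a regulatory and evolutionary signal: methylated CpGs decay
into TpGs over evolutionary time, so regions under methylation pressure
become CpG-depleted, while promoters kept methylation-free accumulate or
retain CpGs. In invertebrate genomes, where methylation is mosaic, mapping
where CpGs concentrate in upstream promoter domains — and whether that
differs between functional groups of genes — is a first, purely
sequence-based probe of promoter methylation potential.

`promoterCpG` implements that analysis end to end:

1. strand-aware extraction of TSS-anchored windows (default −3000..+500)
   from a genome FASTA and GFF3 annotation;
2. per-position CpG (and mirror GpC) density as a 51-bp centered moving
   average, normalized either to G+C content or to the classical
   observed/expected (o/e) ratio, aggregated over genes;
3. randomized control gene models built from genome base composition plus a
   codon-usage-faithful first exon;
4. region-wise CpG frequency comparisons between KEGG functional classes
   (Kruskal–Wallis with Bonferroni correction, Dunn post hoc) and between a
   focal gene set and the genomic background (Wilcoxon rank sum);
5. a synthetic-genome generator with a controllable positional CpG o/e
   profile, so the whole pipeline can be validated against known truth
   without downloading any genome.

## Windows, coordinates and conventions

Gene models are held in a `GRanges` (1-based, the Bioconductor convention);
the TSS is carried as a 0-based coordinate of the first transcribed base in
the `tss` metadata column, computed strand-aware from the gene feature's 5'
end (start for `+`, end for `−`). A single window is extracted per gene —
annotations at this level rarely resolve alternative TSSs reliably, and
per-gene counts are what the downstream statistics consume.

Windows are read 5'→3' in transcriptional orientation; minus-strand genes
are reverse-complemented at extraction. Windows truncated at a scaffold end
are retained for profiling (positions simply absent) but
`filterFullUpstream()` drops them for the headline analyses, which keeps
gene sets comparable: a window missing its far upstream would otherwise
contribute only to TSS-proximal positions. Soft-masked lowercase is
upper-cased and ignored; `N` bases stay in the sequence but are excluded
from every dinucleotide and mononucleotide denominator.

A dinucleotide is indexed at its first base (the C of a CpG), and relative
position 0 is the TSS base itself. Region boundaries are half-open, so the
four analysis regions R1 = [0, 500), R2 = [−500, 0), R3 = [−1000, −500),
R4 = [−3000, −1000) tile the window exactly, with position 0 in R1.

## The density profile

At each relative position the profiler reports the fraction of motif starts
in the 51-position window centered there, the G+C fraction of the same
window, and a normalized density. Choices worth stating explicitly:

* **Kernel.** The moving average is uniform-weight (simple). A triangular
  kernel is available through `profileConfig(kernel = "triangular")` as a
  sensitivity check; in practice the two differ negligibly at width 51.
* **No edge padding.** Positions whose centered window is not fully inside
  the sequence are absent rather than padded — fabricating sequence at the
  domain edges would bias exactly the far-upstream background the
  enrichment ratio divides by. The cost is 25 positions at each end.
* **Normalization.** `gc_fraction` (density ÷ windowed G+C fraction) is the
  default, matching how composite profiles are usually drawn; the
  `obs_over_exp` mode (density ÷ windowed f~C~·f~G~) is the classical CpG
  o/e ratio and is the right scale for parameter recovery, because the
  synthetic generator is parameterized directly in o/e units. Zero
  denominators mark the position missing, never infinite.
* **TSS enrichment ratio.** The near-TSS interval is fixed at [−100, 0) and
  the background at [−3000, −2000) — the background deliberately starts
  where the upstream enrichment ramp has decayed away, and both intervals
  are arguments of `tssEnrichmentRatio()`.

Region-wise CpG frequencies (`regionFrequencyTable()`) use raw, unsmoothed
counts: smoothing across a region boundary would leak signal between
regions and blur exactly the contrast the rank tests measure. A smoothed
variant can be had by profiling first and averaging, but is not the
default.

## Randomized controls and the GpC mirror

Control gene models (`generateRandomizedModels()`) are built composition-up:
3000 upstream bases i.i.d. from the genome base frequencies, then a 500-bp
"first exon" of i.i.d. codons drawn from a codon usage table (167 codons,
final base dropped; 500 is not divisible by 3 and the remainder has no
biological meaning in a control). One shared control set per configuration
is generated rather than one control per real gene, since the control trace
is a single aggregated curve. Codons carry no start/stop grammar — the
controls model composition, not gene structure.

The GpC mirror control exploits an exact identity: counting CpG on the
reversed sequence equals counting GpC on the forward sequence with
positions reversed. `mirrorControlProfile()` therefore profiles motif
`"GC"` forward, which keeps both control curves on the same coordinate
grid. On i.i.d. sequence both curves concentrate around f~C~·f~G~, which is
what the acceptance suite verifies.

## Rank statistics

The region-wise comparisons use rank statistics computed in the package:
Kruskal–Wallis H with mid-ranks and the standard tie-correction divisor,
Dunn's pairwise z with the pooled tie-corrected variance, and the Wilcoxon
rank sum with exact enumeration for pooled n ≤ 20 without ties (doubled
one-sided tail, capped at 1) and a tie-corrected, continuity-corrected
normal approximation otherwise. Base R's `kruskal.test` and `wilcox.test`
serve as independent cross-checks in the test suite. Decisions that the
analysis surface exposes rather than hides:

* The Bonferroni family is the **four regions**, for both the
  Kruskal–Wallis and the Wilcoxon analyses (`family` argument); correcting
  across classes instead, or additionally, is a caller choice.
* Dunn pairwise p-values carry no additional correction by default
  (`dunnAdjust = "none"`); group letter codes are produced at the chosen α
  by an insert-and-absorb compact-letter-display.
* Post-hoc tests run only in regions whose adjusted Kruskal–Wallis p is
  below α.
* Ties are broken by mid-ranks throughout; a region where every value is
  identical yields H = 0, p = 1 rather than an error.

## The synthetic generator

`syntheticGenomeConfig()` fixes a generative truth: per-position CpG o/e
ρ(x) equal to a background level up to `rampStart` (default −2000), rising
linearly to `rampPeakFactor` × background at the TSS, and flat at the peak
through the first exon; multiplicative class- or focal-set offsets over
stated intervals; genes on both strands packed onto multiple scaffolds with
random intergenic sequence. The defaults — uniform base composition,
background o/e 0.6 (a typical invertebrate depletion level), ramp from
−2000 reaching 1.38× at the TSS, even strand split — are the study
conditions the pipeline is validated under.

Emission is a first-order Markov chain conditioning only on whether the
previous base is C. After a C, the next base is G with probability
ρ(x)·f~G~ (x the position of the C, the dinucleotide's index position).
After any other base, the distribution is the *compensating* one that keeps
every per-position base marginal exactly at the configured frequencies.
This second piece matters: if non-C-following bases were drawn plainly
i.i.d., the marginal P(C) would drift up and P(G) down by a ρ-dependent
amount, so the realized CpG start probability and the measured o/e would be
biased (at uniform composition, by ≈ +6% at ρ = 0.6 against ≈ +4.5% at the
ramp peak — enough to distort a 1.38 target to ≈ 1.29). With the
compensating distribution, P(CpG start at x) = f~C~·ρ(x)·f~G~ holds exactly
and the windowed o/e estimator recovers ρ(x) directly. Generability
requires ρ(x)·f~G~ ≤ 1, ρ(x)·f~C~ ≤ 1 and a compensable composition; the
configuration constructor checks all three for every class/focal track
before anything is generated.

What the generator deliberately does **not** emulate: methylation states,
C→T deamination processes, isochore structure, repeat content,
higher-order (beyond first-order) sequence dependence, and codon structure
in the synthetic exon (the peak-ρ emission continues through [0, +500);
codon realism lives in the randomized-control generator, which has its own
path). Passing tests on this generator therefore demonstrate that the
pipeline measures what it claims on sequences with known positional CpG
structure — not that any particular real genome satisfies the generative
assumptions.

## Validation scale and reproducibility

The test suite validates parameter recovery at 5,000 synthetic promoters
(recovered enrichment within ±0.05 of the generative 1.38, and within
±0.03 of 1.0 when the ramp is flat at 2,000 promoters), control/mirror
equivalence at 2,000 randomized models against the analytic f~C~·f~G~ law,
strand symmetry at 2,000 mixed-strand genes, and the type-I error of the
class analysis over 200 replicates of 100 genes per class — sizes at which
the binomial sampling bounds used in the assertions are sharp enough to be
meaningful while the whole suite stays quick. Every stochastic step is
seeded; `simulateDataset()` writes byte-identical files for a fixed
configuration.

## Worked example

```{r example, eval = FALSE}
cfg <- syntheticGenomeConfig(nGenes = 1000, rampPeakFactor = 1.38, seed = 1)
sim <- simulateDataset(cfg)
win <- filterFullUpstream(extractPromoterWindows(sim$genome, sim$genes))
prof <- profileWindows(win, profileConfig(normalization = "obs_over_exp"))
tssEnrichmentRatio(prof)

tab <- regionFrequencyTable(win)
sets <- split(sim$geneTable$gene_id, sim$geneTable$class)
classRegionAnalysis(tab, sets)
```

## Known limitations

* One window per gene from the annotated gene feature: no isoform-level
  TSSs, no UTR inference. Overlapping genes are windowed independently —
  an upstream domain may run into a neighboring gene, as it will in any
  compact genome.
* The published gene counts of real cnidarian datasets depend on which
  annotation tier (gene vs mRNA) defined the TSSs; `parseGeneModels()`
  exposes `featureType` so either convention can be reproduced.
* `gc_fraction` normalization is a ratio of two smoothed estimates and is
  only defined where the windowed G+C fraction is positive.
* The exact enumeration path of the Wilcoxon test is limited to pooled
  n ≤ 20; beyond that the normal approximation (continuity- and
  tie-corrected) is used, which the suite shows is within 0.02 of the
  permutation answer at n = 8 vs 8.
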