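---
title: "Models and methods behind dicodon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dicodon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicodon)
```

`dicodon` implements the computational side of a barcoded reporter assay
that measures how tandem codon-pair repeats affect steady-state mRNA
levels in budding yeast. This vignette explains the statistical model,
the design of the synthetic-data generator, and the numerical and design
choices that a user tuning the package should understand.

## The measurement model

Each insert *i* (a 6-nt codon pair repeated 8× to 48 nt, fused in frame
into a reporter ORF) is linked to a set of random 24-nt barcodes. After
genomic integration, a barcode *b*'s read count in the cDNA sample is
proportional to its clone abundance times the insert's relative mRNA
level, while its count in the genomic DNA sample is proportional to clone
abundance alone. The per-insert level is therefore estimated as

$$\hat{L}_i = \frac{1}{B}\sum_{r=1}^{B}
  \log_2 \frac{\sum_{b \in S_r} m_b}{\sum_{b \in S_r} g_b},$$

where $m_b$ and $g_b$ are the mRNA and gDNA counts of barcode *b* and
$S_r$ is the *r*-th bootstrap resample (barcodes drawn with replacement,
same size as the original set; $B = 100$ by default). Summing counts
before taking the ratio makes the estimator robust to individual
low-count barcodes; the bootstrap standard deviation is reported as the
spread. Resampling a single barcode is constant, so one-barcode inserts
get spread exactly 0.

Levels are reported in log2 units and normalized per library:
**median** normalization (subtract the library median) is the default for
the 4096-insert library, where the median insert is safely assumed
neutral; **spike-in** normalization (subtract the mean level of clones of
known effect carried through every sample) enables comparisons across
genotypes, where the library median itself may shift; **RPM** rescales
both samples to reads-per-million before the ratio, which is a global
level shift of $\log_2(\text{total gDNA}/\text{total mRNA})$.

### Filters

Barcodes need at least `min_reads = 10` reads in the **gDNA** sample.
The gDNA count proxies clone abundance, and mRNA depletion is the signal
being measured, so thresholding the mRNA side would bias strong effects;
an independent mRNA-side threshold exists (`min_reads_mrna`, default 0)
for users who want it. Inserts need `min_barcodes = 2` surviving barcodes
(the assay's own analyses used 2–4 depending on the experiment; it is
per-experiment configurable). An optional variability filter removes
inserts whose per-barcode log2 ratios have a coefficient of variation
(sd/|mean|) above `cv_max`; it is disabled by default because no
principled universal cutoff exists — inspect the spread column before
enabling it.

A bootstrap resample with zero summed mRNA has no finite log-ratio. By
default such inserts are flagged missing (`zero_mrna`) rather than
imputed, because adding a pseudocount would bias exactly the strongest
effects; `pseudocount = 0.5` (added to both sums) is available when a
finite estimate is preferred.

## Linkage and collision filtering

Barcodes are assigned to inserts from linkage reads by exact matching of
the 48-nt insert segment against the reference list. Exact matching is
deliberate: a single substitution in an insert can convert it into a
*different valid library member* (especially in the DMS design), so fuzzy
matching would misassign rather than rescue reads.

Two collision filters follow. Barcodes observed with ≥ 2 distinct inserts
are removed entirely. Then, among the remaining barcodes, every pair
within Levenshtein distance `max_dist = 2` loses its lower-count member
(ties keep the lexicographically smaller string). We apply the rule to
*every* qualifying pair rather than cascading removals in a
processing-order-dependent way: the pairwise rule is order-free,
idempotent (filtering a filtered table is a no-op), and provably monotone
in `max_dist`, three properties the test suite checks. Candidate pairs
are found by pigeonhole 8-mer chunking — for 24-nt barcodes, any pair
within 2 edits must share an 8-mer chunk at an offset shifted by at most
2 — and verified with `utils::adist()`; small inputs use the full
distance matrix. Both paths are checked against an O(n²) brute-force
oracle.

## UMI counting

Where reads carry a 7-nt unique molecular identifier, counting distinct
(barcode, UMI) or (insert, UMI) combinations removes PCR duplicates. UMI
space is finite (4⁷ = 16384), so distinct-UMI counts saturate at high
molecule numbers; the simulator reproduces this by drawing UMIs uniformly
per molecule. This is why the package's exactness tests for the DMS path
use raw-read counting: UMI collisions are real, stochastic, and correctly
break exact proportionality.

## The synthetic-data generator

The simulator exists so that every pipeline stage can be validated
against known truth. It emulates:

- **Library structure**: 4096 codon-pair inserts, `barcodes_per_insert =
  100` plasmid barcodes each, thinned by a binomial bottleneck
  (`bottleneck = 0.2`) so the median surviving clones per insert is ~20 —
  the plasmid-pool-to-genome-integration funnel of the real assay.
- **Effects**: a three-class mixture. Stop-containing inserts form an
  NMD class (N(−3, 0.5²) log2 units); 10% of stop-free inserts are
  destabilized (N(−2, 0.5²), matching the magnitude at which stalling
  dipeptides depress mRNA levels, comparable to stop codons); the rest
  are neutral (N(0, 0.2²)). These defaults were fixed once, from the
  qualitative structure of the assay (most dipeptides neutral, a
  destabilized tail, stop codons strongly depleted), and are
  configuration, not fitting, parameters.
- **Abundances**: log-normal (meanlog 0, sdlog 1) per clone — the
  heavy-tailed clone-size distributions typical of pooled integrations.
- **Counts**: gamma-Poisson (negative binomial) with dispersion
  φ = 0.3 around means proportional to abundance (gDNA) or abundance ×
  2^effect (cDNA). Overdispersion of this order is standard for amplicon
  counts; φ = 0 gives Poisson.
- **Errors**: per-base substitutions at 10⁻³; indels, chimeras and
  quality-score realism are deliberately out of scope (the analysis never
  reads qualities).
- **Spike-ins**: two fixed clones of known insert, barcode, and effect 0
  at median abundance, mirroring control strains mixed into cultures.

What the simulator does **not** model — PCR jackpotting, cross-sample
index hopping, GC-dependent dropout, position-dependent error rates —
bounds what a passing test shows about real data: the pipeline's
*statistical* machinery is correct, not that any particular real library
is free of artefacts.

### The noise-free mode and exactness

With `noise_free = TRUE`, each clone emits exactly `round()` of its
expected read count. Exact recovery of truth (to 1e-9 after median
normalization) then holds whenever expected counts are integral, because
every barcode of an insert shares the same mRNA/gDNA ratio and the
bootstrap becomes constant. The exactness scenarios therefore use uniform
integer abundances and effects on the dyadic grid {1, 0, −1, −2}; with
arbitrary real abundances, rounding to whole reads necessarily perturbs
counts and only approximate recovery is possible. Under default noise at
study scale (4096 inserts, ~20 barcodes/insert, ~50 reads/barcode), the
pipeline recovers true effects with Pearson r ≈ 0.94 (recomputed by
`scripts/acceptance.R` at every run).

## Analytics

**Positional means.** For each codon (or amino acid) and each pair
position, the mean level over the 64 inserts carrying it there, then
median-centred across units within each position (so the table's
per-position median is 0 by construction). Error bars are standard
deviations over contributing inserts.

**CSC.** The codon stability coefficient is the Pearson correlation
between a codon's frequency per insert (count/16) and insert level.
Codons with constant frequency are flagged, not errored. The CSC
inherits correlation's invariance to level shifts and positive count
scaling. Comparison against published CSC/AASC tables is supported only
via `correlate_with_reference()` with a user-supplied table; no external
values are bundled.

**Dipeptides.** Cell (aa1, aa2) averages the synonymous codon-pair
estimates with equal weight by default (each insert-level estimate is
already barcode-aggregated; weighting by barcode count is available by
flag). The full 21 × 21 grid (stop = `*`) is returned with missing cells
flagged.

**Frame rotations.** Reading a repeated hexamer k nt downstream equals
rotating it left by k; rotation is a group action modulo 6 and k = 3
swaps the codons. `frame_shift_correlation()` correlates frame-0
dipeptide levels with levels aggregated by the frame-k image, excluding
stop-containing dipeptides by default (a stop in the shifted frame would
truncate translation, making its "level" uninterpretable).

**Genotype comparisons.** Each level set is median-normalized within its
own library (the library median itself can shift between strains), then
mutant is regressed on baseline by OLS — the axis orientation puts the
perturbed strain on the vertical axis, so negative residuals mean
"stabilized in the mutant relative to the trend". Flags use *raw* log2
residuals with a strict `< −2` cutoff, and a separate fold-change flag
(mutant − baseline ≥ log2 1.5). Raw rather than studentized residuals
keep the threshold in interpretable log2 units; with hundreds of
dipeptides the leverage correction is ~0.3%.

**DMS.** Insert-UMI counts per replicate give per-variant log2 ratios,
averaged across replicates (variants missing from a replicate are
averaged over the replicates present and exposed via `n_replicates`, not
imputed) and normalized by the mean spike-in level per genotype. The 16
design entries that reproduce the backbone sequence are indistinguishable
by sequencing and collapse to one wild-type row (1009 distinct sequences
from 1024 design entries). The matrix averages synonymous codons per
(position, amino acid), marking the wild-type amino acid (F at odd, K at
even positions). Position-wise genotype tests use the two-sided Wilcoxon
rank-sum test — exact null enumeration when the combined sample is ≤ 20
without ties, the continuity-corrected normal approximation otherwise —
on replicate-averaged, stop-free variant levels (a pooling flag is the
natural extension if replicates should enter as independent
observations).

## Numerical and design notes

- **Coordinates**: ORF slices are 1-based inclusive (\[253, 300\] is
  48 nt and codon-aligned); internal string indexing is R's 1-based
  `substr`.
- **Genetic code**: the standard nuclear code via Biostrings; stop
  rendered `*`.
- **DMS backbone**: the (FK)₈ nucleotide backbone alternates synonymous
  codons (TTT-AAA-TTC-AAG ×4) to avoid a pure nucleotide repeat; any
  16-codon backbone can be supplied.
- **Endogenous fragments**: every-2nd-gene selection by expression rank,
  with explicit, configurable exclusions (ORF ≥ 300 nt; no frame-0 stop
  in the slice, which would truncate the reporter fusion). The published
  panel's exact gene list is not reproducible without its expression
  table, so the count of fragments is input-dependent by design.
- **Determinism**: all randomness flows from R's global RNG;
  `run_pipeline()` seeds it once from the config, and identical configs
  produce byte-identical FASTQ and tables (tested via checksums).
- **Problem sizes in the test suite**: the end-to-end recovery checks run
  the full 4096-insert library at ~50 reads per barcode (a few minutes);
  exactness checks use a 256-insert subset, which is sufficient because
  exactness is per-insert and does not improve with scale.

## Known limitations

- Exact insert matching means reads with any insert-segment error are
  lost rather than rescued; at a 10⁻³ substitution rate this discards
  ~5% of 48-nt insert reads, uniformly across variants.
- The collision filter's pairwise rule can remove both members of a
  mutual near-duplicate chain where a cascade would keep every other
  member; with random VNN⁸ barcodes such chains are vanishingly rare.
- Replicate variance shrinkage and differential-expression style
  modelling are out of scope; the bootstrap spread is a per-insert
  description, not a shrunken posterior.
- The simulator's effect mixture is a caricature: real dipeptide effects
  are correlated across synonymous pairs and amino-acid chemistry, which
  the generator ignores (each insert draws independently).
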