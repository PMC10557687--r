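# dicodon

Massively parallel reporter assays (MPRAs) can measure how short coding
motifs change steady-state mRNA levels: thousands of designed inserts are
cloned upstream of a reporter, tagged with random DNA barcodes, integrated
into *S. cerevisiae*, and the ratio of each barcode's abundance in cDNA to
its abundance in genomic DNA reads out the relative mRNA level of its
insert. Applied to all 4096 codon pairs repeated in tandem (8× of each
6-nt "dicodon"), this design reveals which dipeptide repeats trigger
co-translational mRNA decay through ribosome-associated quality control
(RQC), and which codons destabilize mRNAs through codon optimality.

`dicodon` is a tidyverse-style R toolkit for every computational stage of
such an assay:

- **Library design** — enumerate the 4096-member codon-pair repeat
  library, the 1024-variant (FK)₈ deep mutational scanning (DMS) design,
  endogenous ORF fragment panels (the 48-nt slice \[253, 300\] of every
  2nd gene by expression), and stop-free 24-nt VNN⁸ barcodes.
- **Simulation** — generate FASTQ reads with known ground-truth effects
  (three-class effect mixture, log-normal clone abundances, binomial
  bottleneck, negative-binomial counts, 7-nt UMIs, spike-in clones), so
  the whole pipeline is testable without sequencing data.
- **Linkage** — assign barcodes to inserts from linkage reads, drop
  barcodes seen with multiple inserts, and remove near-duplicate barcodes
  (edit distance ≤ 2, lower count loses).
- **Quantification** — UMI-aware barcode/insert counting, read-count and
  barcode-count filters, and the per-insert mRNA level

  `level_i = mean_b[ log2( Σ mRNA_b / Σ gDNA_b ) ]`

  over B = 100 bootstrap resamples of the insert's barcodes, with median,
  spike-in, or RPM normalization.
- **Analytics** — positional codon/amino-acid means, codon stability
  coefficients (CSC: per-codon Pearson correlation between insert codon
  frequency and mRNA level), dipeptide matrices, reading-frame rotation
  comparisons (rotating a repeated hexamer left by k ≡ reading it k nt
  downstream; +3 swaps the codons), genotype regression comparisons with
  residual and fold-change flags, and DMS position × amino-acid matrices
  with position-wise Wilcoxon rank-sum tests.

Fitted comparisons support `tidy()`/`glance()`, and each result type has a
ggplot2 helper (`plot_positional_means()`, `plot_dipeptide_matrix()`,
`plot_dms_matrix()`, `autoplot()`).

## Worked example

Simulate a 64-insert assay with known effects and quantify it end to end:

```r
library(dicodon)

lib <- codon_pair_library()
head(lib, 3)
#> # A tibble: 3 × 7
#>   insert_id   codon1 codon2 hexamer insert_seq                dipeptide has_stop
#> 1 pair_AAAAAA AAA    AAA    AAAAAA  AAAAAAAAAAAAAAAAAAAAAAAA… KK        FALSE
#> 2 pair_AAAAAC AAA    AAC    AAAAAC  AAAAACAAAAACAAAAACAAAAAC… KN        FALSE
#> 3 pair_AAAAAG AAA    AAG    AAAAAG  AAAAAGAAAAAGAAAAAGAAAAAG… KK        FALSE

cfg <- pipeline_config(
  output_dir = "demo_run", seed = 7,
  n_inserts = 64, barcodes_per_insert = 100, bottleneck = 0.2,
  depth_linkage = 2e5, depth_gdna = 4e5, depth_mrna = 4e5
)
res <- run_pipeline(cfg)
#> [design]   0.2s 64 inserts
#> [simulate]   4.1s 1300 clones
#> [link]   6.2s 1300 barcodes retained
#> [count]   8.1s 1298 gDNA / 1298 mRNA barcodes
#> [quantify]   8.1s 64 inserts quantified
#> [analyze]   8.3s tables written

head(res$levels, 4)
#> # A tibble: 4 × 5
#>   insert_id    level spread n_barcodes zero_mrna
#> 1 pair_AAAAAA  0.632  0.317         24 FALSE
#> 2 pair_AAAAAC  0.887  0.308         22 FALSE
#> 3 pair_AAAAAG -0.603  0.470         14 FALSE
#> 4 pair_AAAAAT -1.86   0.335         19 FALSE
```

`level` is the bootstrapped, median-normalized log2(cDNA/gDNA) estimate
for each insert, `spread` its bootstrap standard deviation, and
`n_barcodes` the barcodes that survived filtering (≥ 10 gDNA reads per
barcode, ≥ 2 barcodes per insert). Because this run is simulated, the
estimates can be checked against the generator's truth:

```r
truth <- dplyr::inner_join(res$levels, res$truth$inserts, by = "insert_id")
cor(truth$level, truth$effect)
#> [1] 0.942
```

At the full study scale (4096 inserts, ~20 barcodes per insert after the
bottleneck, ~50 reads per barcode) the same pipeline recovers the true
per-insert effects with Pearson r ≈ 0.94, and in the deterministic
noise-free mode it reproduces them exactly.

The stage functions compose directly when you have your own FASTQ files:
`extract_linkage_pairs() |> filter_barcode_collisions()`, then
`count_barcodes()`, `filter_counts()`, `quantify_inserts()`,
`normalize_levels()`, and the analytics (`positional_means()`,
`compute_csc()`, `dipeptide_levels()`, `frame_shift_correlation()`,
`compare_genotypes()`, `dms_levels()`, `positionwise_test()`, ...).

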