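# tadfish

Allele-resolved analysis of TAD-boundary proximity and gene activity from
high-throughput DNA/RNA FISH imaging.

## The problem

Topologically associating domains (TADs) are delimited by boundaries that
can be visualized, per chromosomal allele, as a pair of DNA FISH spots (5′
and 3′), while a nascent-RNA FISH spot marks whether the gene inside the
TAD is transcribing at that allele. Relating boundary behavior to gene
activity at the single-allele level requires a chain of image-analysis and
statistical steps: nucleus segmentation, FISH spot detection, registration
between the DNA and RNA acquisitions, ploidy-aware quality control,
matching 5′ and 3′ signals into alleles, center-to-center distance
measurement, activity classification, and nonparametric comparisons.
`tadfish` implements that chain end to end, together with a ground-truthed
synthetic-data generator so every stage is verifiable without any external
download.

## The model at the core

Per allele, the 5′→3′ boundary displacement is modeled as a two-state
isotropic Gaussian mixture: with probability *p* the allele is *paired*
(per-axis s.d. *s_p*), otherwise *unpaired* (s.d. *s_u*), so the 3D
distance *d* follows

> F(d) = p · F_χ(d/s_p) + (1 − p) · F_χ(d/s_u),   F_χ = CDF of χ (3 df).

Key measurement conventions (all configurable, defaults as stated):

* pixel size 0.152 µm XY, z step 1.0 µm; distances are centroid-to-centroid
  in physical units, in 2D (max projection) or 3D mode;
* boundary pairs are *closest neighbors*: greedy globally-closest matching
  of 5′ and 3′ spots within a QC-passing cell;
* an allele is **active** if a registered RNA signal lies within 1 µm
  (strict `<`) of either boundary spot;
* the **interaction fraction** is the fraction of alleles with boundary
  distance below 250 nm (strict `<`);
* QC: diploid cells need exactly 2+2 DNA signals and ≤2 RNA signals
  (triploid: 2–3 per DNA channel, ≤3 RNA);
* comparisons: Mann-Whitney U (exact for small samples), Kolmogorov-Smirnov,
  Kruskal-Wallis + Dunn-Bonferroni, two-way ANOVA on per-experiment medians,
  and within-nucleus allele-pair correlation with randomized pair order.

## Worked example

Simulate 500 diploid cells under default conditions, run the full pipeline,
and read the statistics report:

```r
library(tadfish)
res <- run_pipeline(list(n_cells = 500, seed = 1), "demo_out")
res$stats_report[1:2, c("test", "group1", "group2", "n1", "n2",
                        "statistic", "p_value", "category", "note")]
#>               test group1   group2   n1  n2 statistic p_value category
#> 1 distance_summary    all     <NA> 1000  NA  3.10e-01      NA     <NA>
#> 2     mann_whitney active inactive  312 688  1.06e+05   0.841       ns
#>                                            note
#> 1     iqr_um=0.4028;interaction_fraction=0.4390
#> 2 boundary distance, active vs inactive alleles
```

Reading the numbers: 1,000 alleles pass QC; their median projected (2D)
boundary distance is 0.310 µm with IQR 0.403 µm, and 43.9% of boundary
pairs lie within 250 nm (2D distances sit below the ~0.41 µm 3D population
median because the axial component is projected out). 312 alleles carry a
nascent transcription site; active and inactive alleles have
indistinguishable distance distributions (Mann-Whitney p = 0.84, "ns") —
as they must here, since the default generator draws activity independently
of boundary state. The report also contains the silent/monoallelic/biallelic
cell fractions (0.470 / 0.436 / 0.094, binomial for independent alleles)
and within-nucleus allele-pair correlations (Pearson r = −0.026, p = 0.56).

Per-stage record counts land in `demo_out/provenance.json`; spot, allele
and QC tables are CSVs in the same directory. Setting
`simulate = list(p_pair_active = 0.6)` couples activity to pairing and the
same comparison rejects decisively.

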