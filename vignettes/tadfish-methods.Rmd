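---
title: "Methods: allele-resolved TAD-boundary proximity and gene activity from DNA/RNA FISH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-resolved TAD-boundary proximity and gene activity from DNA/RNA FISH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

High-throughput combined DNA/RNA FISH visualizes, in each nucleus, the two
flanking boundaries of a topologically associating domain (TAD) as two
diffraction-limited DNA spots per allele (one 5′, one 3′) together with the
nascent transcript of a gene inside the TAD as an RNA spot. From these
images one wants, per allele: the 5′–3′ boundary center-to-center distance,
whether the allele is transcriptionally active, and — across many alleles —
the fraction of boundary pairs closer than an interaction threshold, plus
statistical comparisons between conditions and between active and inactive
alleles.

`tadfish` implements that chain as composable functions over tibbles:
simulation (`simulate_ground_truth()`, `degrade_to_spot_table()`,
`render_stack()`), calibrated image IO (`image_stack()`, `read_stack()`,
`max_project()`), detection (`segment_nuclei()`, `detect_spots()`,
`register_translation()`, `assign_spots_to_nuclei()`), allele calling
(`qc_filter_cells()`, `pair_boundaries()`, `boundary_distance()`,
`classify_activity()`, `interaction_fraction()`,
`expression_state_fractions()`), and statistics (`mann_whitney()`,
`ks_test()`, `kruskal_dunn()`, `compare_experiment_means()`,
`allele_pair_correlation()`, `summarize_distances()`, `categorize_p()`),
orchestrated by `run_pipeline()`.

```{r, eval = FALSE}
library(tadfish)
res <- run_pipeline(list(n_cells = 2000, seed = 1), "demo_out")
res$stats_report
```

## The synthetic-data generator

Real deposited image sets are far too large for routine verification, so
every stage is validated against a generative model whose ground truth is
known exactly.

**Geometry.** Nuclei are non-overlapping spheres (default radius 3 µm)
placed by rejection sampling in a field imaged at 0.152 µm XY pixel size
with 8 z planes at 1.0 µm steps (a 7 µm axial span) — the acquisition
geometry of the high-throughput assay this emulates. Placement retries are
capped at 100 × `n_cells`; configurations denser than the ~0.55 jamming
coverage of random sequential disk packing are rejected up front.

**Boundary distances.** Each allele draws a pairing state
Bernoulli(`p_pair`) and a 5′→3′ displacement from an isotropic Gaussian
with per-axis standard deviation `paired_scale_um` (paired state) or
`unpaired_scale_um` (unpaired). The 3D distance is therefore
`scale · χ₃` (chi distribution, 3 df), and the population obeys the mixture
CDF `F(d) = p·F_χ(d/s_p) + (1−p)·F_χ(d/s_u)` — a closed form used as an
oracle throughout the tests. The two-state form is the simplest model that
reproduces infrequent, transient boundary pairing; it is a stand-in for
verification, not a claim about the true distance law of any locus.

**Defaults as study conditions.** `p_pair = 0.3`, `paired_scale_um = 0.08`,
`unpaired_scale_um = 0.35` put the population median 3D distance at
~0.41 µm and the fraction of alleles below 250 nm at ~0.33, the scale
reported for TAD-boundary loci by high-throughput FISH; `p_active = 0.3`
gives mostly silent/monoallelic cells. `rna_offset_scale_um = 0.2` anchors
the nascent-RNA spot at the 5′ boundary (genes in the emulated TADs lie
near one boundary) with >95% of RNA signals within 1 µm of the anchor —
consistent with the empirical justification of the 1 µm activity radius.
These values were fixed once, from the published scale of the quantities,
and are not tuned per test.

**Coupling knob.** `p_pair_active` (default `= p_pair`) sets the pairing
probability of active alleles separately. The default encodes the null of
interest — activity independent of boundary proximity; raising it simulates
a coupled alternative so the power of the comparison can be demonstrated.

**Degradation and rendering.** `degrade_to_spot_table()` bypasses imaging:
per-channel Bernoulli detection (`detect_eff`), Gaussian localization noise
(`loc_noise_um`), and a rigid shift of the RNA acquisition
(`channel_shift_px`) applied before registration. `render_stack()` produces
the full 4-channel stack: DAPI as PSF-blurred nuclear disks, each FISH spot
as a 3D Gaussian (σ = 1.3 px laterally; axially `spot_sigma_z_um`,
defaulting to 3× the lateral physical width — the typical axial elongation
of a confocal PSF, without which spots midway between 1 µm z planes would
render at a few percent of their amplitude), plus background and Poisson
shot noise. Photophysics (blinking, chromatic field distortions), irregular
nuclear shapes, and replication-dependent spot doubling are deliberately
out of scope — so passing round-trip tests demonstrates correctness of the
measurement chain on well-behaved data, not robustness to every real-world
artifact.

**Determinism.** One root seed; each cell consumes a child stream derived
by counter, so enlarging `n_cells` leaves earlier cells bit-identical. A
subtle design point: the boundary displacement vector is drawn *first* and
only the allele midpoint is re-sampled when the pair does not fit inside
the nucleus. Conditioning on the midpoint rather than the displacement
keeps the distance law exactly the stated mixture, which is what makes the
closed-form oracles legitimate.

## Detection choices

Nucleus segmentation (Otsu threshold → hole filling → distance-transform
watershed, built on EBImage primitives) is a transparent stand-in with the
same contract as the learned segmenters used on real material; it is
sufficient for smooth synthetic nuclei and is not claimed to match them
elsewhere. Border-touching nuclei are excluded by default because distances
near crops are unreliable.

Spot detection is Laplacian-of-Gaussian at scale `sigma_px` (default 1.3 px,
matched to a ~200 nm PSF at 152 nm pixels). The threshold is
`min_snr` (default 8) times the robust spread of the response (MAD × 1.4826)
— one tunable, insensitive to background level. A numerical floor of
10⁻⁹ × max response keeps FFT convolution ripple from registering as
detections on noise-free images. Subpixel centroids are intensity-weighted
means over a window of half-width ⌈σ⌉ after subtracting the window-border
median; plateau ties in the maximum filter resolve to the lexicographically
smallest (x, y). The default analysis runs on 2D maximum-intensity
projections; `mode = "3d"` adds the z centroid of the axial profile under
the detected (y, x) position.

Channel registration is phase cross-correlation with upsampled-DFT subpixel
refinement (matrix-multiply evaluation in a ±1.5 px neighborhood at
1/`upsample` resolution). Integer shifts of circularly identical images are
recovered exactly; subpixel shifts to ~1/upsample px. Registration is
estimated from DAPI image pairs and then applied to RNA spot coordinates;
a `registered` flag prevents double application.

## Allele calling

Quality control admits diploid cells with exactly 2 + 2 boundary signals
and ≤ 2 RNA signals, and triploid cells with 2 or 3 signals per DNA channel
and ≤ 3 RNA signals; every failure carries a reason code.

"Closest neighbors" is made precise as greedy globally-closest matching:
repeatedly take the closest unmatched (5′, 3′) pair, ties broken by spot
index. For well-separated alleles this equals the minimum-total-distance
bipartite assignment; the regimes where the two diverge are crowded
configurations in which same-channel spots approach the ~2σ merge
resolution of the detector — configurations that cannot reach the allele
stage through real detection, because merged spots change the count and the
cell fails QC. Matching defaults to projected 2D coordinates, consistent
with measuring distances on 2D projections; both 2D and 3D distances are
reported, with 3D as an explicit mode.

Activity follows the strict rule: an allele is active when a registered RNA
signal lies within 1.0 µm (strict `<`) of either boundary spot. RNA spots
are assigned by increasing distance, at most one RNA per allele and one
allele per RNA; surplus RNA stays unassigned. Both the 1.0 µm radius and
the 250 nm interaction threshold (also strict `<`) are configuration fields
with these conventional defaults; strictness at the boundary is a
measure-zero choice stated for bit-exactness.

## Statistical layer

Distance distributions are summarized as median and full interquartile
range (Q3 − Q1) with linear-interpolation quantiles (R type 7) — the
quantile rule is convention-sensitive at small n, so it is fixed and
documented. Two-sample location comparisons use the Mann-Whitney U test:
exact null distribution when there are no ties and `n_a·n_b ≤ 400`,
tie-corrected normal approximation with continuity correction otherwise
(the crossover is configurable). Distribution shape comparisons use the
two-sample Kolmogorov–Smirnov test. Multi-group comparisons use
Kruskal-Wallis with tie correction followed by pairwise Dunn z tests,
Bonferroni-multiplied and capped at 1.

Multi-experiment aggregation mirrors how replicate experiments are
summarized in practice: one median per experiment, compared across a
condition × locus design by fixed-effects two-way ANOVA with
Bonferroni-adjusted condition contrasts within each locus. The factor
structure (experiments as replicates, interaction included when more than
one locus is present) is the minimal design consistent with that
aggregation and is an interpretation, stated as such. With a single
experiment per design cell the function refuses and points at the
distribution-level test. Mean-of-medians dispersion is reported both as SD
and SEM since either appears in figure-legend conventions.

Within-nucleus allele correlation uses only nuclei with exactly two
measured alleles; because allele identity is arbitrary, pair order is
randomized per nucleus under a stated seed, and both Pearson and Spearman
coefficients are reported.

Significance categories implement two schemes: the conventional
`*** < 0.001, ** < 0.01, * < 0.05, ns ≥ 0.05` (default) and an alternative
for very large allele samples (`*** < 1e-100`, `** < 1e-20`, `* < 0.01`).

## Verification strategy and problem sizes

The test suite checks each operation against an independent oracle: exact
enumeration for pairing (all bipartite assignments) and for small-sample
Mann-Whitney p-values (all group labelings), closed-form chi-mixture CDFs
for distance laws, brute-force ECDF scans for KS, simulation round trips
for rendering/detection/registration, and Monte-Carlo calibration for test
sizes. The end-to-end property checks use 1,000 cells for the pairing
oracle, 10,000 alleles for parameter recovery, 200 rendered cells for the
detection round trip, 5,000 cells for activity fidelity, 2,000 replicates
for each type-I-error calibration, and 200 runs × 2,000 alleles for the
null-versus-coupled power demonstration; these sizes give 3-standard-error
bands tight enough to be informative while keeping the default suite quick
on one CPU. `scripts/acceptance.R` recomputes the same quantities from
scratch against the installed package.

## Known limitations

* The mixture distance model and uniform allele placement are verification
  devices; real loci have chromosome-territory structure, and real nuclei
  are neither spherical nor uniform in probe accessibility.
* The segmentation stand-in targets smooth, well-separated nuclei only.
* No modeling of burst kinetics from RNA intensities, allele phasing, or
  hierarchical cell-level clustering in the statistics (distribution-level
  tests treat alleles as exchangeable, as the aggregation-by-experiment
  route is provided for the clustered view).
* Registration recovers a rigid translation only; rotation, scaling and
  field-dependent chromatic shifts are out of scope.
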