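---
title: "Gray- and white-matter functional network analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray- and white-matter functional network analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Overview

`gwnet` implements a voxel-level resting-state functional-connectivity (FC)
pipeline that treats white-matter (WM) BOLD signal as a first-class object
alongside gray matter (GM): cleaned voxel time series are summarized by their
whole-tissue correlation patterns, clustered into functional networks with
correlation-distance K-means, the number of networks is selected by fold-based
Dice stability, and network-level Fisher-z statistics compare two groups,
relate FC to behavior, and detect gray-white loops in the
significant-difference edge graph.

Because no subject-level data accompany this problem, the package ships a
synthetic BOLD phantom (`phantom_spec()`, `generate_cohort()`) with planted
network structure and known group differences. Every stage of the pipeline is
validated against that ground truth; the `analysis/` scripts run the whole
workflow as a narrative, and `scripts/acceptance.R` recomputes the headline
quantities from scratch.

The package is organised as an analysis workflow (numbered driver scripts over
library functions) rather than a command-line tool, because the object of
interest is a sequence of analyses over a cohort, not a utility a user would
invoke per-file; every computational step lives in `R/` where the tests can
reach it.

## The phantom: what it emulates and what it does not

`generate_cohort()` writes, per subject, a 4D BOLD NIfTI, a 6-column rigid-body
motion TSV (translations in mm, rotations in radians), and a 0/1/2 tissue
label NIfTI; plus one deep-nuclei atlas NIfTI and one behavioral TSV for the
cohort. The default ("desk-scale") conditions are a 24 x 24 x 12 grid of 3 mm
voxels, 200 volumes at TR 2 s, 4 GM + 5 WM planted networks, and 12 + 12
subjects — small enough that the full pipeline runs in minutes while every
moving part (masking, motion screening, spike regression, pairwise-masked
averaging, stability selection) is genuinely exercised. A full-scale cohort
(~44 + 49 subjects) is a parameter change, not a code change.

Key design choices:

* **Exact coupling control.** Each subject's network latents are independent
  Gaussian series mixed through the Cholesky factor of the coupling matrix, so
  the *population* correlation between latents equals the requested coupling
  exactly; the pain group receives `group_effect` deltas (default: +0.3 on one
  GM-WM edge). Couplings and coupling-plus-deltas are checked for positive
  semidefiniteness and rejected otherwise.
* **Contiguous parcels with CSF furrows.** Planted parcels are contiguous
  boxes (GM in the lower interior slab, WM above it), so mask-restricted
  smoothing preserves their structure. Same-tissue parcels are separated by a
  1-voxel CSF furrow: without it, the 4 mm kernel couples the boundary voxels
  of adjacent parcels identically in every data fold and imposes a spurious,
  perfectly reproducible parcel hierarchy on the stability analysis.
* **Deep nuclei.** A 3 x 3 x 3 block inside the WM slab carries a GM parcel's
  latent but is labeled WM by every subject's segmentation; the atlas marks it
  with the five deep-nuclei codes. This exercises the relabeling path of
  `build_group_masks()` end to end.
* **Nuisance structure.** On top of latent-plus-noise, each voxel receives a
  baseline offset, a random linear trend, a 0.005 Hz scanner drift, a global
  physiological signal shared with CSF voxels, a motion-coupled component, and
  large artifacts at motion-spike volumes — one term per cleaning stage, so a
  cleaning failure is attributable. `artifacts = FALSE` disables all of them,
  giving the bare zero-noise identity (voxel series equals its latent) used in
  tests.
* **Behavior.** Ages are uniform on 19-30, sex is balanced, and scores follow
  the published means and SDs (VAS 13.66 +/- 16.35 before, 20.48 +/- 18.09 at
  24 h; anxiety 27.73 +/- 11.00 and 29.82 +/- 10.48); only means and SDs are
  reproduced — the published skewness values imply mild asymmetry that a
  Gaussian draw ignores. The pain group's VAS change is a linear combination
  of the chosen edge's latent Fisher z, age, sex, and noise, with the noise
  orthogonalized in-sample so the planted partial correlation (default -0.31)
  is exact on the latent z. The SD of the VAS *change* (12 by default) is not
  published and was set to a plausible test-retest value. Controls receive no
  scores, matching the study design.

What the phantom does **not** emulate: hemodynamic response shapes, scanner
noise spectra and spatial autocorrelation, susceptibility artifacts, true
registration/segmentation error fields, and between-subject topographic
variability of networks. Passing tests therefore demonstrate that the
*pipeline arithmetic* is correct and that the method recovers structure under
controlled conditions — not that the method is robust to everything real data
can do.

## Cleaning

`clean_series()` follows the stated preprocessing order: drop the first 10
volumes, per-voxel linear detrend, ideal band-pass (0.01-0.1 Hz, implemented
as an FFT-domain mask, TR-aware, edges inclusive), then nuisance regression
with the 24-parameter motion set (6 parameters, their one-lag copies, both
squared; lag zero-padded), the mean CSF signal, and one indicator column per
volume whose framewise displacement exceeds 1 mm. Spike volumes are
*regressed*, not deleted — an indicator column forces the residual at that
volume to zero while keeping the time axis intact. WM and whole-brain mean
signals are deliberately not regressed.

Two numerical choices matter:

* The motion and CSF regressors pass through the same detrend + band-pass
  transform as the data, and the band-passed raw trend is included as an extra
  nuisance column. With those two details the sequential pipeline becomes an
  exact orthogonal projection: residuals are band-limited, mean-free,
  trend-free, orthogonal to every regressor, and cleaning its own output (with
  `drop_first = 0`) is a numerical no-op for spike-free runs. Without them,
  filtering reintroduces a trend component and regression reintroduces
  out-of-band energy, and "cleaned" data changes on every pass.
* `combined = TRUE` switches to the joint alternative — one regression on
  intercept, trend, a Fourier basis spanning all stopped frequencies, raw
  nuisance signals, and spikes — which avoids any step-order question
  entirely. The default remains the sequential order because it is the
  procedure as stated.

Framewise displacement uses the common backward-difference convention,
`FD(t) = sum |d trans| + 50 mm * sum |d rot|`, with FD(1) = 0. Subject-level
exclusion drops a subject iff any |translation| strictly exceeds 2.0 mm or any
|rotation| strictly exceeds 2.0 degrees; the rotation comparison is done in
radians against the converted limit so a value exactly at the boundary is
kept. Smoothing (`smooth_within_mask()`, FWHM 4 mm) is a sparse row-stochastic
operator whose Gaussian kernel is renormalized over in-mask voxels only —
constants are preserved and no signal crosses the GM/WM boundary. Collinear
nuisance columns are dropped with a warning after unit-norm scaling (so rank
detection is not driven by the regressors' disparate units). A trilinear
resampler is provided for real data; phantoms are generated at target
resolution.

## Masks

`build_group_masks()` thresholds the across-subject tissue fractions: WM at
>= 60%, GM at >= 20% (inclusive comparisons; the source procedure does not
state the direction, and inclusive is the convention), with WM taking
precedence and atlas-marked deep nuclei moved from WM to GM unconditionally.
Per-subject probability maps reduce to maximum-probability labels with ties
broken GM > WM > CSF (the conservative direction). The atlas correction also
overrides the per-subject labels used downstream for pairwise masking: without
that, relabeled nuclei voxels would have zero GM coverage in the group average
(every segmentation calls them WM) and would be silently excluded from
clustering. Voxel ordering is ascending linear index, x-fastest, everywhere.

## Voxel-by-node correlation matrices

`checkerboard_nodes()` selects, in 0-based coordinates with slice phase
`p = z mod 2`, the in-mask voxels with `x = p (mod 2)` and `y = p (mod 2)`:
every second voxel along rows and columns, with the phase alternating between
slices so a mask confined to a single column is never lost. This reading
yields quarter density per slice. The published node counts (4,895 WM, 4,759
GM of 19,576 / 42,795 mask voxels) are not exactly mask/4 — the exact grid
phase of the original is unrecoverable and the count is geometry-dependent, so
the property tested is the rule, not those counts.

`subject_corr()` computes Pearson r between every mask voxel and every node;
zero-variance series yield missing values, never zeros. `group_average()`
averages raw correlations entry-wise over only those subjects in whom *both*
voxels carry the target tissue label in the subject's own segmentation,
recording per-entry coverage (`fisher_z = TRUE` averages atanh-transformed
values instead). Rows with at least 90% non-missing entries are clustered,
with remaining gaps imputed by the row mean; the missingness policy is ours —
the source is silent.

## Parcellation and stability

`kmeans_rows()` is Lloyd's algorithm under correlation distance
(1 - Pearson r between rows): rows are centered and unit-normalized, centroids
are renormalized member means, empty clusters are re-seeded at the row
farthest from its assigned centroid, and the best of 10 random restarts by
total within-cluster dispersion is kept, deterministically given a seed.
`stats::kmeans` is Euclidean-only, which is why this is implemented here.

`stability_profile()` splits node columns into 4 random near-equal folds,
clusters the rows of each fold independently at each K (2-22 at full scale),
forms each solution's co-assignment adjacency (A(u,v) = 1 iff rows u, v share
a cluster) over a fixed seeded subsample of at most 2,000 rows, and compares
all C(4,2) = 6 fold pairs with the Dice coefficient, computed via the
contingency table so it is label-permutation invariant. "The average over all
four adjacent matrices" is read as the mean over the 6 pairwise comparisons —
the only reading that yields a single number per K. K values with mean Dice
strictly above 0.85 are stable; when several K pass, all are reported and the
choice is the analyst's (the original study reports one K per tissue without
stating the tie-break). The final parcellation is full-matrix K-means at the
chosen K, not a fold consensus.

### A structural caveat of fold-based stability

Folds resample *nodes only*; all folds see the same subjects. Any
cohort-level realization — in the phantom, the empirical couplings among
planted networks; in real data, the sample's network similarity structure —
is therefore shared by every fold and acts as a common tie-breaker at K below
the true number. With 4 exchangeable GM parcels at K = 2 there are only three
ways to merge, and the shared realization picks the same one in every fold,
so the co-assignment matrices agree exactly and Dice saturates at 1.0 — as
stable as the true solution. The effect is structural: both the shared
tie-break signal and the fold-level noise derive from the same subject
sample, so their ratio (roughly the square root of the nodes per parcel) does
not move with noise level, and we verified empirically that raising voxel
noise fivefold leaves it unchanged. It fades when the merge option space is
large: the 5-parcel WM tissue at K-2 (15 coarser groupings) and both tissues
at K+2 (splits are fold-arbitrary) show clear stability deficits. The
validation suite asserts the strict true-K dominance for all four comparisons;
the GM K-2 case fails by exactly this tie and is reported as a known property
of the method rather than patched over. Practically: a high Dice at small K
means "reproducible under node resampling", not "correct K" — the Dice > 0.85
rule should be read as a *filter* for admissible K, with the final choice
informed by granularity requirements.

## Network statistics

Network time courses are unweighted means over member voxels. FC is Pearson r
between network time courses, Fisher-z transformed (`z = atanh r`), split into
within-GM, within-WM and GM-WM families. Distributions are screened by type-2
(SPSS-convention) sample skewness and excess kurtosis per edge and group, with
the conventional (-2, 2) acceptance band. One-sample t-tests against zero,
Bonferroni-corrected within each matrix family, define each group's
significant edges; the union over the two groups is the tested set for the
group comparison (the least exclusionary reading of "for these significant
FC"). Group differences use the pooled-variance two-sample t-test
(`var_equal = FALSE` gives Welch), Bonferroni-corrected with family size equal
to the number of tested edges in that family.

The behavioral analysis residualizes the edge's z values and the behavioral
score on intercept, age and sex, correlates the residuals, and tests with
`t = r * sqrt((n - 2 - k)/(1 - r^2))` on `n - 4` degrees of freedom (k = 2
covariates). The default behavioral variable is the 24 h minus baseline score
difference; the function takes any per-subject vector, so correlating the raw
24 h score is a one-line change (both readings appear in the source study).

`find_loops()` enumerates simple cycles of length 3 to `max_len` (default 4 —
covering the reported 3-network loops with headroom) in the graph of
significantly different edges across all three families, keeps cycles with at
least one GM and one WM node, canonicalizes over rotation and reflection so
each loop is reported once, and retains each edge's direction of group
difference. Enumeration is a bounded DFS validated against exhaustive
brute-force enumeration in the tests.

## Validation studies and problem sizes

The shipped studies use the desk-scale phantom: the recovery study
(`planted_recovery_study()`) runs the full pipeline on 10 independent cohorts
(24 x 24 x 12 grid, 4 + 5 networks, 200 volumes, 12 + 12 subjects) and
summarizes adjusted Rand index at the true K and stability-Dice margins at
K +/- 2; the power study (`edge_power_study()`) simulates 100 cohorts of
20 + 20 subjects at the network-latent level with a +0.3 coupling increase on
one gray-white edge and reports the fraction flagged by the Bonferroni-
corrected two-sample test. These sizes keep the complete validation suite in
the minutes range on a single core while leaving all statistical machinery
identical to a full-scale run.

## Known limitations

* The phantom's noise is white in space and time; spatially correlated noise
  would reduce the effective benefit of smoothing and lower recovery.
* The ideal (brick-wall) frequency filter matches the testable contract but
  has infinite impulse response; tapered filters would behave differently at
  the band edges.
* Stability-based selection of K inherits the node-resampling caveat above.
* Only undirected FC is analyzed; directionality is out of scope, as in the
  source methodology.
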