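---
title: "Regional MS lesion quantification: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional MS lesion quantification: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lesionquant)
```

# The problem

Relapsing-remitting multiple sclerosis produces focal white-matter lesions
that are hyperintense on T2-weighted MRI; a subset of them is hypointense on
T1-weighted images ("black holes"), indicating more severe tissue injury.
Comparing a pediatric-onset cohort with an adult cohort requires a pipeline
that (i) brings each subject's PD-, T2- and T1-weighted volumes — acquired
under two different protocols — onto one analysis grid and intensity scale,
(ii) segments T2 lesions and T1 hypointensities reproducibly across those
protocols, (iii) converts masks into per-region counts and volumes, and
(iv) applies a pre-specified battery of group tests. `lesionquant`
implements that pipeline over a synthetic multi-contrast brain phantom, so
every stage is testable against known ground truth without any patient
data.

# The phantom

`build_region_atlas()` constructs a brain from nested ellipsoids: a WM
interior, a cortical GM shell, a thin peripheral (subarachnoid) CSF shell,
paired elongated ventricles, and an infratentorial compartment (below an
axial tentorium plane) split into a brainstem column — stacked midbrain,
pons and medulla, taken to include the cerebellar peduncles — and the
surrounding cerebellum. Base labels partition the brain exactly, so the
inventory identities (whole brain = supratentorial + infratentorial,
brainstem = midbrain + pons + medulla) hold at machine precision. The
periventricular region is a morphological dilation of the ventricles
(default 3 mm), a pragmatic stand-in for a construction that is not
published in detail.

`generate_subject()` implants spherical lesions (jittered radii, sub-voxel
centres) into the WM of requested regions, enforcing the one-voxel
separation that the counting rule later relies on. Lesions are PD/T2
hyperintense; each carries a graded T1 profile ramping from
`t1_lesion_core_multiplier` (default 0.7) at the centre through 0.85 at the
edge of the hypointense core to ~1 at the lesion boundary, with the core
radius set so a fraction `t1_core_fraction` of the lesion's voxels falls
strictly below the protocol threshold. Two acquisition protocols are
emulated: pediatric (2 mm contiguous axial slices) and adult (3 mm), both
0.98 mm in-plane, with WM:GM T2 contrast ratios of 1.36 and 1.38 and a
slight T1 lesion-contrast difference constructed so that a relative
threshold of 0.85 under the pediatric protocol selects the same tissue as
0.83 under the adult protocol (`t1_profile_scale = 0.83/0.85`).

Three realism features deserve explanation because the pipeline depends on
them:

* **Within-tissue texture** (`texture_sigma`, default 3 intensity units for
  PD/T2 and 1 for T1, at an 8 mm spatial scale). Real tissue intensities
  vary smoothly within a class; without this the intensity histogram
  degenerates into zero-width spikes and percentile landmarks become
  meaningless. The milder T1 texture reflects the flatter appearance of
  spoiled-gradient T1 acquisitions and keeps the NAWM-relative threshold
  well posed against a single pooled reference.
* **Peripheral CSF shell.** With only ventricular CSF (~1% of the mask),
  the 2nd/98th percentile landmarks fall on cluster boundaries and shift
  with lesion load; with a realistic ~9% CSF fraction they sit stably
  inside the CSF cluster in every contrast.
* **Sub-voxel lesion centres.** Spheres centred exactly on grid points bias
  slice-direction volumes (a 3 mm-slice grid catches one slice of a small
  core instead of its fair share), which systematically distorted the
  cross-protocol calibration by +0.008 before jittering.

The noise model is additive Gaussian (sigma 1.5 on tissue means of 85–250,
SNR ~65–90, typical of 1.5 T), not Rician; at this SNR the difference is
negligible and the Gaussian is analytically convenient in tests. The bias
field is a sum of 2–3 broad Gaussian bumps in the log domain, zero-centred
over the brain and scaled to a configurable peak log-magnitude (cohort
default 0.2), then exponentiated — smooth and strictly positive by
construction.

What the phantom does **not** emulate: cortical folding, partial-volume
mixing beyond grid resampling, Rician noise floors, scanner-specific
artefacts, anatomical variability between subjects (one template geometry
serves all), and any real spatial distribution of MS lesions. Passing tests
therefore demonstrate the correctness of the algorithms under controlled
contrast, not clinical-grade accuracy on patient data.

# Preprocessing

Processing order is resample → bias-correct → register → normalize.

**Resampling** is trilinear onto the common adult grid (0.98 × 0.98 × 3 mm,
voxel volume 2.8812 mm^3); masks use nearest-neighbour or are re-thresholded
at 0.5.

**Bias correction** (`estimate_bias_field()`) is a log-domain surrogate for
iterative non-uniformity correction: masked Gaussian smoothing (sigma 20 mm)
of log intensities gives a first field, voxels whose residual is atypical
(beyond 1.5 robust SDs — mostly GM, CSF and lesions) are trimmed, and the
field is re-estimated over the remaining, mostly-WM voxels. The 20 mm
default separates the 8 mm texture scale from the 25–45 mm bias scale: under
a null field the estimate stays within 2% of 1.0 despite tissue structure,
while corrected WM coefficient of variation drops strictly for every tested
bias amplitude up to 0.5. The returned field has mask-mean exactly 1 and
`correct_bias()` preserves the mask-mean intensity exactly.

**Rigid registration** (`rigid_register()`) minimises masked mean-squared
difference over 6 parameters with Nelder–Mead, two resolution levels
(smoothed at 3 mm, then unsmoothed) and a coarse seeding grid over rotations
(±4°) and translations (±3 mm). Two numerical hazards shaped this design:
interpolation acts as a low-pass filter, so resampling a noisy image
slightly off-lattice *reduces* MSD and creates a false minimum at the
identity (removed by the smoothed coarse level), and rotations about the
axial axis of a near-rotationally-symmetric head have a shallow basin
(handled by the seeding grid). Recovery accuracy on phantoms is well inside
0.5 mm / 0.5°. In the pipeline the PD and T1 volumes are registered to T2 on
head silhouettes, because MSD across different contrasts is not meaningful.

**Intensity normalization** (`normalize_intensity()`) is a two-piece linear
map sending the 2nd percentile, median and 98th percentile over the brain
mask to fixed targets (0, 100, 200). Landmarks are type-1 (order-statistic)
quantiles: a monotone map then commutes with them exactly, which makes the
normalization idempotent to machine precision — interpolated quantiles
average across the map's own breakpoint and break that property. Values
beyond the outer landmarks extrapolate with the adjacent slope, so the map
is monotone on the whole line.

# Segmentation

**T2, supratentorial.** A four-class (WM/GM/CSF/lesion) multivariate
Gaussian model over (PD, T2, T1) is fitted by maximum likelihood on labeled
training voxels (`fit_tissue_model()`; priors are the class fractions,
near-singular covariances get a ridge). A voxel is lesion when the posterior
`pi_L N(x; mu_L, Sigma_L) / sum_c pi_c N(x; mu_c, Sigma_c)` exceeds 0.5 (the
MAP rule for a two-way decision; configurable). No spatial regularisation is
applied. In the pipeline the model trains on one dedicated phantom per
protocol group using its ground-truth labels — interior voxels only, since
resampled boundary voxels are partial-volume mixtures that smear the class
Gaussians. Candidate voxels are restricted to one-voxel-eroded WM: the
partial-volume layer at WM/CSF interfaces mimics lesion intensities in all
three contrasts simultaneously and would otherwise dominate the false
positives.

**T2, infratentorial.** The classifier is not reliable below the tentorium
(in the original workflow this region was segmented manually), so a
relative-intensity stand-in is used: WM voxels in the compartment whose T2
intensity exceeds 1.3× the infratentorial WM mean, intended to be reviewed
through `apply_manual_edits()` (an add/remove/keep edit-volume importer that
replaces interactive editing).

**T1 hypointensities.** A voxel is a black-hole voxel when it lies inside
the final T2 mask (the "confirmed bright on T2" rule, implemented as
containment) and its T1 intensity falls below `fraction` × the mean T1 of
surrounding normal-appearing white matter — WM within 5 mm of the lesion
surface, lesions excluded, pooled over all lesions, with a global-NAWM
fallback (and a warning) if the ring is empty. Thresholding runs on the
bias-corrected, *unnormalized* T1: a ratio threshold is invariant to global
scale but not to a two-piece affine map. The fractions are 0.85 (pediatric
protocol) and 0.83 (adult).

**Cross-protocol calibration.** `calibrate_t1_threshold()` reproduces the
procedure that justified those fractions: given subjects scanned under both
protocols, it finds the protocol-B fraction whose T1 lesion volumes match
protocol A at the reference fraction, minimising the absolute median of
per-subject volume differences over a 0.005-step grid and refining by
bisection (the signed median difference is monotone in the fraction). The
median was chosen over the mean for robustness to a single outlier pair;
the original criterion is not published. On ten synthetic dual-protocol
subjects the constructed 0.85 → 0.83 pair is recovered within ±0.005.

# Quantification

Connected components are 26-connected by default — the most inclusive
reading of "clusters are distinct lesions only if separated by at least one
voxel" — configurable to 6 or 18, and verified exactly against an
independent flood-fill implementation. T2 lesions below 3 voxels are
discarded from both counts and volumes (the published minimum-size rule; the
rule is stated for T2 only, so T1 components default to a 1-voxel minimum).
Note the published gloss "3 voxels (9 mm^3)" implies 3 mm^3 voxels while the
resampled grid has 2.8812 mm^3 voxels; the voxel-count rule is taken as
authoritative.

Volumes are voxel-membership sums (cm^3). Counts assign each component once,
to the region holding the majority of its voxels, ties going
supratentorial — so a lesion straddling the tentorium is counted in one
compartment while its volume splits by membership, and compartment counts
add exactly. Frequency maps are voxelwise subject fractions over a
compartment on the template grid (phantoms supply an identity template
transform; `to_template()` applies any affine with trilinear/nearest
resampling), and the average anatomy is the voxelwise mean.

# Statistics

The battery mirrors the published comparison table: incidence rows by
Fisher's exact test; lesion volumes by Student's pooled-variance t on
log(volume + 1) (the log-shift constant is 1 cm^3; the published analysis
names the transform but not the constant); infratentorial volumes and the
periventricular/non-periventricular split by Mann–Whitney; per-subject
T1:T2 volume ratios and lesion counts by t. Significance is raw p < 0.05
with no multiplicity correction, as the comparisons are treated as
pre-specified.

`fisher_exact_2x2()` uses the point-probability two-sided convention (sum of
same-margin tables no more probable than the observed one, with a 1e-7
relative tolerance absorbing floating-point ties) and matches a log-factorial
enumeration oracle to ~1e-13 over all tables with margins ≤ 30.
`mann_whitney_u()` enumerates all assignments exactly for n1+n2 ≤ 12 (valid
under ties), uses the exact null distribution of U for tie-free samples up
to 50 per group — the `wilcox.test` convention, whose size at n = 29+29 is
0.0483 against 0.0468 for the continuity-corrected normal approximation —
and otherwise the tie-corrected normal approximation with continuity
correction. Degenerate inputs (all values identical; two constant equal
samples) return p = 1 by convention.

`simulate_inventories()` draws per-subject regional inventories directly
from cohort-level distributions (volume means/SDs and incidence rates of the
two published cohorts), preserving inventory additivity. It exists for
statistical checks of the reporting battery where image simulation adds
nothing. One caveat it exposes: volumes are truncated at zero, so the
infratentorial volume difference (4.31 vs 2.08 cm^3, SD 2.7/2.4) yields a
detection rate near 0.80 at n = 29/29 rather than the ~0.91 that untruncated
normals would give.

# Problem sizes and reproducibility

The bundled analysis (`analysis/01_simulate.R` … `05_report.R`) runs 10
subjects per cohort on a 94 × 94 × 120 mm field of view; the test suite uses
10 phantom seeds for recovery checks, 10 dual-protocol pairs for the
threshold calibration, 2 × 10^4 null replicates for the type-I checks, and
2-subject cohorts for the end-to-end determinism check. All randomness
flows from explicit seeds (cohorts fan a master seed out to per-subject
seeds), and two pipeline runs under one seed produce byte-identical CSV
reports. `scripts/acceptance.R` recomputes the headline quantities from
scratch under a caller-supplied seed.

# Known limitations

The Bayesian segmentation carries no spatial prior or probabilistic atlas
(whether the original method used one is not recoverable); the bias
surrogate is not a full histogram-sharpening deconvolution and will absorb
intensity structure smoother than ~2× its kernel scale; the infratentorial
stand-in is a threshold rule, not a manual rater; the phantom's protocol
difference in T1 contrast is constructed rather than physical, so the
calibration result demonstrates procedure correctness, not scanner physics;
and at the phantom's high lesion contrast the supratentorial Dice is near 1,
so the suite bounds regressions rather than measuring clinically realistic
segmentation difficulty.
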