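# lesionquant

Regional quantification of multiple-sclerosis lesions on multi-contrast
brain MRI, built as a fully testable analysis pipeline: a synthetic
phantom generator stands in for patient scans, so every stage — from bias
correction to the final group statistics — can be verified against known
ground truth.

The scientific setting is a comparison of pediatric-onset and adult
relapsing-remitting MS (RRMS) cohorts: T2-hyperintense lesion volume (T2LV)
and count, T1-hypointense ("black hole") volume (T1LV), their regional
distribution (supratentorial vs infratentorial; brainstem, pons, midbrain,
medulla, cerebellum; periventricular vs not), lesion frequency maps in a
common template space, and incidence/volume comparisons between groups.
The two cohorts were scanned with different protocols (2 mm vs 3 mm axial
slices, slightly different T1 contrast), which is why the pipeline includes
grid harmonisation, per-image intensity standardisation, and a
cross-protocol calibration of the T1 threshold.

## What the package implements

- **Phantom cohorts** (`build_region_atlas`, `generate_subject`,
  `generate_cohort`): multi-contrast (PD/T2/T1) brain phantoms with a region
  atlas, implanted spherical lesions with graded T1-hypointense cores,
  multiplicative bias fields, tissue texture and noise, under a pediatric
  (2 mm) or adult (3 mm) acquisition protocol; full ground truth travels
  with every subject.
- **Preprocessing** (`resample_to_grid`, `estimate_bias_field`,
  `rigid_register`, `normalize_intensity`): trilinear resampling onto the
  common 0.98 × 0.98 × 3 mm grid, a robust log-domain bias-field surrogate,
  6-parameter MSD registration of PD/T1 to T2, and the two-piece linear
  intensity map pinning the 2nd/50th/98th percentile landmarks.
- **Segmentation** (`fit_tissue_model`, `segment_t2_lesions`,
  `segment_infratentorial_t2`, `segment_t1_hypointense`,
  `calibrate_t1_threshold`): Bayesian multispectral T2 lesion
  classification, with a voxel counted as lesion when
  `P(lesion | PD,T2,T1) = pi_L N(x;mu_L,Sigma_L) / sum_c pi_c N(x;mu_c,Sigma_c) > 0.5`;
  a relative-threshold infratentorial stand-in; T1 black-hole thresholding
  at 85% (pediatric) / 83% (adult) of the surrounding normal-appearing
  white matter mean; and the paired-protocol procedure that calibrates one
  fraction against the other.
- **Quantification** (`label_lesions`, `filter_min_size`,
  `regional_inventory`, `lesion_frequency_map`, `average_anatomy`):
  26-connected component counting with the one-voxel separation rule and
  the 3-voxel minimum lesion size, regional volumes in cm^3, voxelwise
  lesion frequency maps and average anatomies.
- **Group statistics** (`fisher_exact_2x2`, `two_sample_t`,
  `mann_whitney_u`, `log_shift_transform`, `incidence_table`,
  `group_report`): the published table's battery — Fisher's exact tests on
  incidence, Student's t on log(volume+1), Mann–Whitney for non-normalized
  variables — at a pre-specified alpha of 0.05.

## Worked example

The `analysis/` directory is a numbered workflow (simulate → preprocess →
segment → quantify → report) writing its tables under `results/`. A run at
the demo size (10 subjects per cohort, master seed 42):

```sh
Rscript analysis/01_simulate.R
# pediatric n=10  true T2LV 12.67 (3.16) cm^3  infratentorial 7/10
# adult     n=10  true T2LV 9.28 (2.20) cm^3  infratentorial 6/10

Rscript analysis/02_preprocess.R
# pediatric ped001: WM CV 0.1385 -> 0.1027; T2 landmarks 94.0 / 136.1 / 247.4
# adult     adu001: WM CV 0.1059 -> 0.0738; T2 landmarks 93.6 / 136.8 / 259.9

Rscript analysis/03_segment.R
# median T2 Dice: pediatric 0.954, adult 0.989
# calibrated adult T1 fraction: 0.8293 (|median volume diff| 0.0005 cm^3)

Rscript analysis/04_quantify.R
# pediatric measured T2LV 11.63 (3.53) cm^3
# adult     measured T2LV 9.08 (2.21) cm^3

Rscript analysis/05_report.R   # group_report.csv + published_incidence_tests.csv
```

Reading these numbers: the generator draws whole-brain T2LV around the
cohort means it is configured with (12.76 and 10.03 cm^3); preprocessing
reduces the white-matter coefficient of variation by roughly a third under
a 0.2-amplitude bias field; segmentation recovers the implanted lesions
with Dice ≳ 0.95 through the full resampling chain (pediatric subjects pay
a small partial-volume penalty for the 2 → 3 mm resampling, visible again
as a slightly low measured T2LV); and the calibration recovers, to within
half its grid step, the 0.83 adult threshold constructed to be equivalent
to the 0.85 pediatric one. Stage 5 also recomputes the published cohorts'
incidence tests from the printed patient counts, e.g. infratentorial T2
lesions in 22/29 children vs 13/29 adults, Fisher p = 0.031.

The same machinery is available programmatically:

```r
library(lesionquant)
res <- run_pipeline(pipeline_config(n_per_group = 10, seed = 42,
                                    out_dir = "results/pipeline"))
res$report   # incidence, volume, ratio and count comparisons with p-values
```

## Layout

```
R/                  package code (phantom, preprocess, segment, quantify, stats, pipeline)
analysis/           numbered workflow scripts (the narrative analysis)
results/            tables written by the workflow and the acceptance script
scripts/acceptance.R
tests/testthat/     unit, property and acceptance tests
vignettes/          methods vignette: models, parameters, design decisions
```
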