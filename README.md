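# nigraquant

Quantitative iron–neuromelanin MRI analysis of the substantia nigra (SN) for
Parkinson's disease (PD) research.

Dopaminergic neurons of the SN carry neuromelanin (NM), a pigment that is
hyperintense on NM-sensitive T1 TSE MRI, and their degeneration in PD is
accompanied by iron accumulation that raises magnetic susceptibility on
quantitative susceptibility mapping (QSM). `nigraquant` implements the
quantitative side of a multimodal SN protocol for radiology and movement-
disorders groups: given NM-sensitive, QSM and SWI-magnitude midbrain volumes
with manually drawn SN and background masks on three representative axial
slices, it extracts the standard SN-mask parameter set, combines the best
discriminators into a composite marker, and reproduces the full statistical
evaluation layer.

## The parameters and the composite marker

From each subject the package extracts, per modality on its own voxel grid:

| parameter | definition |
|---|---|
| `nm_signal` | mean NM-sensitive signal in the SN mask (a.u.) |
| `nm_contrast_range` | P90/P10 of in-mask NM signal (type-7 percentiles) |
| `nm_size` | SN mask area, mm² (3 slices, both hemispheres pooled) |
| `nm_size_high` | area above the high-signal cutoff mean(bg) + k·sd(bg), k = 3 |
| `qsm_chi_mean` | mean susceptibility χ in the SN mask (ppb) |
| `qsm_size`, `qsm_size_low` | QSM mask area, and area with χ < 70 ppb |
| `smwi_signal`, `smwi_size`, `smwi_size_low` | SMWI mean, mask area, and area below the background 10th percentile |

SMWI (susceptibility map-weighted imaging) is synthesised from QSM and the
SWI magnitude as `magnitude × w(χ)^4`, with `w` a linear ramp from 1 at
70 ppb to 0 at 170 ppb. All three low/high-signal thresholded areas shrink or
grow with nigral degeneration, and the composite marker multiplies the three
best-performing parameters:

```
composite = (NM_P90 / NM_P10) × Size_NM,high × Size_QSM,low
```

Every factor is lower in PD (narrower NM dynamic range, loss of high-NM
voxels, loss of the low-susceptibility nigrosome territory), so low composite
values indicate disease; classification uses a Youden-optimal cutoff with
ties assigned to the patient side.

The statistical layer provides pooled-SD standardized mean differences
(`hedges_g`), t/Kruskal–Wallis group comparisons, ROC analysis with DeLong
confidence intervals and operating points, Bonferroni-corrected Spearman
correlation tables against clinical scores (UPDRS-I/II/III, MMSE, age), and
rater agreement (Fleiss'/Cohen's kappa, ICC(2,1)).

Because no public imaging cohort accompanies this protocol, the package
includes a synthetic midbrain phantom (`phantom_config`, `generate_cohort`,
`render_subject_volumes`) calibrated to published case–control summary
statistics (111 controls / 80 patients): per-group feature and clinical
marginals are matched exactly, and a latent-severity Gaussian copula
reproduces the published imaging–clinical rank-correlation structure. The
phantom can emit feature tables or full NIfTI volumes with masks whose
zero-noise extraction reproduces the generator's ground truth exactly.

## Worked example

```r
library(nigraquant)

cfg    <- calibrate_copula(phantom_config(seed = 42))  # study-sized cohort
report <- run_pipeline(cfg)

subset(report$group_summary,
       feature %in% c("nm_contrast_range", "nm_size_high",
                      "qsm_chi_mean", "qsm_size_low"),
       c(feature, mean_control, sd_control, mean_patient, sd_patient,
         hedges_g, auc))
```

```
           feature mean_control sd_control mean_patient sd_patient hedges_g   auc
 nm_contrast_range         1.18      0.115         1.12      0.305     0.28 0.806
      nm_size_high        87.35     61.790        25.33     30.405     1.21 0.809
      qsm_chi_mean        85.08     26.438       126.88     34.206     1.40 0.846
      qsm_size_low        96.43     56.895        36.78     34.796     1.22 0.809
```

One simulated cohort of 191 subjects: patients show the expected higher SN
susceptibility and smaller thresholded mask areas, with large effect sizes
(pooled-SD g ≈ 1.2–1.4) and single-parameter AUCs near 0.8.

```r
report$roc$composite$auc
#> [1] 0.839
report$roc$composite$operating_point
#> cutoff ...: sensitivity 86%, specificity 76%, accuracy 80%
report$agreement$fleiss_all
#> fleiss_kappa = 0.721 (191 subjects, 4 raters)
```

The composite marker outperforms each of its factors, and four simulated
radiologist readers (error rates matching published reader performance on
SMWI) agree at the "substantial" kappa level. `run_pipeline(cfg, out_dir =
"out")` additionally writes the feature/subject tables, group-difference,
relative-difference and correlation reports, ROC curve data and a JSON
summary.

A thin command-line wrapper covers the same stages:

```sh
Rscript inst/cli/nigraquant.R run --config cfg.yaml --out out/
Rscript inst/cli/nigraquant.R simulate --config cfg.yaml --out sim/ --image-level
Rscript inst/cli/nigraquant.R extract --nm nm.nii.gz --qsm qsm.nii.gz ...
```

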