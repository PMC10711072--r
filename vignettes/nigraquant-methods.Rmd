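---
title: "Methods: quantitative SN iron-neuromelanin analysis and the midbrain phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative SN iron-neuromelanin analysis and the midbrain phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nigraquant)
```

## Scope and model

`nigraquant` quantifies Parkinsonian nigral degeneration from three
co-acquired midbrain contrasts: neuromelanin-sensitive T1 TSE (voxel
0.5 × 0.5 × 3 mm), QSM (0.5 × 0.5 × 1 mm, susceptibility in ppb) and a
SWI-magnitude companion from which SMWI is synthesised. Analysis is
deliberately mask-based: the bilateral SN is segmented on three
representative axial slices per modality (on iron-sensitive images, just
below the inferior pole of the red nucleus; on NM-sensitive images, from the
last slice through the interpeduncular fossa), together with a background
reference region. All statistics are computed per modality on its own voxel
grid; no inter-modality resampling is attempted, matching the separate
acquisition protocols.

Two biological signals drive the parameter set. Neuromelanin loss follows a
posterolateral-to-anteromedial gradient, narrowing the in-mask signal
dynamic range (the P90/P10 *contrast range*) and shrinking the area that
survives high-signal thresholding. Iron accumulation raises mean
susceptibility and erodes the low-susceptibility (χ < 70 ppb) territory
that contains nigrosome-1. The composite marker is the plain product

$$\mathrm{composite} = \frac{NM_{90}}{NM_{10}} \cdot \mathrm{Size}_{NM,high}
  \cdot \mathrm{Size}_{QSM,low},$$

taken raw (no rescaling of factors): the product of three quantities that
all decrease with disease is itself strongly decreasing, and a monotone
transform of the factors would change the value but not the ROC, which is
rank-based. Low values indicate disease; ties at a classification cutoff go
to the patient side (favouring sensitivity, and making classification
deterministic).

## Tunable parameters

* `qsm_chi_cutoff` (ppb, default 70): the low-susceptibility threshold. The
  value is part of the protocol being implemented, not a free parameter.
* `nm_k` (unitless, default 3): background-SD multiplier for the NM
  high-signal cutoff, mean(bg) + k·sd(bg) — the standard background-
  statistics rule in NM-MRI. The exact "optimized" rule used with the
  original protocol is not public; an `auc_sweep` mode is provided that
  scans a cutoff grid and keeps the one maximising group-separation AUC of
  the thresholded area on a labelled calibration cohort.
* `smwi_low_quantile` (default 0.1): the SMWI low-signal cutoff is this
  quantile of the background SMWI signal; only "thresholding for low signal
  voxels" is specified by the protocol, so a background quantile was chosen
  as the least parametric rule.
* SMWI weighting (`smwi_chi_low` = 70 ppb, `smwi_chi_high` = 170 ppb,
  `smwi_power` = 4): the published weighting's constants are not printed;
  the ramp is anchored at the protocol's own 70 ppb cutoff, the ceiling and
  exponent follow common SMWI practice and are configurable.
* Percentiles use linear interpolation between closest order statistics
  (R type 7) throughout, so all percentile-based quantities are bit-stable.

## Statistical layer: choices where the protocol is silent

* **Effect size.** The pooled-SD standardized mean difference is reported
  *without* the small-sample bias correction: recomputing from the reference
  cohort's printed (mean, sd, n) reproduces its tabulated values only in the
  uncorrected form (e.g. 1.151 rather than 1.146 for mean susceptibility).
  `corrected = TRUE` gives the bias-corrected variant.
* **ROC.** AUC is Mann-Whitney concordance with ties counted ½, computed
  from ranks; the CI is DeLong's placement-variance interval (cross-checked
  against `pROC` in the test suite). Operating points maximise Youden's J,
  with ties broken toward higher specificity.
* **Group comparison.** `auto` mode applies a Shapiro-Wilk screen
  (α = 0.05, both groups) and uses Welch's t-test when neither group
  rejects normality, Kruskal-Wallis otherwise — the protocol names both
  tests without a per-variable assignment, so p-values are not treated as
  exact reproduction targets.
* **Correlations.** Spearman with average ranks; the Bonferroni family is
  the 4 × 5 imaging-by-clinical grid (20 tests), matching the
  multiple-comparison context in which the reference correlations were
  reported.
* **Agreement.** ICC is the two-way random, absolute-agreement, single
  measure form ICC(2,1) — the natural choice for "can a different rater
  reproduce the number", and sensitive to rater bias. Kappa statistics use
  the standard Fleiss and Cohen constructions.

## The synthetic midbrain phantom

No deposited cohort exists, so every downstream stage is exercised on a
phantom whose defaults *are* the published study conditions: 111 controls /
80 patients, per-group feature marginals and clinical-score marginals taken
from the reference tables, and a target matrix of full-cohort Spearman
correlations between the four highly discriminant parameters and age, MMSE
and UPDRS-I/II/III.

**Marginals.** Most features are Gaussian within group. The
size-after-thresholding features are modelled as zero-censored normals
(their printed SD approaches or exceeds the mean, and a vanished mask is a
real event), and the contrast range as 1 + a zero-censored normal, since a
P90/P10 ratio cannot fall below 1. In both cases the latent parameters are
solved from closed-form censored-normal moments so the requested mean and SD
hold exactly. A structural clamp enforces thresholded ≤ unthresholded mask
size; for the SMWI low-signal area, whose marginal places real mass above
its parent size, the latent parameters are refit on a large fixed draw so
the *post-clamp* moments match the targets.

**Dependence.** Each subject carries a latent severity factor. Every
feature's and clinical score's Gaussian copula score loads on severity, and
each severity-linked clinical score additionally owns a small orthogonal
auxiliary factor (loading 0.4) on which features may load too. A strict
one-factor model is rank-1 within group and cannot reproduce the published
correlation pattern (its MMSE and UPDRS-I cells misfit by up to ~0.09);
the auxiliary factors absorb exactly that residual structure, making the
construction a fuller Gaussian-copula fit while severity remains the single
shared disease axis. Calibration is numerical: a large common-random-number
cohort (25× the study size) is simulated once under a fixed internal RNG
stream, and coordinate-descent grid sweeps fit the severity loadings, then
the clinical loadings, then the age coupling (only the NM thresholded size
has a published age association, r = −0.22), and finally the per-cell
auxiliary loadings. Severity loadings are sign-constrained to each
feature's disease direction so that increasing latent severity can never
increase the NM contrast range or thresholded area, nor decrease mean
susceptibility. Because full-cohort rank correlations arise jointly from
this copula *and* from the group separation already fixed by the marginals,
cohort-level AUCs are emergent properties, not tunable targets.

**Image rendering.** With `image_level = TRUE` each subject becomes a set
of volumes: two axis-aligned SN ellipses per slice over three slices
(template sized so the control-mean mask areas are reproduced, ~557 mm² NM
and ~278 mm² QSM, rescaled per subject to the drawn mask size), plus a
rectangular anterior background ROI with a deterministic ±texture. In-mask
intensity profiles are constructed so that the extraction pipeline
reproduces the subject's drawn features: NM values follow a linear ramp
with exact mean and P90/P10 (exact because type-7 quantiles of equally
spaced values interpolate linearly), with the background level placed so
the mean + 3·SD rule isolates exactly the target suprathreshold count; a
floored contrast ratio (exactly 1) with a nonzero suprathreshold area
switches to a two-level profile. Susceptibility uses two symmetric ramps on
either side of 70 ppb whose side-means solve the overall mean under the
target below-cutoff count. SMWI targets are painted directly and the
magnitude is back-computed through the weighting; voxels at the weighting
ceiling (w = 0) are painted as exact SMWI zeros. Intensities are assigned
along the posterolateral→anteromedial axis (lowest NM and lowest χ most
posterolateral, where depigmentation begins and nigrosome-1 sits);
`gradient_strength` ∈ [0, 1] relaxes the strictness of that spatial
ordering without touching any statistic, since all extracted features are
permutation-invariant within masks. Ground truth is finally *re-measured*
from the painted (pre-noise) volumes, so sizes are quantised to whole
voxels and the zero-noise round trip is exact by construction; rare
infeasible target combinations (e.g. a mean susceptibility inconsistent
with its below-cutoff count) degrade gracefully and are reconciled the same
way. Noise is additive Gaussian (`noise_sd`); Rician noise, partial volume
and coil inhomogeneity are out of scope.

**Reader simulation.** Binary PD ratings are drawn independently per reader
given the true group, with per-reader sensitivity/specificity defaulting to
the published SMWI reader performance. This supports the agreement
statistics; it does not model reader correlation beyond the shared truth.

## What passing tests do and do not show

The phantom matches printed group marginals, a printed correlation matrix,
and plausible reader error rates. It does not carry real lesion morphology,
scanner artefacts, segmentation variability, or the unknown joint
distribution of the real cohort — so quantities that depend on that joint
distribution (cohort AUCs, sensitivities/specificities, p-values) are
checked as properties (e.g. the composite's AUC must not fall below its
best factor's by more than 0.02) rather than as numeric reproduction
targets.

## Numerical and testing choices

* Problem sizes: moment-convergence checks run at n = 10,000 per group,
  averaged over five seeded replicates because the widest marginal (SMWI
  low-signal area, CV ≈ 1.5) has ~1.5% sampling error in its mean at that
  n; parameter recovery uses 100 replicates at the study size (111/80) and
  is scored as the aggregate fraction of (quantity × replicate) checks
  inside ±0.25 (effect sizes) and ±0.12 (rank correlations), since at
  n = 191 those bands are only ~1.5σ of pure sampling noise for the largest
  effects, making per-quantity rates uninformative about generator quality.
* All cohort randomness derives from one seed; calibration uses its own
  fixed internal stream so fitted loadings depend only on the targets.
  Identical configuration + seed gives byte-identical cohorts and reports.
* Degenerate inputs are signalled with classed conditions: empty masks,
  non-positive P10 (contrast undefined), single-class ROC, zero pooled
  variance, zero between-subject variance (ICC), chance-saturated kappa.
  Zero background variance makes the NM cutoff fall back to the background
  mean with a warning.

## Known limitations

Manual three-slice segmentation is taken as given (no automated SN
segmentation); QSM reconstruction from raw phase is out of scope (volumes
are consumed, not reconstructed); the SMWI weighting constants are
plausible defaults, not the proprietary values; and the phantom's composite
performance should be read as internal validation of the pipeline, not as a
clinical performance claim.
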