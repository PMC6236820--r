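# margindose

Contour-based prediction of ipsilateral lung dose–volume metrics for breast
proton therapy.

Before a treatment plan exists, clinicians often need to know what lung dose
a proton plan could plausibly achieve — to set planning goals, judge plan
quality, or inform a referral. Highly conformal proton plans have falloff
isodose surfaces that resemble uniform expansions of the planning target
volume (PTV). `margindose` exploits that: the fraction of the ipsilateral
lung (IL) inside the PTV expanded isotropically by a margin *m*,

&nbsp;&nbsp;&nbsp;&nbsp;*V*(*m*) = |(PTV + *m*) ∩ IL| / |IL|,

predicts the dose–volume metric *V*<sub>*D*</sub> (lung fraction receiving
at least *D*) once *m* has been calibrated against planned cases by
minimising the root-mean-square prediction error

&nbsp;&nbsp;&nbsp;&nbsp;*m*<sub>*D*</sub> = argmin<sub>*m*′</sub> √⟨(*V*(*m*′) − *V*<sub>*D*</sub>)²⟩,

with the mean error ⟨*V*(*m*) − *V*<sub>*D*</sub>⟩ tracked as a bias
measure and all plans rescaled to a 50.4 Gy(RBE) reference prescription.
The shipped default model maps the 20 Gy(RBE) level to an 11 mm margin and
the 5 Gy(RBE) level to a 22 mm margin. Everything runs on plain voxel
grids: expansion is a signed Euclidean distance threshold (anisotropic
spacing honoured, compiled transform), prediction is an overlap count.

The package provides:

* `volumetric` core — signed distance maps, margin expansion/erosion,
  overlap fractions, *V*(*m*) curves;
* a DVH engine — prescription rescaling, trilinear dose resampling,
  *V*<sub>*D*</sub> / *D*<sub>*V*</sub> queries, falloff-width metric;
* the margin model — RMSE calibration, cohort-growth convergence,
  contour-only prediction;
* a phantom factory — synthetic thoracic geometry with exactly conformal
  (and deliberately cold-spotted) dose fields, so every claim is testable
  without patient data;
* IO — NIfTI masks/doses, DICOM RT-STRUCT/RT-DOSE (axis-aligned subset),
  YAML cohort manifests, JSON models, CSV curves, and a CLI
  (`inst/scripts/margindose.R`) with `predict`, `calibrate`, `curve` and
  `phantom` subcommands.

## Worked example

Calibrate on a jittered synthetic cohort, check convergence, then predict
for a new case from its contours alone:

```r
library(margindose)

spec <- phantom_spec(seed = 42)          # jittered synthetic cohort
cohort <- make_cohort(12, spec)

fit <- calibrate_margin(cohort, D = 20)
fit
#> <calibration_result> D = 20 Gy(RBE): m = 11 mm, RMSE 1.19 pp, ME +0.08 pp (n = 12)

conv <- convergence_run(cohort, D = 20, m = fit$margin_mm)
sprintf("converged at n = %d (RMSE %.2f pp)", conv$n_converged,
        conv$trace$rmse[conv$n_converged])
#> "converged at n = 10 (RMSE 1.11 pp)"

new_case <- make_phantom(phantom_spec(jitter_mm = 0, dose_jitter_mm = 0))
predict_volume(new_case$ptv, new_case$lung, default_margin_model(), 20)
predict_volume(new_case$ptv, new_case$lung, default_margin_model(), 5)
#> contour-only prediction: V20 = 7.1%, V5 = 23.8%
```

The calibration recovers the 11 mm margin that the phantom's conformal dose
was built with (its 20 Gy(RBE) isodose sits exactly 11 mm outside the PTV),
with an RMSE of about one percentage point of lung volume coming from the
cohort's case-to-case conformality jitter. The prediction for the new case
uses no dose grid at all: 7.1% of this phantom's lung lies within 11 mm of
its PTV, 23.8% within 22 mm.

The same pipeline from the shell:

```sh
Rscript inst/scripts/margindose.R phantom   --out-dir cohort --n 12 --seed 42
Rscript inst/scripts/margindose.R calibrate --manifest cohort/manifest.yaml \
        --dose-level 20 --out-dir cal
Rscript inst/scripts/margindose.R predict   --manifest cohort/manifest.yaml \
        --dose-level 20 --out-dir pred
```

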