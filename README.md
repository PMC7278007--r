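# sctdose

Desk-scale dosimetric evaluation of a segmentation-based synthetic CT
(sCT) method for MRI-only radiotherapy planning of the brain.

MRI-only treatment planning must derive electron-density information
from MR images, since MR intensity carries no attenuation information.
One practical approach segments the MR image into a small set of
tissue classes and assigns each class a fixed Hounsfield-unit value:

* cortical bone 942 HU, air −1000 HU, grey matter 41 HU, white matter
  25 HU, cerebrospinal fluid 15 HU, other soft tissue 40 HU.

`sctdose` implements the full evaluation loop for such a conversion on
a synthetic cohort of digital head phantoms (no patient data are
required or included):

1. **Phantom cohort** — seeded, co-registered CT/MR head pairs with
   six tissue classes, an air sinus, a contrast-enhancing lesion with
   clinically ranged GTV/PTV volumes, noise, MR bias field, skull HU
   gradient and partial-volume blur (`generate_cohort`,
   `phantom_config`, `noiseless_config`).
2. **sCT conversion** — EM Gaussian-mixture segmentation with
   bias-field estimation and rank-based class labelling, hard masks
   with a fixed tie-break priority and speckle cleanup, HU lookup
   (`run_sct_pipeline`).
3. **Bone metrics** — bone masks at a strict >300 HU threshold, Dice
   coefficient DSC = 2|A∩B|/(|A|+|B|), bone volumes and their relative
   difference, MAE over the crown-to-cranial-base body region
   (`bone_report`).
4. **Dose recalculation** — a simplified divergent 6 MV photon engine
   (exponential attenuation along Siddon ray traces, inverse-square,
   error-function penumbra) computes the CT-based plan normalised to
   the prescription at the PTV median, then recomputes the identical
   plan on the sCT with the same normalisation constant
   (`recalculate_on_sct`).
5. **DVH comparison** — ICRU-83 style parameters (D_max, D_0.1cc,
   D_2%, D_50%, D_95%, D_98%, D_mean) on the PTV and on the OAR ring
   (body tissue within 2 cm of the PTV edge), compared as
   ΔD = 100·(D_sCT − D_CT)/D_CT, with exact Wilcoxon signed-rank and
   Mann–Whitney U tests (`dvh_comparison`, `wilcoxon_signed_rank`,
   `mann_whitney_u`).
6. **Gamma analysis** — global 3D gamma index at 2%/2 mm and 1%/1 mm
   (dose differences normalised to the maximum reference dose, >10% of
   max-dose threshold, gamma capped at 2), with a brute-force oracle
   for validation (`gamma_map`, `gamma_brute_force`).

The numbered scripts under `analysis/` run the whole study
(simulate → convert → bone metrics → dose/DVH/gamma → cohort report →
outlier experiment → null calibration) and write their tables under
`results/`.

## Worked example

A realistic glioma case at desk-scale resolution, converted and
evaluated end to end:

```r
library(sctdose)
cfg  <- phantom_config("glioma", spacing_scale = 3, seed = 11)
case <- generate_case(cfg)
case
#> phantom_case (glioma, seed 11): GTV 49.09 cm^3, PTV 201.58 cm^3
#> grid3d: 67 x 67 x 30 voxels, spacing (3, 3, 6) mm

rec <- run_case(case, case_id = "demo")
rec$bone
#>   case_id  group v_ct_cm3 v_sct_cm3 dv_pct    dsc mae_hu
#> 1    demo glioma    484.3     487.6  0.669 0.9962  99.22

subset(rec$dvh, structure == "PTV")[, c("parameter", "delta_pct")]
#>   parameter delta_pct
#> 1     d_max   -0.7695
#> 2   d_0.1cc   -0.7275
#> 3    d_2pct   -0.5140
#> 4   d_50pct   -0.3187
#> 5   d_95pct   -0.3267
#> 6   d_98pct   -0.4008
#> 7    d_mean   -0.3527

rec$gamma[, c("criterion", "pass_rate_pct")]
#>   criterion pass_rate_pct
#> 1    2%/2mm        100.00
#> 2    1%/1mm         99.01
```

Reading the output: the sCT overestimates the skull volume by 0.7%
with near-perfect overlap (DSC 0.996 — the smooth phantom anatomy is
much easier to segment than patient data), the mean absolute HU error
inside the head is ~99 HU (dominated by the skull's continuous HU
gradient, which the six-value sCT cannot represent), recalculating the
identical plan on the sCT changes every PTV DVH parameter by less than
1% (slightly negative: the sCT's uniform 942 HU skull attenuates a
little more than the blurred, graded CT skull), and the dose
distributions agree at 100% / 99% of evaluated voxels under the
2%/2 mm and 1%/1 mm gamma criteria.

On a noiseless phantom (`noiseless_config()`) the pipeline is exact:
DSC 1, MAE 0, all ΔD = 0, both pass rates 100% — a fixed point the
test suite asserts.

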