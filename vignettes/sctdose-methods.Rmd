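---
title: "Methods: evaluating a segmentation-based synthetic CT at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating a segmentation-based synthetic CT at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package computes

MRI-only radiotherapy planning of the brain needs electron-density
information that MR images do not carry, so a synthetic CT (sCT) is
generated from the MR image and used as the attenuation data for dose
calculation. One family of sCT methods segments the MR image into a
small number of tissue classes and assigns each class a fixed
Hounsfield-unit (HU) value. `sctdose` implements a desk-scale evaluation
of such a six-class conversion: it generates co-registered CT/MR head
phantoms, converts the MR to an sCT, and quantifies (i) bone
segmentation accuracy (Dice coefficient, bone volume, mean absolute HU
error), (ii) dosimetric agreement when an identical photon plan is
recalculated on the sCT (ICRU-83 DVH parameters, relative differences),
and (iii) spatial dose agreement via the global 3D gamma index at
2%/2 mm and 1%/1 mm.

The six classes and their HU values are: cortical bone 942, air −1000,
grey matter 41, white matter 25, cerebrospinal fluid 15, and "other
soft tissue" 40. The first five are literature values used by
segmentation-based conversions; the identity and HU of the sixth class
is the package's own choice (a generic soft-tissue value) and is
configurable via `hu_table()`.

## The synthetic cohort and what it emulates

No patient data ship with the package. The `phantom` module generates a
seeded cohort of head phantoms standing in for a clinical cohort of 10
glioma and 10 brain-metastasis patients:

* **Anatomy.** Nested ellipsoids: a soft-tissue scalp (6 mm), a skull
  shell (7 mm, configurable), a CSF layer (4 mm), a grey-matter shell
  (12 mm) and a white-matter core, plus an air sinus cavity in the
  anterior skull base and an ellipsoidal lesion placed uniformly at
  random inside the eroded brain.
* **Lesion volumes.** Drawn uniformly from the clinical GTV ranges
  (glioma 14.2–112.3 cm³, metastasis 0.1–16.4 cm³). The GTV→PTV margin
  is derived per case by matching the quantile of the GTV range to the
  same quantile of the clinical PTV range (sphere-equivalent radii), so
  cohort PTV volumes land inside the clinical ranges by construction.
* **Geometry.** 1×1 mm in-plane resolution with 2 mm slices for glioma
  and 1 mm slices for metastasis cases; `spacing_scale` coarsens all
  axes for desk-scale runs (the default experiments use
  `spacing_scale = 3`, i.e. roughly 64³-equivalent grids, chosen so a
  full 20-case cohort runs in well under a minute per stage).
* **CT simulation.** Class-mean HU plus, in the realistic regime, a
  continuous skull HU gradient (1300 HU at the cortical tables falling
  to 700 HU in the diploë), 0.5-voxel Gaussian partial-volume blur, and
  Gaussian noise (SD 20 HU, a typical head-CT noise level).
* **MR simulation.** A single T1w-like channel with class means
  air 0 < bone 30 < CSF 65 < GM 100 < soft 135 < WM 170 (arbitrary
  units; WM brightest and CSF dark as on T1-weighted images), times a
  smooth multiplicative bias field (random quadratic polynomial,
  amplitude 0.1), plus Gaussian noise (SD 5, about 3% of the WM mean).
  The lesion is "contrast-enhancing": its intensity is the GM mean
  times 1.4, which places it between soft tissue and WM and makes it a
  genuine segmentation confounder.

`noiseless_config()` switches all degradations off. In that limit the
CT is exactly the class-mean lookup of the labels, the MR classes are
perfectly separable, and the whole pipeline has a zero-error fixed
point (Dice 1, MAE 0, all dose differences 0, both gamma pass rates
100%). This limit is what several tests pin down exactly.

What the phantom does **not** emulate: cortical folding, MR sequence
physics (the clinical method uses Dixon imaging; we generate one
scalar channel), thermoplastic-mask and beam-hardening artifacts,
registration error (phantom pairs are generated co-registered, so
rigid registration is deliberately out of scope), and realistic skull
pneumatization. Consequently the phantom is *easier* to segment than
patient data: Dice coefficients come out near 0.99 where the clinical
study reports ≈0.8, and gamma pass rates are correspondingly higher.
Passing tests therefore validate the *machinery* (metrics, dose
comparison, statistics) and the *mechanisms* (noise degrades accuracy,
body-outline errors depress dose), not clinical performance.

## Segmentation and sCT assembly

The clinical conversion used an external template-prior EM
segmentation. Here the segmentation is self-contained:

1. The body outline is found by intensity thresholding (10% of the
   99th intensity percentile) followed by hole filling, so internal
   air cavities stay inside the outline.
2. Air is assigned by thresholding everywhere (outside the outline and
   in internal cavities). This avoids a degenerate mixture component:
   air is a sliver of the in-body volume, and a 6-component fit tends
   to starve the air component and split a large class instead.
3. The remaining in-body voxels are fitted with a 5-component Gaussian
   mixture by EM (k-means initialisation at intensity quantiles, a
   variance floor of (10⁻⁴ × intensity range)², convergence at 10⁻⁵
   relative log-likelihood — tighter tolerances only chase
   classification-irrelevant drift when classes overlap — at most 300
   iterations, error on non-convergence). A multiplicative bias field
   is re-estimated at most four times inside the loop as a quadratic
   polynomial fit to the class-centred log-ratio of observed intensity
   and assigned class mean, using only confidently classified voxels
   (posterior > 0.9), with MAD trimming of outliers and a damped,
   clamped update. The centring, trimming and damping keep the
   polynomial from absorbing anatomy — an unconstrained fit diverges
   on this phantom because the nested-ellipsoid anatomy is itself
   nearly quadratic. On bias-free data the update is the identity,
   which preserves the noiseless fixed point.
4. Components are labelled by matching fitted-mean ranks to the
   expected intensity ordering (or by majority overlap with an optional
   atlas hint).
5. Hard masks are the per-voxel argmax with ties broken by the fixed
   priority bone > CSF > GM > WM > soft > air; connected components of
   bone or air smaller than 0.05 cm³ are reassigned to soft tissue.
6. The sCT is the piecewise-constant HU lookup of the masks; if a
   different reference grid is requested, the class labels are
   resampled nearest-neighbour before the lookup so the output stays
   six-valued.

The lesion has no dedicated class: contrast-enhancing tissue folds
into whichever class its intensity matches (by default between soft
tissue and WM), which is exactly the failure mode of interest when
judging robustness to contrast agents.

## Dose engine

The clinical study recalculated plans in a commercial treatment
planning system. That algorithm is out of scope; the package's engine
is a deliberately simple divergent-beam model applied *identically* to
CT and sCT, which is all the comparison methodology requires (any
physically monotone engine exercises the DVH/gamma machinery, and the
zero-error fixed point is preserved by construction):

dose_b(v) = w_b · exp(−μ_eff · d_rad(v)) · (SAD / r(v))² · P(v)

with μ_eff = 0.0049 mm⁻¹ (6 MV water-equivalent), d_rad the
radiological depth from source to voxel (exact Siddon-style voxel
traversal of the density volume), r the source distance, SAD 1000 mm,
and P an error-function lateral penumbra (σ = 3 mm at the field edge,
projected to the isocentre plane). No buildup or scatter modelling —
the surface dose is therefore the entrance maximum, and OAR-ring
maxima can exceed PTV maxima. HU→density uses a piecewise-linear
calibration anchored at (−1000, 0.001), (0, 1.0), (942, 1.512),
(3071, 2.2).

Plans are 4 equally weighted coplanar beams (configurable) at evenly
spaced gantry angles aimed at the PTV centroid, with a square field
covering the PTV bounding box plus 5 mm. The prescription (default
30 Gy; the absolute level cancels in all relative metrics) is imposed
by scaling the CT-based dose so the PTV median equals the
prescription; the *same* constant is reused for the sCT dose. This is
the plan-copy semantics: differences between the two dose grids
reflect the attenuation data alone.

## DVH comparison

DVH parameters follow the near-max/near-min convention: D_X% is the
minimum dose of the hottest X% of the structure (the (1 − X/100) dose
quantile with linear interpolation between voxel order statistics —
the interpolation rule is the package's choice), D_0.1cc the minimum
dose of the hottest 0.1 cm³ (falling back to D_max with a warning for
structures under 0.1 cm³), D_max the voxel maximum (reported separately
from D_0.1cc), and D_mean the arithmetic mean. Relative differences
are 100 × (D_sCT − D_CT)/D_CT. The OAR surrogate is the ring of BODY
tissue within 2 cm of the PTV outer edge, excluding the PTV: the
exclusion is supported by the clinical volume arithmetic (PTV and OAR
volumes would otherwise overlap), and the ring is clipped to BODY.
Note the ordering D_0.1cc ≥ D_2% only holds for structures above
5 cm³, where 0.1 cm³ is the smaller (hotter) subvolume.

Within-group CT-vs-sCT comparisons use a two-sided Wilcoxon
signed-rank test (Pratt zero handling; exact null distribution by
enumerating the sign-flip generating function over the observed
midrank multiset for up to 25 non-zero differences, normal
approximation with zero and tie corrections above). Between-group
comparisons use a two-sided Mann–Whitney U test (exact enumeration of
all group assignments for pooled n ≤ 12, tie-corrected normal
approximation above). Both switchovers are package choices; two-sided
tests throughout.

## Gamma analysis

The gamma index is global: dose differences are normalised to the
maximum of the *reference* (CT-based) dose — the direction matches the
relative-difference convention; which distribution "global" refers to
is configurable. Voxels at or below 10% of the maximum reference dose
are not evaluated, and gamma is capped at 2. The fast implementation
searches trilinearly interpolated evaluated dose on an offset lattice
of step dta/10 out to radius cap × dta (beyond which gamma would
exceed the cap anyway), visiting offsets by increasing distance so the
scan stops as soon as the pure distance term exceeds the best gamma —
an exact pruning — and then refines the best offset by compass search
down to 4 µm steps. The in-package brute-force oracle is independent
plain-R code: an exhaustive 0.1 mm lattice (0.07 mm in the acceptance
comparison) with its own trilinear interpolation and only
mathematically exact pruning. Agreement between the two is asserted to
0.02 gamma units on smooth dose pairs; note both are lattice searches,
so the comparison is only meaningful where the lattice resolves the
gamma surface (dose gradients of a few tenths of a Gy per mm at a
30 Gy maximum). Every report row embeds the full criteria (dose
difference, DTA, threshold, cap, normalisation), since gamma results
are not interpretable without them.

## Numerical and design choices

* Voxel-centred 0-based geometry, world coordinates in mm, x fastest;
  one convention across containers, resampling, distance transforms
  and ray tracing.
* Distance transforms are exact Euclidean (Felzenszwalb–Huttenlocher
  separable parabola method) honouring anisotropic spacing.
* Volumes are exchanged as NIfTI-1 (via RNifti) or MetaImage (own
  reader/writer; no R package provides the format); float32 payloads,
  masks as uint8. DICOM is deliberately not supported: synthetic data
  has no scanner metadata.
* Per-case seeds derive from the master seed as `seed × 1000 + index`;
  the segmentation seed is the case seed + 1. Everything downstream is
  deterministic given the master seed.
* The bone threshold is a strict exceedance (> 300 HU), so on the
  piecewise-constant sCT the bone mask equals the 942 HU class mask
  exactly.
* The "crown to cranial base" MAE region is implemented as the BODY
  mask restricted to the top 55% of axial slices containing BODY (+z
  superior); no landmark detection is attempted.
* BODY is the filled head outline and therefore *contains* the air
  sinus: a body outline is what the dose engine and the body-dilation
  outlier mechanism operate on.

## Known limitations

The dose engine has no buildup, scatter, or MLC modelling; absolute
doses are not clinically meaningful, only CT-vs-sCT differences are.
The phantom's smooth ellipsoid anatomy inflates segmentation accuracy
relative to patients. The statistical tests at cohort size 10+10 have
limited power, exactly as in the emulated study design. Gamma
agreement between the fast path and the oracle is only asserted where
lattice searches resolve the gamma surface; clinical-grade dose
gradients at 1 mm DTA would need a finer oracle than is practical in
plain R.
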