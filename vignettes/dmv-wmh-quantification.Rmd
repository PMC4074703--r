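---
title: "Quantifying deep medullary vein visibility and WMH burden: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying deep medullary vein visibility and WMH burden: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dmvq)
```

## The measurement problem

White matter hyperintensities (WMH, leukoaraiosis) are patchy or confluent
bright regions in the cerebral white matter on T2/FLAIR MRI of older adults.
One candidate mechanism is venous: collagenosis and stenosis of the small
deep medullary veins (DMVs) that drain the periventricular white matter can
produce venous ischemia and vasogenic edema. On susceptibility-weighted
(SWI) phase images, deoxygenated venous blood is paramagnetic and DMVs
appear as thin hypointense lines, so their *visibility* — quantified as a
segmented voxel count — is an in vivo proxy for venous caliber and
deoxygenation. `dmvq` implements the full quantitative chain that relates
this vein voxel count to WMH volume:

1. **Phase correction** — homodyne high-pass filtering of the complex GRE
   data removes the smooth background field (air/tissue interfaces, shim)
   while preserving the localized susceptibility signature of veins.
2. **Threshold segmentation** — a Gaussian is fitted to the parenchyma
   intensity histogram; WMH voxels are those above `mu + 3 sigma` on FLAIR,
   DMV voxels those below `mu - 2 sigma` on corrected phase. Both
   multipliers are protocol constants, fixed a priori.
3. **Volumetry** — WMH volume (WMHV) is voxel count times voxel volume;
   head size is removed via `CWMHV = WMHV * meanICV / ICV`, with the mean
   intracranial volume always bound over the analyzed cohort.
4. **Regional partitions** — periventricular vs deep WMH by a 10-mm
   Euclidean distance from the lateral ventricles (anisotropy-aware, 3D),
   and a regional WMH volume restricted to the same five 2-mm slices used
   for the vein count (the periventricular slab).
5. **Cohort statistics** — median split of CWMHV, Welch t and Fisher exact
   group comparisons, partial Pearson correlation (residualization on
   age, sex, education, microbleed and lacune counts), backward stepwise
   logistic regression with age forced, two-way ICC, Bonferroni adjustment.

Because the underlying patient scans are not publicly available, every
stage is exercised against seeded synthetic phantoms and cohorts with known
ground truth; the published cohort values (e.g. partial r = 0.506) serve as
defaults of the cohort generator, not as claims this package can reproduce
from data.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `k_wmh` | 3 | SD | FLAIR hyperintensity threshold above the fitted mean |
| `k_dmv` | 2 | SD | phase hypointensity threshold below the fitted mean |
| `central_matrix` | 32 | freq. bins | retained central block of the 2D spectrum (on a 256 x 256 acquisition matrix) |
| `n_slices` | 5 | slices | periventricular slab; 5 x 2.0 mm = 10 mm |
| `pvh_distance_mm` | 10 | mm | periventricular/deep cutoff, inclusive |
| in-plane spacing | 0.4688 | mm | acquisition resolution (240 mm FOV / 256) |
| slice thickness | 5.0 / 2.0 | mm | FLAIR / SWI |

The filter's central matrix is an *absolute* spectral size: its effect
depends on the acquisition matrix. On the native 256 x 256 grid it keeps
12.5% of each in-plane axis; phantoms meant to probe filter fidelity should
therefore use a 256-wide (or at least ~192-wide) grid, which the shipped
tests do.

## The synthetic world

`phantom_spec()` describes a miniature head: ellipsoidal brain and
intracranial envelopes, two lateral-ventricle ellipsoids, spherical lesions
with intensity offsets in parenchyma-SD units, and veins as piecewise-linear
tubes (rasterized by mm distance-to-segment, so anisotropic voxels are
handled exactly) that subtract a fixed phase depth. Geometry is
deterministic; only noise depends on the seed.

Values the protocol does not pin down were chosen once, on physical
plausibility, and are stated here rather than tuned:

* FLAIR parenchyma mean 100, SD 10 (arbitrary image units — no patient
  intensity statistics exist to copy).
* Phase noise SD 0.08 rad, typical of 3-T GRE phase SNR in parenchyma.
* Vein phase depth 0.8 rad and tube radius 0.6 mm: a strongly paramagnetic
  venule plus blooming, about 1–2 voxels wide in-plane at 0.4688 mm.
* Background field: 2nd-order polynomial with ~0.5–1 rad range across the
  field of view.
* The cohort generator's covariate means/SDs follow the published baseline
  table (age 66.5 ± 12.8 y, CWMHV 35.3 ± 28.3 ml, DMV count 3676 ± 1071,
  …), with the partial correlation between log-CWMHV and DMV count given
  the adjustment covariates as the tunable target (default 0.506). The
  construction (`x = a'z + sqrt(1-|a|^2) e_x`, correlated unique parts)
  makes the implied population partial correlation equal the target
  exactly, which the tests assert from the precision matrix.

What a green phantom test does **not** establish: the phantoms contain no
partial-volume CSF, no coil shading, no flow or motion artifacts, no
T2-weighted anatomy, and lesions/veins with idealized geometry; Bloch
physics is out of scope. Passing means the *algorithms* implement the
stated rules faithfully, not that the pipeline is validated on patients.

## Numerical choices

* **Spectrum block placement.** The central block is applied to the
  DC-centred spectrum; for even sizes the block takes the DC bin plus the
  remaining bins symmetrically, favouring the lower index. This is fixed so
  the filter is bit-reproducible. A Hann taper exists but is off by
  default; the sharp block is the reference behaviour.
* **Robust distribution fit.** "Fitted distribution of brain parenchyma" is
  realized as a least-squares Gaussian fit to the Freedman–Diaconis
  histogram restricted between the 2nd and 90th intensity percentiles, so
  lesion (upper) or vein (lower) tails cannot inflate the SD — the shipped
  comparison shows a 2% lesion tail at +6 SD biasing the naive moment SD by
  >30% while the robust fit stays within 2%. A plain-moments
  estimator is available for comparison. The same fit serves the phase
  model; the fit scale is the corrected phase itself.
* **Tie rules.** Voxels exactly at a segmentation threshold are *not*
  segmented; distance exactly 10 mm is periventricular (inclusive); values
  exactly at the median go to the low group. All fixed and tested.
* **Distance transform.** Full 3D squared-distance lower-envelope transform
  with the physical spacing per axis; verified against an O(n^2)
  brute-force oracle on anisotropic grids.
* **Connected components** use 26-neighbourhood connectivity in 3D.
* **Registration** (FLAIR moving, phase fixed — the phase grid is never
  resampled) optimizes normalized mutual information (or MSE for
  same-modality tests) over 6 rigid parameters: coarse multi-start within
  ±4°/±4 mm on a subsampled grid, then Nelder–Mead at full resolution with
  relative tolerance 1e-5. Masks move by nearest-neighbour pull-back.
* **Stepwise elimination** uses exact refit likelihood-ratio tests with
  removal threshold p > 0.10 rather than the SPSS "conditional" score
  approximation: the exact test is well-defined, and the greedy path is
  verified against a brute-force replay of every removal decision. The
  univariate screen (p < 0.1) applies to clinical candidates; demographics
  and the vein count enter regardless, and age is forced throughout. MMSE
  is excluded as a consequence, not a cause, of WMH severity.
* **Fisher's exact test** enumerates all margin-preserving tables and sums
  probabilities no larger than the observed table's (the probability
  method), budgeted at r x c <= 12 cells; larger tables error with a
  chi-square suggestion rather than silently approximating.
* **ICC** defaults to the two-way, single-measures, absolute-agreement form
  (the stricter choice); the consistency form is one flag away.
* **t-test** defaults to Welch; the pooled variant is available. The
  all-constant, equal-means degenerate case is defined as t = 0, p = 1.

## Design decisions on genuinely open points

* **Multi-echo combination.** The acquisition had 11 echoes but no stated
  combination rule; the package accepts one complex (or magnitude+phase)
  volume and leaves echo combination to the caller.
* **False-vein removal.** The original workflow removed false DMVs
  (microbleeds, sulcal vessels) manually. The package substitutes an
  exclusion-mask interface plus an automatic shape flagger
  (`flag_false_dmv_candidates()`): components that are too small
  (< 10 voxels by default — sub-vein-scale speckle at this resolution),
  too large (volume cap, disabled by default), near-spherical
  (elongation < 3, the microbleed signature), or touching the cortical rim
  can be flagged. `run_subject()` applies the flags as an exclusion by
  default; the flagger itself never mutates a segmentation.
* **PVH rule scope.** The 10-mm periventricular rule was originally applied
  to confluent lesions only; it is applied uniformly here (simpler and
  monotone), which slightly reclassifies small juxtaventricular punctate
  lesions.
* **Basal ganglia reference.** "Immediately above the basal ganglia" is an
  anatomical judgement; the slab selector takes an explicit reference slice
  index and never infers it from images.
* **ICV delineation** is an input mask (phantom truth or external tool); no
  skull-stripping is attempted.
* **Grids.** FLAIR (5 mm) and SWI (2 mm) phantoms share a physical space so
  resampling is exercised; a same-grid mode exists for identity-transform
  tests. Configs and reports are JSON; volumes are NIfTI-1.

## Limitations

* The paper-scale cohort results are not reproducible without the patient
  images; the package demonstrates recovery of *known* synthetic targets
  only (e.g. a generated partial correlation of 0.6 at n = 200 is recovered
  within its 95% CI).
* The pure-R distance transform and registration are sized for desk-scale
  volumes (~10^6 voxels); they are quadratic-free but not optimized for
  full clinical resolutions.
* The homodyne filter attenuates part of the vein dip itself (about 30% at
  the native relative cutoff); vein counts are therefore calibrated to the
  protocol's acquisition geometry, as in the original workflow.
* Phase unwrapping, QSM, mIP venography and SWI magnitude-mask
  multiplication are deliberately out of scope.
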