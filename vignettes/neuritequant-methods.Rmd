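---
title: "neuritequant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuritequant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`neuritequant`: what each stage computes, which parameters matter, what the
synthetic generator does and does not emulate, and where the design was
genuinely open.

## The measurement problem

Neuronal differentiation assays in NG108-15-class cells quantify four
readouts from two-channel fluorescence images (DAPI nuclei + a green
marker) and two kinds of bench tables:

1. mean neurite length per cell (neurofilament staining or label-free
   proxies, 48-h growth and 60-min pharmacological retraction);
2. counts of synaptotagmin-1 puncta lying on neurites;
3. the nuclear vs cytoplasmic distribution of RhoA;
4. plate-reader (G-LISA RhoA activity at OD 490 nm, BrdU proliferation at
   OD 450–540 nm) and RT-qPCR readouts reduced to fold changes.

No public image set accompanies this class of experiment, so the package
pairs every analysis stage with a generator that produces scenes with
*exact* ground truth, and all validation is against that ground truth.

## À trous wavelet spot detection

`atrous_decompose()` implements the undecimated B3-spline scheme:
$A_0 = I$, $A_j = A_{j-1} * h_j$ where $h_j$ is (1/16, 1/4, 3/8, 1/4, 1/16)
with $2^{j-1}-1$ zeros between taps, applied separably; $w_j = A_{j-1} -
A_j$. Borders are mirror-reflected, chosen because it preserves the exact
reconstruction identity $I = A_J + \sum_j w_j$ (asserted to 1e-9 relative
in the tests) and adds no intensity bias. `detect_spots()` thresholds each
plane of `scale_range` at $k\,\hat\sigma_j$ with $\hat\sigma_j =
\mathrm{MAD}(w_j)/0.67449$ (a robust scale estimate that tolerates the
signal's own outliers), multiplies the thresholded planes, binarizes, and
keeps connected components with area in `[min_area, max_area]`. Centroids
are intensity-weighted by the multiscale product.

Parameter defaults: `k_sigma = 3` (the usual 3-sigma operating point),
`min_area = 2` px, `max_area = 200` px, `n_scales = 4`. The default
`scale_range = c(1, 3)` includes the finest plane deliberately: planes 2
and 3 of pure noise are spatially correlated, so their joint exceedance
alone still produces occasional 2–3 px false blobs, whereas a joint
exceedance that also requires fine-scale support is vanishingly rare on
blank fields. With puncta rendered at PSF scale the finest plane carries
strong signal, so recall is unaffected. Nuclei use `scale_range = c(3, 4)`
with `min_area = 40`, `max_area = 5000` px, matching nucleus radii of
4–6 µm at 0.65 µm/px. Touching nuclei are not split; the generator keeps
nuclei separated, and declumping is out of scope.

## Pixel classification and neurite length

`compute_pixel_features()` builds a frozen, versioned 25-feature bank:
intensity plus six filter families (Gaussian smoothing, gradient magnitude,
Laplacian, both Hessian eigenvalues, largest structure-tensor eigenvalue)
at σ ∈ {1, 2, 4, 8} px. Hessian eigenvalues are the ridge detectors that
make 2–3 px neurites separable from somata; the scales bracket neurite
widths through soma diameters. Derivatives are central differences on the
smoothed image with replicated borders.

`train_pixel_classifier()` fits a seeded `ranger` probability forest
(100 trees, depth ≤ 14, 3000 pixels per class per scene). Any classifier
returning per-pixel 3-class posteriors can substitute. `segment()` takes
the argmax, removes neurite components < 5 px, fills holes < 25 px inside
cell bodies, and reads the cell count from the DAPI channel via the wavelet
nucleus detector. A conservative prefilter (pixels of the 2-px-smoothed
image below median + 3·MAD are labelled background directly) restricts
forest evaluation to candidate foreground; on our scenes the gate sits far
below the dimmest structures (neurites are ≳ 15 robust sigmas above
background), and `prefilter = FALSE` disables it.

**Length measure.** The neurite mask is thinned (Zhang–Suen, plus a
staircase-removal pass that deletes corner pixels whose perpendicular
orthogonal neighbours remain diagonally connected). Length is counted on
the skeleton adjacency graph: orthogonal steps 1 px, diagonal steps √2 px
(diagonal links short-circuited by a shared orthogonal neighbour are
skipped), minus 0.1 px per orthogonal/diagonal direction change (the
classical corner correction, which removes the ~7% staircase over-estimate
of oblique lines), plus 1 px per skeleton endpoint (thinning retracts each
free end by roughly half the stroke width). The tests pin this estimator to
analytic bars at 0°, 30° and 45° within 5%. Without the corner term the
plain (1, √2) count cannot be rotation-robust to 5%, so the correction is a
deliberate amendment of the simpler rule. Absolute lengths of strongly
curved neurites are still under-estimated (sub-pixel wiggle is smoothed
away by rasterization and thinning); all headline quantities are ratios
between conditions measured with the same estimator, which cancels this
bias — the fold-recovery tests quantify the residual error.

Per-cell normalization divides the total skeleton length of the image by
the DAPI-object count; no attempt is made to assign neurites to individual
cells. A zero nucleus count raises a missing-denominator error rather than
returning 0.

## Spot context and classification

Each detected spot gets exactly 50 features: 40 bilinear samples on the
circle of radius 9 px (angles counter-clockwise from the +column axis), the
number of local maxima of that circular profile, and mean intensities of
centered squares of sides 3–19 px. The 40 + 1 + 9 split is a declared,
versioned reconstruction of the three feature families (profile, maxima
count, multi-window means). A punctum on a straight neurite shows exactly
two profile maxima — the two points where the neurite crosses the circle —
which is the geometric signature separating on-neurite from isolated or
spurious detections. Maxima are counted after a 3-sample circular moving
average, with strict inequality and plateau collapse; profile values are
quantized to 1e-8 of their range first so numerical ripple in flat regions
cannot create maxima. Spots closer than 10 px to the border are computed
with mirror padding and flagged `padded`.

The spot classifier is a seeded ranger forest trained *without* bootstrap
resampling (`replace = FALSE`, `sample.fraction = 1`); tree diversity comes
from feature subsampling only. This makes the decision function a
deterministic functional of the empirical training distribution, so
duplicating training rows is a no-op — a property the test suite asserts.

## Nuclear vs cytoplasmic quantification

`compartment_masks()` thresholds both 1-px-smoothed channels (Otsu by
default; `fixed` and `percentile` are available because Otsu fails once
nuclei dominate the green histogram, e.g. configured ratios ≳ 4). Nuclei
are DAPI objects ≥ 30 px; cytoplasm is green minus nuclei.
`rhoa_localization()` assigns cytoplasm pixels to the nearest nucleus
centroid (Euclidean; the scenes' cells are convex, so a geodesic variant
was not implemented) and excludes a 2-px dilated guard band around nuclei
from the cytoplasm so PSF-mixed boundary pixels do not contaminate it.
Nuclear statistics use the full DAPI object: eroding a "core" would bias
the mean upward because the simulated subnuclear puncta are centrally
concentrated. Both reported metrics — the nuclear/cytoplasmic mean ratio
and the SD of nuclear intensities over the cytoplasmic mean — are ratios of
raw intensities, hence invariant to multiplicative rescaling; additive
offsets pull them toward 1, which is property-tested, so background
subtraction is the caller's responsibility.

## The synthetic generator

Scenes are rendered shapes → ideal intensity map → Gaussian PSF →
Poisson shot noise → additive Gaussian read noise, with ground truth taken
from the pre-noise geometry. Key defaults (all configurable via
`scene_config()`):

| parameter | default | rationale |
|---|---|---|
| pixel_size | 0.65 µm/px | 20×-objective class |
| field | 512 × 512 px (desk scale) | ~333 µm square |
| n_cells | 12 | 10–50 cells/field regime |
| nucleus radius | 5 ± 0.5 µm | DAPI objects at this magnification |
| soma radius | 9 µm | NG108-15-like somata |
| neurites/cell | 1 + Poisson(1) | 1–4 processes |
| neurite length | 60 µm × condition multiplier | 48-h control scale |
| neurite width | 1.3 µm (2 px) | thin processes |
| psf_sigma | 0.8 µm | wide-field-class PSF |
| background / soma / neurite / DAPI | 100 / 400 / 350 / 600 counts | mid-range 16-bit SNR |
| poisson_scale | 1 photon/count; `Inf` = off | shot-noise dominated |
| gaussian_sd | 10 counts | read noise |
| spots on/off neurite | 0.04 /µm, 3e-4 /µm² | resolvable puncta |

Neurites are unit-step random-walk polylines (heading increments
N(0, 0.1 rad)) launched from the soma perimeter, reflected off a border
margin so the designed length is always fully rendered; the final step is
fractional, making the polyline length *exactly* the designed length. All
layout randomness (positions, radii, neurite counts, per-neurite length
factors) is drawn before any condition multiplier is applied, so two
conditions generated from the same seed differ only by the multiplier and
their ground-truth ratio equals it exactly — the basis of the
parameter-recovery tests. Puncta are placed as a Poisson process along the
centerline (on-neurite) or uniformly with a 3-px exclusion buffer around
neurites (off-neurite), then thinned to a 5-px hard core so neighbouring
puncta stay optically resolvable; the synaptotagmin marker renders the
diffuse non-vesicular component at 5% of the neurofilament amplitudes. The
RhoA marker renders the nuclear signal so that the raw nuclear mean is
`nuc_cyto_ratio × multiplier` times the raw cytoplasmic level, with 40% of
it carried by five subnuclear Gaussian puncta — both the mean ratio and the
nuclear SD then scale linearly with the multiplier.

Time-lapse series reuse one master geometry and only evolve neurite length:
elongation adds `growth_rate` µm/h per neurite tip; retraction follows
$L(t) = L_0\,[1 - T(1 - e^{-t/\tau})]$ with τ = 27 min, and the asymptotic
total $T$ derived from the calibrated 77% decrease at 60 min. With τ = 27
min, more than half (≈ 87%) of the total retraction occurs within the
first 40 minutes. Frames share the layout seed; noise is fresh per frame.
The series are rendered in fluorescence contrast even though live-cell
instruments often image label-free; the segmentation stages are
contrast-agnostic by contract, and modelling phase optics is out of scope.

**Not emulated:** photobleaching, drift, uneven illumination, 3-D stacks,
brightfield/phase rendering, touching nuclei, cell division, migration
trajectories. Passing the recovery tests therefore shows the *pipeline* is
unbiased under the stated noise and geometry model; it does not certify
performance on real micrographs with those artefacts.

## Assay and statistics layer

Plate tables draw replicate ODs as `control_mean × multiplier + N(0, sd)`
(control means 0.8 G-LISA, 1.2 BrdU). qPCR Ct tables shift the treated Ct
by −log2-fold-change with gapdh fixed; `qpcr_fold_change()` is ΔΔCt with
amplification efficiency exactly 2, so generator and reduction are exact
inverses in the noiseless limit. Percent changes are `(1 − treated/reference)
× 100` (positive = reduction); the reversed comparison is the algebraic
−33.3% for a 0.75× multiplier, not +25%. `run_stats()` wraps `stats::aov`,
`t.test` and Bonferroni-adjusted `pairwise.t.test`; repeated measures use
positions as subjects (`value ~ group + Error(subject)`), require a
balanced design, and pair the post-hoc t-tests. The exact
repeated-measures structure behind published F-statistics of this assay
family is not recoverable without the raw data; the implemented design is
documented here, not asserted as the original.

## Problem sizes

The shipped experiments are desk-scale: the acceptance script uses
512 × 512 scenes, 10 per condition, a 3-position 61-frame retraction series
at 224 × 224, and noiseless assay tables (~5 min on one CPU); the test
suite re-runs the same recoveries at 256 × 256 with 6 scenes per condition
and identical tolerances, plus 1000-replicate null simulations for the
ANOVA calibration. Classifier training uses 4 scenes cycling over control
and treated conditions so short and long neurites are both represented.

## Known limitations

* Absolute neurite lengths are biased low for tortuous processes (ratio
  metrics are unaffected; see the length-measure section).
* Otsu thresholding fails when one compartment dominates the histogram; use
  `fixed` or `percentile` thresholds for extreme ratios.
* On-neurite puncta counts saturate sublinearly at high densities because
  of the hard-core thinning and detector merging; the shipped densities
  stay in the linear regime.
* The classifiers are trained on synthetic texture; applying them to real
  images requires retraining on hand-labelled pixels/spots via the same
  `train_*` entry points.
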