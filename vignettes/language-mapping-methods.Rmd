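---
title: "Mapping the language network from task and resting-state BOLD: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the language network from task and resting-state BOLD: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langmapr)
```

## The problem

Before resecting a brain lesion near eloquent cortex, surgeons need a map of
the patient's language areas. Two fMRI routes exist. Task fMRI contrasts
BOLD activity between a sentence-generation (SG) condition and a
tone-listening (TL) baseline in a block design; it requires the patient to
perform the task well. Resting-state fMRI instead isolates the language
network (LANGrest) from the synchrony of spontaneous BOLD fluctuations
(below about 0.1 Hz) with no task at all, via spatial independent component
analysis (sICA). Both maps are ultimately judged against intraoperative
electrocortical stimulation (ECS) during awake craniotomy — the gold
standard — under a simple rule: an eloquent stimulation site counts as
detected when the map has a peak within 10 mm of it.

`langmapr` implements this whole chain: a grid/map data model in MNI space,
a block-design GLM with the canonical haemodynamic response and multiple-
comparison control, extended-Infomax spatial ICA with rule-based network
identification, mass-based lateralization indices, a second-order paired
comparison of the two map types, and the 10-mm concordance statistic.
Because the clinical imaging data underlying the shipped tables are not
public, a seeded synthetic BOLD generator provides ground-truth data for
validation, and the patient-level tables (cohort, laterality indices,
stimulation outcomes) ship as fixtures.

## Task arm: GLM

The design matrix contains the SG and TL boxcars convolved with the
canonical double-gamma HRF (response gamma peaking at 6 s, undershoot gamma
at 16 s scaled by 1/6, sampled over 32 s, peak-normalised), a discrete-
cosine drift basis with all frequencies below 1/128 Hz, and an intercept;
no global-signal regressor. Runs discard their first 3 volumes. Voxel-wise
OLS yields `beta` maps and the SG > TL t contrast,
`t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)`. Voxels whose residual variance
is numerically zero (constant time courses, noise-free simulations) have no
defined t and are removed from the map's mask rather than reported as huge.

Two thresholding families are provided. Voxel-level FWE uses Bonferroni
across in-mask voxels — conservative and assumption-light, in place of
random-field theory, whose smoothness-estimation machinery is out of scope;
users comparing against SPM should expect slightly stricter cutoffs.
Cluster-level FDR forms clusters at an uncorrected voxel p (default .001,
26-connectivity) and applies Benjamini-Hochberg over cluster-extent
p-values drawn from a permutation null (residual time permutation for GLM
fits, sign-flipping of paired differences for second-order maps; default
500 permutations, seeded).

A note on the high-pass: a finite-window DCT filter attenuates but does not
annihilate drifts near its cutoff, and sine-phased slow drifts leave
boundary residuals of a few percent. The tests assert what the filter
actually guarantees — under 1% amplitude residual for slow (600-s)
cosine-type drift and at least 99% variance removal for any phase at
periods of 300 s and above. Prewhitening (AR(1)) is not modelled; the
generator's noise is white, and this is a documented limitation for real
data. Multiple task sessions are pooled as fixed effects
(`t_contrast_pooled()`): per-session effects averaged, variances summed,
degrees of freedom added.

## Rest arm: spatial ICA

The decomposition is spatial: voxels are the realisations, every component
is a spatial map mutually independent of the others over voxels, and each
map has a single time course (the mixing column). This orientation is fixed
in code because transposing it is a classic implementation bug. The
pipeline is: discard, smooth, band-pass to 0.01-0.1 Hz, PCA-whiten the
temporal dimension, run extended Infomax (natural-gradient entropy
maximisation; the kurtosis-switching nonlinearity of Lee, Girolami and
Sejnowski, robust to sub-Gaussian sources and toggleable to the strict
logistic rule), z-score each map over the mask, and fix each component's
sign so its spatial skewness is non-negative — making "activation" positive
so that the conventional z = 2 component threshold is meaningful.
`n_components` defaults to 55 to mirror the clinical protocol, but is
validated against the temporal rank of the data; desk-scale simulations use
10-20.

Component identification replaces the clinical two-rater consensus with a
deterministic rule engine over an explicit sphere atlas (12-mm radii;
centres from the published group peak tables where available, literature-
conventional otherwise, all recorded in the shipped YAML). LANGrest
requires peaks in MTG, IFG and ANG (either hemisphere); the ventral
attention network (VAN) — its main false-positive risk — requires
supramarginal/TPJ and IFG peaks and is vetoed by a dominant angular-gyrus
peak, encoding the ANG-vs-SMG discriminator; the salience network needs
dACC, posterior pre-SMA and anterior insula/frontal operculum; DAN needs
IPS and FEF; the left fronto-parietal control network needs DLPFC and
anterior OFC and is vetoed by dominant MTG activity. Peaks feeding the
rules are identified at z = 3 — stricter than the z = 2 visual threshold —
because peak identification proceeds by further thresholding at higher z,
which suppresses spurious noise maxima. Rule evaluation is deterministic;
ties break by summed matched-peak z, then by the fixed order LANG, VAN, SN,
DAN, lFPC; `report = TRUE` emits the per-rule evidence so a human can audit
the choice, mirroring the rater review.

## Laterality and concordance

The lateralization index is mass-based:
`LI = 100 (R - L) / (R + L)` over suprathreshold statistic mass outside a
5-mm midline strip. Positive values mean RIGHT-hemisphere dominance — the
convention of the shipped laterality table (and of the Edinburgh handedness
scale), and the opposite of the common LI-toolbox convention. The
bootstrapped/threshold-free LI curve is out of scope; mass LI is its
deterministic core. Dominance classification is sign-only by default; an
optional `bilateral_band` treats small |LI| as bilateral, since the
clinical cutoff is not published.

Concordance: each CM-positive stimulation site is one unit; a modality
detects it when a peak lies within 10 mm (coordinate mode) or inside the
site's atlas region (label mode, used for the fixture, which records sites
as region labels — the only machine-checkable form of the published
outcome table). Sensitivity is 100 x detected/total sites. The shipped
fixture has 31 patients with an induced language disturbance contributing
32 sites (one patient has two); 11 sites are flagged rest-only, giving
21/32 = 65.6% task sensitivity and 32/32 = 100% rest sensitivity.
Site-level counting is used because it is the only reading that reproduces
both published percentages simultaneously. Specificity is not estimable
from this design and is not attempted.

## The synthetic generator: what it emulates and what it does not

Networks are sums of isotropic Gaussian nodes (`amplitude` is the peak
height, `sigma` the spatial scale). Rest runs are
`sum_k map_k (x) s_k(t) + noise`: each network modulated by an independent
band-limited (0.01-0.1 Hz) time course built from Laplacian innovations
(unit variance, non-zero excess kurtosis), plus white Gaussian voxel noise.
Task runs are `effect_size * map (x) (SG boxcar * HRF) + drift + noise`
with a seeded random cubic polynomial drift. Acquisition defaults follow
the clinical protocol: TR 2.28 s, 270 volumes, 16-s epochs, 3 discarded
volumes, 6-mm FWHM at 3-mm resolution, z = 2, FWE .05, 128-s high-pass,
10-mm concordance radius. Every generator is a pure function of its
arguments including the seed.

The generator does not model physiological (cardiac/respiratory) noise,
head motion, susceptibility distortion, autocorrelated noise, or
lesion-induced neurovascular uncoupling. Passing recovery tests therefore
demonstrate the correctness of the analysis chain on data satisfying its
assumptions, not its robustness to everything real patient data contain.

### Problem sizes and the two desk-scale grids

Two deliberately small grids keep the validation suite tractable:

* `demo_grid()` — 20x20x20 voxels at 8 mm, anchored in MNI space so that
  the real template coordinates (e.g. the MTG node at -63, -28, -9) are
  usable. The end-to-end demonstration (`run_demo()`) runs here: 150
  volumes, 6 planted networks, ICA at 20 components, smoothing at 16 mm =
  2 voxels (the same kernel-to-voxel ratio as the protocol's 6 mm on 3-mm
  voxels), noise SD 0.5.
* `validation_grid()` — 20x20x20 voxels at the study resolution of 3 mm,
  abstract (not anatomical), used for quantitative source recovery with the
  six 3-node `validation_templates()` (sigma 6 mm), 150 volumes, noise SD
  1, 8-mm smoothing, 10 components.

Why two grids? Quantitative ICA recovery at amplitude = noise = 1 needs two
things at once: smoothing that meaningfully suppresses voxel noise (kernel
clearly above voxel size, hence 3-mm voxels) and spatial maps with high
excess kurtosis (sparse, compact nodes relative to the mask — this, not raw
energy, is what Infomax identifiability rests on; the same nodes widened to
sigma 10-12 mm on the small box blur into near-Gaussian marginals that no
ICA, ours or any reference implementation, can separate). The MNI-anchored
demonstration grid cannot satisfy the first condition (8-mm voxels are
needed to fit the brain into a 20-cube), so it is used for what it is good
at — anatomy-dependent classification, selection, laterality and
concordance — while the recovery numbers come from the validation grid.
Network nodes in the shipped MNI templates use sigma 12 mm, a realistic
node scale given published language-network cluster extents of several
thousand 3-mm voxels.

## Numerical choices

* Coordinates are RAS+ MNI millimetres; the affine follows NIfTI sform
  semantics (0-based voxel indices, voxel centres); R-facing indices are
  1-based. The default 3-mm grid spans [-78, 78] x [-112, 76] x [-50, 103]
  (53 x 63 x 52 voxels) with an ellipsoidal default mask (semi-axes 1.1 x
  the half-extents) — the exact clinical bounding box is not published, so
  this is a stand-in.
* Smoothing uses mask-renormalised separable convolution, so constants are
  preserved up to the mask edge and compactly supported mass is conserved
  away from it.
* Peak extraction: 26-connected local maxima strictly above threshold,
  greedy suppression closer than 8 mm (the common peak-table convention; no
  published value).
* Infomax: random orthonormal start (seeded), learning rate 0.1 halved on
  overshoot, convergence when the relative weight update falls below 1e-7,
  warning (with diagnostics) rather than failure at `max_iter`. Recovered
  sources are rescaled to unit variance; components are ordered by
  explained variance.
* Ties everywhere break deterministically (descending value, then lower
  index), so identical seeds give bitwise-identical outputs.
* Histology grouping follows the published categories, including DNET under
  the nontumoral lesions. The grade split computed from the table (33
  high-grade, 9 low-grade among 42 glial tumours) does not match the
  published 32/10 exactly and is reported as computed.

## Known limitations

Bonferroni FWE is stricter than random-field FWE at matched alpha; the
permutation cluster null assumes exchangeable residuals; no AR modelling;
the rule engine is only as good as its sphere geometry (VAN/DAN/lFPC
coordinates are conventions, not published values); the LI dominance cutoff
for "bilateral" is a user choice; and simulated data omit the noise
structure of real acquisitions. The rsfMRI-vs-ECS sensitivity of 100%
reproduced from the fixture is a transcription of published outcomes, not
new evidence.
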