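---
title: "Models and methods: lamina-resolved plaque quantification on synthetic hippocampal cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In amyloid mouse models, plaque burden is not uniform across the hippocampus:
it differs between subfields (CA1, CA2/3, dentate gyrus) and between the
laminae of each subfield (stratum oriens, pyramidale, radiatum,
lacunosum-moleculare; molecular layer, granule layer, hilus). Quantifying
burden at this resolution from immunofluorescence sections is usually a
semi-manual ImageJ workflow: segment layers on a VGLUT1 stain, separate CA1
from CA2/3 on a WFS1 stain, build an amyloid mask from the 6E10 channel with
an automatic Triangle threshold and a particle-size filter, then measure the
mask's area fraction inside each region of interest. A companion experiment
counts immunopositive somata per marker channel and reports directional
overlap percentages (e.g. the fraction of APP-positive interneurons that are
Reelin-positive).

`laminaq` re-implements that workflow as deterministic, testable code, and
pairs it with a synthetic image generator that plants known ground truth.
Because no raw microscopy from the original study is available, *parameter
recovery on synthetic cohorts* is the package's form of validation: every
stage (segmentation, plaque masking, measurement, statistics) is judged by
whether it recovers what the generator planted.

# The synthetic generator

## Geometry

A section is a schematic stack of curved laminar bands: the four CA bands
(SO, SP, SR, SLM, outer side first) sitting on the three DG bands (MO, SG,
hilus), mirroring the apposition of SLM and the DG molecular layer in a real
coronal section. CA bands are split into CA1 (left) and CA2/3 (right) at a
configurable fraction of the tissue width. The geometry is deliberately
schematic rather than atlas-warped: every downstream measurement depends
only on region membership of pixels, not on anatomical shape, so a curved
band stack exercises the identical code paths at a fraction of the
complexity.

The packaged cohort geometry is a 1024 px square at 0.65 µm/px (≈ 666 µm of
tissue) with band thicknesses SO 60, SP 70, SR 110, SLM 85, MO 90, SG 50,
H 70 µm. The pixel size is a compromise chosen once: fine enough that the
10 µm² particle cutoff spans ~24 pixels (so the size filter is genuinely
resolved), coarse enough that an entire 11-region schematic fits in one
image with per-region plaque counts large enough for stable recovery at
n = 8 animals per arm. It is configurable everywhere.

## Channels and noise

Three structural channels are rendered: a VGLUT1-like channel (bright
neuropil, dark cell-body bands, ≥ 3:1 contrast before noise), a WFS1-like
channel elevated only over CA1, and an Aβ/6E10-like channel carrying the
plaque field. Plaques are a Poisson process per region — counts ~
Poisson(area × density × age-scaling × per-animal multiplier), centres
uniform over the region, radii log-normal (meanlog log 2.6 µm, sdlog 0.4).
Those radius defaults put ~17 % of plaques below the 10 µm² cutoff, so the
strict `> 10 µm²` rule always has work to do. Noise is additive Gaussian
read noise (σ = 6) plus an intensity-scaled Gaussian standing in for shot
noise (σ = 0.6·√I), quantized to 8-bit as the original workflow's TIFF
exports were. The background level (25) keeps the noise floor clear of the
quantization clip so channel histograms stay unimodal around their modes.
Plaque and soma footprints are rendered with hard edges; a point-spread blur
is deliberately out of scope, which means thresholding here is easier than
on real microscopy — passing recovery tests shows the pipeline is correct,
not that it is robust to every optical artefact.

## Planted effects and calibration

The two-arm experiment (control vs GABAergic-BACE1-cKO) multiplies each
region's density by a ratio in [0, 1]. The study-level targets are
*aggregate* reductions — 31 % whole hippocampus, 24 % CA1, 75 % SP of CA1,
50 % DG, 50 % MO — which are emergent mixtures of per-lamina ratios weighted
by area × density, additionally blurred by plaques straddling lamina
boundaries (pixel-wise attribution) and by plaque overlap. `calibrate_ratios()`
solves for the ratios exactly under that measurement model: the expected
coverage field is the FFT convolution of the per-region density map with the
radius survival kernel P(R > d); the Boolean-model correction 1 − exp(−µ)
accounts for overlap; a damped Newton iteration makes the five expected
*measured* aggregate reductions equal the targets. Laminae are tied into
five groups (SP of CA1; other CA1 laminae; CA2/3; MO; SG+H) so the system
is square. The calibration is deterministic and cached per session.

Arms are generated as matched pairs by common random numbers: the cKO plaque
field of animal *i* is a per-region binomial thinning of the same animal's
control field. Thinning a Poisson process is again a Poisson process at the
thinned rate, so each arm is marginally faithful; pairing only removes
between-animal sampling noise from the *difference*, the standard
variance-reduction design for recovery benchmarks. The generator also
supports fully independent arms (`paired = FALSE`), which the
null-calibration study uses, since the type-I behaviour of the
independent-samples tests is only defined for independent arms.

## Cells and marker tables

Somata are placed by a hard-core (dart-throwing) process — minimum
separation 10 µm, one soma diameter plus a guard band so that pixelized
discs never touch within a channel — in
five CA1 scopes: the SR/SLM border band (± 20 µm around the SR–SLM
boundary), SO, SP, and the SR and SLM interiors. The reference experiment
reports *directional* conditionals both ways (e.g. P(Reelin | APP+) and
P(APP+ | Reelin)); a consistent joint distribution is parameterized per
scope by the APP+ base rate `a`, and per marker by q = P(M | APP+) together
with the target c = P(APP+ | M), from which P(M | APP−) = a·q·(1−c)/(c·(1−a))
follows. Pairs that would need a probability above one are rejected at
config load. P(APP | CCK) is planted at 0.95 in every scope so the pooled
conditional is exactly 0.95 regardless of scope weights; GABA_B_R1 is forced
(q = 1) wherever APP is positive. Placement weights make the APP+ population
split 60/20/2/8/10 over border/SO/SP/SR/SLM. The border width (20 µm) is a
definition the package owns: the reference treats "the border" as a place
but never defines its extent.

ELISA-style Aβ42 concentrations are log-normal with configured mean and CV
(default CV 0.10, control mean 50 pg/mg, cKO mean 17 % lower). With n = 12
per arm this reproduces a reduction SEM of ≈ 3 points, matching the
precision the reference reports; the absolute scale is arbitrary since every
downstream statistic is scale-invariant.

# The measurement pipeline

**Hippocampus delineation.** A first threshold (Otsu by default, fixed value
to mimic manual thresholding) separates bright neuropil from everything
darker; a second Otsu pass restricted to the sub-threshold intensities finds
the floor between true background and the dark cell-body bands. Pixels above
the floor are tissue, so SP/SG belong to the mask from the start; the mask
is the largest 8-connected component, lightly closed (4 µm) and hole-filled.
Selecting the component before closing matters: closing first would let
supra-floor background speckle percolate into the mask.

**Cell-body bands.** Within the mask, a second threshold (Otsu on the
interior histogram) separates the dark SP/SG bands from neuropil. The search
runs in a slightly eroded core — the mask boundary carries a one-to-two
pixel fringe of background-level intensities that would otherwise bridge the
two bands — and each accepted band is then grown back through the raw dark
mask so its tips reach the tissue boundary. Components below 2000 µm² are
discarded. SP is the band overlapping the WFS1-high territory; if the WFS1
contrast between candidates is below 1.2× the assignment is refused rather
than guessed.

**Laminar partition.** Tissue nearer SP than SG (in the normalized sense
d(SP)/(d(SP)+d(SG)) < 0.68, the CA-side share of typical band proportions)
is CA, the rest DG. On the CA side, the non-SP component farther from SG
than SP itself is SO; the other is SR+SLM, split at a configurable fraction
(default 0.56) of the normalized distance from SP to the DG side — the
reference drew this boundary by hand, so the fraction is an explicit,
documented knob rather than a hidden heuristic. On the DG side the component
nearer CA is MO, the farther one the hilus. Imported region files (label
TIFF or polygon JSON, even-odd pixel-centre rule) bypass all of this
verbatim.

**Subfield split.** The per-column mean WFS1 profile over the CA territory
is smoothed (7-column running mean) and thresholded; the single change point
minimizing misclassification against a step function defines the CA1/CA2-3
boundary, CA1 on the WFS1-high side. A numerically constant profile yields
the whole CA on one side plus a warning.

**Plaque mask.** The Aβ channel histogram (256 bins; integer 0–255 data is
binned as-is, anything else linearly rescaled — rescaling integer data would
scatter empty gap bins through the histogram and distort the Triangle
geometry) is thresholded by the Zack/ImageJ Triangle rule: peak, longer tail
(ties to the right), line from (peak, height) to (tail end, 0), threshold at
the bin of maximum perpendicular distance, ties toward the peak, mirrored
back if the histogram was flipped. Foreground components are 8-connected
(ImageJ particle convention); particles survive only if strictly larger
than 10 µm²; border-touching particles are retained. An implementation-
independent brute-force oracle (explicit point-to-line distances, exhaustive
scan) guards the Triangle rule in the test suite.

**Measurement.** Region area = label pixel count × pixel area; plaque area =
mask∩region pixel count × pixel area; area fraction = their ratio × 100.
Aggregates (CA1, CA2/3, DG, hippocampus) pool pixels — they are never means
of per-lamina fractions — so lamina areas sum exactly to subfield areas and
plaque areas are additive by construction. A particle overlapping two
regions contributes its pixels to each separately, matching the mask∩ROI
semantics of the original workflow.

**Colocalization.** Each marker channel is thresholded (fixed 90 by default
— the reference thresholded manually, and Otsu is unreliable when a marker's
foreground is a fraction of a percent of pixels), 8-connected components in
a 20–300 µm² soma window become detections with intensity-weighted
centroids. Detections from different channels are the same cell when their
masks overlap with Dice ≥ 0.5, matched greedily by descending Dice,
one-to-one per channel pair — symmetric and order-invariant. Cells take the
lamina under their centroid; the border scope collects cells within 20 µm of
the SR–SLM boundary. Directional percentages are 100·n(A⁺B⁺)/n(A⁺), with an
empty A-population flagged undefined rather than reported as zero. Counts
are pooled across sections before percentages, as the reference pooled
cells across sections and animals.

# Group statistics

Percent reduction is defined on arm means, 100·(1 − mean(cKO)/mean(control)):
arms are independent animals and no pairing exists in the *analysis* design.
Its SEM propagates the two arm SEMs through the ratio to first order
(delta method), cross-checked against a parametric bootstrap in the tests;
the reference never states how its ± values were computed, so the delta
method is this package's documented choice. The arm × region comparison is a
classical two-way ANOVA with interaction on untransformed area fractions
(the reference reports raw percent area; a log option exists but is off by
default), the ELISA comparison a pooled-variance Student t, the time course
a per-region one-way ANOVA across ages. No multiple-testing correction is
applied across regions, matching the reference's per-region stars. All of
these are scale-invariant, which the suite asserts.

One calibration subtlety: with mouse-to-mouse variability (the per-animal
density multiplier, CV 0.15 by default) observations within an animal are
correlated across regions — a repeated-measures layout. The classical
two-way ANOVA ignores that and its arm test is anti-conservative under such
a generator, exactly as it is for the real experiment it mimics. The
null-calibration study therefore runs with the animal random effect off
(`animal_cv = 0`) and independent arms, isolating the test's own sampling
assumptions; under those conditions arm p-values are uniform and the type-I
rate sits at the nominal 5 %. This limitation is inherited from the
reference analysis, not introduced here; a mixed model is an explicit
non-goal.

# Problem sizes and replication choices

The recovery experiment uses 8 animals per arm at 1024² px — the reference's
own n — and one section per animal. The ELISA study uses 500 replicate
12-vs-12 comparisons. Colocalization pools CA1-only sections (768×1024 px)
until ≥ 1000 APP⁺ cells are recovered (~17 sections, ~3500 cells). The
replicate-heavy calibration studies (null uniformity, power) use the
measurement-level fast path `simulate_measurements()` — the identical
Poisson / log-normal-size / strict-filter model minus rendering — whose
agreement with the raster path is itself a test. Unit tests run the same
geometry at half resolution (1.3 µm/px); resolution is a pure scale
parameter throughout.

# Known limitations

- The geometry is schematic; nothing is learned about atlas registration or
  anatomically realistic curvature.
- Hard-edged discs and Gaussian noise understate the difficulty of real
  thresholding (no PSF, no uneven illumination, no autofluorescence).
- The SR–SLM boundary fraction and the 20 µm border width are definitions,
  not measurements; results quoted per those scopes inherit them.
- The ANOVA's repeated-measures blindness, above.
- ELISA simulation is statistical only: no plate chemistry, standard curves
  or extraction yields.
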