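---
title: "Quantifying nanopillar surfaces: models, estimators and design choices"
author: "nanopillar package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanopillar surfaces: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopillar)
```

# Scope

Black-silicon (bSi) surfaces etched into dense forests of nanopillars kill
bacteria mechanically, and how well they do so depends on fine details of
the nanotopography: tip density, pillar height, and the short-range spatial
order of the tips. This package implements the computational side of that
characterization: detecting pillar tips in calibrated micrographs with a
small neural network, summarizing their spatial arrangement with the
pair-correlation function and neighbour-count distributions, extracting the
same characteristic length scale independently from tiled Fourier spectra,
reducing height maps to standard roughness and bearing-curve metrology, and
converting paired plate counts into bactericidal efficiencies. A
synthetic-data generator with known ground truth ties everything together:
every estimator in the package is validated against data whose true
parameters are known by construction.

This vignette explains the models behind each module, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic validation does and does not demonstrate about real micrographs.

# The synthetic surface model

`generatePattern()` draws tip positions on a rectangular field (nm units
throughout). Three ingredients mirror what etched pillar forests look like
in top view:

* **Hard core.** Each pillar excludes others from a disc of radius
  `exclusionRadius` (default study value 150 nm): mechanically, two pillars
  cannot stand closer than roughly a tip width, and closer pairs lean into
  bundles that top-view detection sees as one object. Placement is dart
  throwing (sequential rejection); a density beyond the hexagonal packing
  bound $2/(\sqrt{3}d^2)$ aborts with an error naming that bound.
* **Short-range order.** Real pillar spacings concentrate around a
  characteristic distance (~300–400 nm) without long-range order. When
  `spacing` is set, an iterative soft-disc repulsion with interaction
  radius equal to `spacing` relaxes the pattern: every pair closer than the
  target pushes apart until neighbours sit near the target distance or the
  pattern jams. This produces a liquid-like structure whose g(R) first
  peak falls at approximately `spacing`. The alternative of Lloyd
  (centroidal Voronoi) relaxation orders the pattern toward the density's
  own natural spacing ($\approx 340$ nm at 10 tips/µm²) rather than a
  prescribed one, so the soft-disc form was chosen: it honours the
  prescribed characteristic distance.
* **Jitter and bundling.** Gaussian positional jitter (`jitterSd`) broadens
  the order realistically — with ~35–50 nm of jitter the first g(R) peak
  has height ≈ 1.4–1.9, typical of the liquid-like order seen on etched
  surfaces, instead of the sharp near-crystalline peak a fully jammed
  pattern shows. With probability `bundleProb`, tip pairs closer than 1.5
  hard-core radii merge into their midpoint, mimicking pillar bundles
  recorded as single objects. The hard core is re-enforced afterwards, so
  the returned pattern always satisfies the exclusion constraint exactly.

The tip count is Poisson with mean density × area, so realized densities
scatter around the nominal value exactly as a stationary point process
would. All randomness flows from one integer seed per call; the pipeline
derives per-stage sub-seeds deterministically from a master seed and the
surface label, in that documented order.

`renderMicrograph()` draws one isotropic Gaussian blob per tip (FWHM =
`tipWidth`, default 110 nm) on a uniform background with additive Gaussian
read noise, clipped to the 8-bit gray range — enough realism to exercise
detection and spectral analysis against ground truth. It is deliberately
*not* a physical SEM model: no charging, edge brightening, tilt projection,
or the internal pillar structure a real secondary-electron image contains.
`generateHeightMap()` composes smooth pillar bumps by maximum, so each
summit equals its drawn height (Normal with the configured mean/SD,
truncated at 0) on a zero baseline. `generateViability()` simulates paired
control/surface colony counts with multiplicative counting noise around a
known kill fraction.

# The tip detector

The classifier is a fully connected 432–24–2 multilayer perceptron with
logistic activations in both layers: a 12 × 12 pixel patch enters as three
identical colour channels (grayscale sources replicate the channel), 24
hidden units, and two outputs for the classes E (empty space) and P
(pillar tip) with target signals [1, 0] and [0, 1]. Training is classic
on-line back-propagation of the squared-error loss: one weight update per
patch presentation, patches reshuffled every epoch. The defaults that the
original recipe leaves open are fixed here for reproducibility: learning
rate 0.1, weights initialized Uniform(−0.5, 0.5) from a seed, and patch
intensities normalized to [0, 1] by the global image min–max (the scanner
applies the same normalization). The analytic gradients are verified in the
test suite against central finite differences to 10⁻⁵ relative error.

Training data come from 7 patches per class cut from a reference image,
expanded 72-fold by 24 equidistant rotations at scales 0.90/1.00/1.10
(504 patches per class). Rotation/rescale resampling is bilinear with
mirror reflection beyond the patch borders; rotation by 0° at scale 1 is
exactly the identity, and rotational invariance holds on the inscribed
disc of the patch (the corners of a rotated square necessarily sample
padding, so corner pixels are reflection artefacts by construction).

The nominal recipe trains for 2000 epochs over the augmented set. On the
well-separated synthetic patches the loss curve is flat long before that,
so this package's own validation runs use 200 epochs (tests) — a problem
size chosen because held-out accuracy is already at 100% there; nothing in
the method depends on the larger count.

`scanMicrograph()` forward-passes every 12 × 12 window on a stride grid
(default stride 2 px) and records the P-output activation; because the
three input channels are identical for grayscale images, the three channel
blocks of the input weight matrix collapse into one effective 144-column
matrix, which makes scanning a single matrix product per window block.
`detectTips()` takes local maxima (8-neighbourhood, ties kept) above a
threshold (default 0.5, the natural decision boundary of a logistic output;
the original workflow does not state one) and greedily prunes detections
closer than `minSeparation` (default 100 nm ≈ one tip width, mirroring
bundle merging) keeping the higher response. Ties between the two output
neurons classify as E — the conservative choice that avoids false tips.

On synthetic renders at 11 tips/µm² the full chain (sample, augment, train,
scan, detect) recovers tip positions with F1 ≥ 0.9 at a one-tip-width
matching radius and densities within the ±4 tips/µm² scatter printed for
the real surfaces.

# Pair-correlation function

For a stationary point pattern with density $\rho_0$, the pair-correlation
function is $g(R) = \rho(R)/\rho_0$, where $\rho(R)$ is the mean density of
other tips at distance $R$ from a typical tip; $g = 1$ for complete spatial
randomness (CSR), 0 inside an excluded area, and > 1 at preferred spacings.
The estimator bins ordered tip pairs into annuli (default width 20 nm up to
1000 nm) and divides by $n\,\rho_0$ times the annulus area, with
$\rho_0 = n/|A|$.

Because fields of view are small (tens of µm at most), edge correction is
mandatory: a pair at distance $R$ near the border would be under-counted.
Each pair is weighted by the Ripley isotropic factor — the reciprocal of
the fraction of the circle of radius $R$ around the first tip that lies
inside the field. The closed-form fraction for rectangles (valid for
$R \le \min(W,H)/2$, which the estimator enforces) is cross-checked in the
tests against a numeric circle-sampling oracle, and binned pair counts are
checked to equal brute-force enumeration exactly. For CSR input the
estimator normalizes to 1 within Monte-Carlo error; for hard-core input it
is exactly 0 below the exclusion radius.

`firstPeak()` reports the first local maximum above 1 beyond `minR`
(default 100 nm, excluding the excluded-area zone), refined by a parabola
through the maximal bin and its neighbours. A monotone or sub-unity curve
yields an explicit "no peak" result. The default bin width resolves a
~306 nm peak while keeping ≥ 10 pairs per bin at realistic densities.

`neighborDistribution()` counts, for interior tips only (at least one
cutoff from every edge — conservative minus-sampling, so no correction
factors are needed), the other tips within `cutoff` (default 500 nm, the
span of the first peak). Denser surfaces shift this distribution to larger
counts; `compareNeighborDistributions()` reports the mean shift and a
first-order stochastic dominance flag.

# Tiled Fourier spectra

`tiledFFT()` averages magnitude spectra over square tiles (default
512 × 512 px) cut on a stride grid (default 100 px, partial tiles
discarded, anchored at the top-left corner). Averaging displaced tiles of a
stationary texture suppresses spectral variance while preserving the
isotropic "halo" ring that a characteristic spacing without orientational
order produces. Magnitude rather than power is averaged, matching the
typical FFT display output of image-analysis workflows; no apodization is
applied by default (a Hann option exists) since tile-edge leakage only
contributes a low-q skirt that the halo search excludes anyway. The DC bin
of the displayed spectrum is replaced by the mean of its neighbours — a
display convention; the original value is retained in the object and the
per-tile Parseval identity is covered by a test.

`radialSpectrum()` averages over annuli of constant wave number, with the
$2\pi$ convention $q = 2\pi f/\text{pixelSize}$ ($f$ in cycles/px), and
`haloPeak()` locates the magnitude maximum beyond `qMin` (default excludes
the low-q envelope) with parabolic refinement. `qToR()`/`RToQ()` convert
via $R = 2\pi/q$: this convention is fixed because it reproduces the
pairing of a 306 nm real-space spacing with $q \approx 0.0205$ nm⁻¹ that
the source measurements print. Under the same convention the printed
window $q \in [0.016, 0.021]$ corresponds to 299–393 nm, so the printed
lower bound of the "330–390 nm" scale range is not exactly consistent;
the convention is documented rather than silently reconciled.

**A caveat the validation makes explicit.** For a point pattern whose
first-neighbour shell sits at distance $d$, scattering theory puts the
first structure-factor peak near $q \approx 7/d$, about 10–15% above
$2\pi/d$ (a perfect hexagonal lattice at 10 tips/µm² already has its first
reciprocal peak at 0.0213 nm⁻¹). Direct structure-factor computations on
the generated patterns confirm this: a 306-nm-spaced synthetic pattern has
its halo at $q \approx 0.022$ nm⁻¹, just above the printed
$[0.016, 0.021]$ window, while its g(R) peak recovers 306 nm exactly as
intended. Real SEM images additionally contain projected pillar-body
structure at scales above the tip spacing, which pushes measured halos
toward lower q; the deliberately minimal dot renderer omits that. The
corresponding acceptance check is therefore expected to sit marginally
outside the printed window, and this is a property of the idealized
synthetic imagery, not of the spectral estimator (which recovers
constructed sinusoid and ring wave numbers to sub-bin accuracy in the
tests).

# Surface metrology

`roughness()` implements the areal definitions
$R_a = \langle|h-\bar h|\rangle$ and
$R_q = \sqrt{\langle(h-\bar h)^2\rangle}$ (whether the source AFM analysis
used line-wise or area-wise definitions is unstated; area-wise is the
modern ISO 25178 choice). $R_q \ge R_a$ always; a constant map gives
(0, 0) rather than an error. An optional first-order plane subtraction is
off by default because synthetic maps are already level.

`bearingCurve()` is the Abbott–Firestone exceedance curve: for levels
descending from the summit, the fraction of the area at or above the
level. One extra level just above the summit anchors the curve at 0, and
it reaches 1 at the lowest point; for a pillar forest it rises as the
level drops through the pillar tops and plateaus below their bases, at a
depth set by the pillar height.

`aspectRatio()` is height divided by tip width. The printed geometry
tables do not define their aspect ratio, but height/tip-width reproduces
all three printed values (8.4, 6.0, 8.8) from the printed means within
±0.05, so that definition is adopted and the reproduction is a unit test.

# Bactericidal efficiency

`bactericidalEfficiency()` converts paired control/surface CFU counts into
cells inactivated per cm² per minute:
$(\text{control} - \text{surface}) \cdot \text{dilution} / (\text{area}
\times \text{time})$ per replicate, summarized as mean ± SEM with a
two-tailed paired Student t test (via `stats::t.test`). Negative
per-replicate efficiencies (surface > control) are retained and flagged
rather than truncated, because truncation would bias the mean upward. Two
degenerate cases are fixed by documented convention: identical inputs give
t = 0, p = 1 (no evidence of a difference), while a constant non-zero
difference is reported as an error result (zero-variance differences make
the statistic undefined). The conventional significance direction
(p < 0.05 significant) is used. Over 200 simulated replicate sets the
estimator recovers the generator's true kill rate within two standard
errors, i.e. without detectable bias.

# Pipeline determinism and problem sizes

`runPipeline()` validates its JSON/list config strictly (unknown keys are
rejected), requires an explicit master seed, and derives one sub-seed per
surface and stage, so a config reproduces its report byte-for-byte;
timestamps live only in the run log. Artifacts (tips CSV, PNG render,
g(R) CSV, report JSON) are written per surface when an output directory is
given, and the config hash is stamped into every report.

Validation problem sizes were chosen so the whole suite runs in minutes:
10 × 10 µm fields (~1000 tips) for spatial statistics, 15 × 15 µm
(~2250 tips) for the CSR normalization check, 5 × 5 µm renders at
10 nm/px with 200 training epochs for the detector chain, and 200
replicate sets for the efficiency bias check. The pixel size of the
synthetic micrographs (10 nm/px) is a free calibration parameter — the
source imaging magnification does not fix one — chosen so a 110 nm tip
spans ~11 px, comfortably above the 3-px resolvability guard.

# What passing tests do and do not show

The synthetic generator reproduces the *statistical* structure of etched
nanopillar surfaces: hard-core exclusion, liquid-like short-range order at
a prescribed spacing, realistic densities, Gaussian-blob tips and noisy
backgrounds. Passing the suite therefore shows the estimators are correct
and the detection chain works on imagery of that structure. It does not
show robustness to what real SEM adds — charging gradients, edge
brightening, focus drift, tilted projections of pillar bodies, bundling
geometries more complex than midpoint merging — nor does it validate the
absolute roughness values of real AFM scans, which depend on instrument
artefacts the height-map generator does not model. The headline biological
numbers of any particular study (dead-cell percentages, printed
efficiencies) derive from raw images and plate counts that are not
published; only the estimators, not those exact values, are reproducible.
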