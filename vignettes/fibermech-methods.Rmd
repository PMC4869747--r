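---
title: "Quantifying stress-fiber amount, architecture and cell stiffness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stress-fiber amount, architecture and cell stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibermech)
```

# Overview

`fibermech` implements a combined analysis for living adherent cells that
were imaged by epifluorescence (GFP-tagged cytoskeletal proteins) and
probed by atomic force microscopy (AFM) at the same time.  It has three
layers:

1. **Image quantification** — segment stress fibers with an oriented
   filter bank, refine the binary fiber map, separate fiber fluorescence
   from the unbound-monomer background, and summarize each cell by the
   amount of protein in filamentous form and by three architecture
   descriptors (alignment, apparent thickness, radial location).
2. **Force-curve analysis** — fit force-indentation ramps with a
   bottom-effect cone correction (BECC) that stays valid on thin regions
   of a cell above a rigid substrate, locate the contact point, derive
   the local sample height, and pool per-cell stiffness.
3. **Statistics** — linear stiffness-versus-amount models on binned
   cells, analysis of covariance between cohorts, and a normalized
   architecture-modulation model selected by nested F-tests.

Because real instrument data cannot ship with a package, `fibermech`
includes synthetic generators for both data types with exact ground
truth; every stage is validated against them.

# Image quantification

## Fiber segmentation

The segmenter convolves the image with a bank of *elongated
Laplace-of-Gaussian* (eLoG) kernels: the sign-flipped Laplacian of an
anisotropic Gaussian, rotated in $\pi/30$ steps ($n = 30$ kernels, 6°
apart).  A bright line aligned with a kernel's long axis maximizes that
kernel's response, so the per-pixel argmax over the bank gives the local
orientation of fibers (LOF) in $[0°, 180°)$, and the per-pixel maximum
response is thresholded (Otsu's method on the in-cell response
histogram, by default) to give the binary fiber mask.

Kernel shape defaults are $\sigma_\parallel = 6$ px along the fiber axis
and $\sigma_\perp = 1.5$ px across it, with support $6\sigma_\parallel$.
The across-axis scale matches the apparent width of a stress fiber
imaged at 20× with ≈0.5 µm pixels; the along-axis scale buys orientation
selectivity without bridging neighbouring parallel fibers.  All kernels
are exactly zero-mean, which makes the mask invariant to any additive
intensity offset; Otsu's threshold makes it invariant to intensity
scale.

Two intrinsic artifacts of LoG banks are worth knowing.  At the *edge
rows* of a wide bright band the best-responding kernel tilts away from
the true direction by up to two bank steps, because an oblique kernel
crossing the ridge collects more signal there than the aligned kernel
sitting off-axis.  And at *fiber ends* the orientation is genuinely
ill-defined over roughly half a kernel support.  Both effects surface in
the refinement stage (below) as trimmed pixels.

## Refinement

The binary map is refined by iterating two steps to a fixed point:

* **Coherence-enhancing diffusion (CEDF)**: the mask is relaxed to a
  real field and diffused anisotropically, with diffusivity near 1 along
  locally coherent line directions (from the smoothed structure tensor)
  and near 0 elsewhere, then re-binarized at 0.5.  Gaps of 2–3 px along
  a line close; isolated blobs do not spread.  Defaults: gradient scale
  1 px, tensor scale 4 px, 15 steps of $\Delta t = 0.2$ (total diffusion
  time 3 — the time needed to bridge a 2–3 px gap), coherence contrast
  $10^{-6}$ on the unit-amplitude relaxed mask.  The result is returned
  as the union with the input: enhancement only adds pixels.  A pure
  re-binarization would also erode line ends by one pixel per pass, so
  the enhance/trim iteration would creep along fibers instead of
  terminating; making removal the trim's exclusive job guarantees a
  fixed point in practice and keeps the two steps interpretable.
* **Orientation trim**: a fiber pixel is kept only when the mean cosine
  of the axial orientation difference to all other fiber pixels in its
  9×9 neighbourhood exceeds 0.995.  Differences are folded at the
  0°/180° seam (1° and 179° are 2° apart).  Two adjustments make the
  criterion compatible with a 6°-quantized LOF map: differences up to
  one bank step count as perfect alignment (otherwise a single-bin
  disagreement, $\cos 6° = 0.9945 < 0.995$, would reject legitimate
  fiber pixels), and a pixel must see at least 13 fiber neighbours —
  half the count contributed by a minimal 3-px-wide fiber crossing the
  window.  The neighbour-count rule is what actually removes isolated
  bright dots: a symmetric bright spot leaves a small (~2×6 px)
  *mutually coherent* argmax remnant that the cosine criterion alone
  cannot reject.  Setting `angle_slack_deg = 0, min_neighbors = 1`
  restores the literal criterion.

The iteration is capped at 50 rounds (with a warning); in practice it
converges in 3–6.

## Background and F-protein map

Unbound GFP monomer fills the cytoplasm, so the background tracks the
local cell thickness, with a dip over the nucleus (which excludes free
GFP-fusion protein).  It is estimated as a per-pixel *masked median*: a
21×21 window median computed from non-fiber pixels only, with windows
clipped at image borders (padding would invent intensities).  A window
with fewer than 10 usable pixels grows by 10 px per side until enough
are available, preserving locality.  Subtracting this map and keeping
positive residuals on fiber pixels gives the F-protein map; its sum is
$F_{GFP}$, the amount of GFP-tagged protein in filamentous form.  The
correction equalizes the measured brightness of identical fibers lying
over thick and thin regions of the cell.

## Calibration to total filamentous protein

With $P_{GFP}$ the cell's total fluorescence and $P_{endo}$ a batch-level
scaling factor for the endogenous pool, equal binding probability of
tagged and untagged monomers gives
$F_{total} = F_{GFP}\,(1 + P_{endo}/P_{GFP})$ and the filamentous
fraction $F_{total}/(P_{endo}+P_{GFP}) = F_{GFP}/P_{GFP}$ (independent
of $P_{endo}$).  $P_{endo}$ is estimated from cells measured in both the
GFP channel and a total-protein dye channel, as the value that makes the
straight-line fit of dye versus $F_{total}$ pass through the origin.
The intercept is monotone in $P_{endo}$ near the root but bends back
toward zero at very large values (where the fit degenerates), so the
implementation brackets the first sign change on a log-spaced grid
before root-finding by bisection.

## Architecture descriptors

* **Fiber alignment** $FA = 1 - \sqrt{\bar C^2 + \bar S^2}$ with
  $\bar C, \bar S$ the means of $\cos\theta_n, \sin\theta_n$ over fiber
  pixels; $\bar\theta = \operatorname{atan2}(\bar S, \bar C)$.  FA near
  0 means aligned fibers.  Computed directly on the orientations in
  $[0°, 180°)$ as published; note that uniformly random axial angles
  then give $1 - 2/\pi \approx 0.363$, not 1.  A `double_angle = TRUE`
  flag provides standard axial statistics on $2\theta$ for users who
  want the conventional behaviour (uniform → 1); the published form is
  the default.
* **Apparent fiber thickness** $FT$: mean F-protein intensity over the
  fiber pixels, scaled by the same $1 + P_{endo}/P_{GFP}$ factor.
* **Radial location** $RL$: the cell footprint is partitioned into
  1-px-thick concentric rings and the mean F-protein intensity per ring
  is computed; $RL$ is the normalized radius (1 = outermost ring) of the
  densest ring.  Rings are the level sets of the Euclidean distance
  transform — equivalent to iterated unit erosion with an exact
  Euclidean disc, and free of the square/diamond metric distortion of
  3×3 structuring elements.  Ties go to the periphery; rings without
  fiber intensity count as zero density so the argmax stays defined.
* **Cell geometry**: area from the pixel count, aspect ratio and major
  axis from the mask's second-moment ellipse.

# Force-curve analysis

The contact model is a cone of half-angle $\theta$ indenting an
incompressible elastic layer of height $h$ bonded to rigid glass:

$$F = \frac{8 E \tan\theta\,\delta^2}{3\pi}\left\{1 +
  1.7795\,\frac{2\tan\theta}{\pi^2}\,\frac{\delta}{h} +
  16\,(1.7795)^2\tan^2\theta\,\frac{\delta^2}{h^2}\right\}$$

with $F = k d$ (cantilever spring constant times deflection),
$\delta = (Z - Z_{CP}) - d$ and $h = Z_{CP} - Z_{glass}$.  Poisson's
ratio 0.5 is baked into the constants.  As $h \to \infty$ the braces
tend to 1 and the classical conical contact force is recovered.

The contact point is found by a sequential search: every sample that
leaves at least 10% of the ramp in contact is tried as $Z_{CP}$; the
modulus enters the model linearly, so $E$ is a closed-form least-squares
estimate per candidate, and the candidate maximizing the $r^2$ of the
fit to the contact segment wins (ties to the shallower contact).  The
winner is then refined continuously between its two flanking samples,
which recovers noiseless synthetic curves essentially exactly.  The
curve baseline (offset and tilt) is removed first using the earliest
quarter of the ramp.  Fits with $r^2 \le 0.75$ are flagged and excluded
from pooling.  Per cell, accepted fits at locations lower than 4 µm are
pooled as *cytoskeleton* and higher than 5 µm as *nuclear region*, each
summarized by its median.

A practical identifiability note: at realistic deflection noise
(≈2 nm), moving $Z_{CP}$ by ±200 nm with a compensating modulus changes
the residual by an order of magnitude less than the noise floor, so
*individual* fitted moduli scatter by tens of percent even though the
estimator is unbiased (the median over repeated curves stays within a
few percent of truth).  This is intrinsic to contact-point-plus-modulus
estimation at this signal-to-noise ratio, and is exactly why the
per-cell value is a median over many locations.

# Statistics

Per-cell records are sorted by filamentous fraction and averaged in
consecutive bins (10 cells for cytoskeletal data, 4 for nuclear-region
data) before fitting $E = E_0 + \alpha\,[F]$ by ordinary least squares.
Cohorts are compared by analysis of covariance on the joint regression:
the slope difference is the F-test of the interaction term, the
intercept difference the F-test of the group offset under a common
slope, with a Scheffé adjustment available for simultaneous comparisons
among more than two fits.

Architecture modulation is modelled on the ratio of measured to
predicted stiffness:

$$E/E_{fit} = a + b\,\frac{FA}{\langle FA\rangle} +
  c\,\frac{FT}{\langle FT\rangle} + d\,\frac{RL}{\langle RL\rangle}$$

with sample-mean normalizers.  All $2^3$ subsets of $\{FA, FT, RL\}$ are
fitted; a subset is admissible when it improves significantly (nested
F-tests at 0.05) on *every* proper subset, and the largest admissible
subset is selected (ties by residual sum of squares).  Cells with a
non-positive predicted $E_{fit}$ are excluded with a warning.

Two consequences of fitted stiffness lines are provided by
`derived_quantities()`: the asymptotic myosin-to-actin fraction ratio at
equal predicted stiffness, $\alpha_{actin}/\alpha_{myosin}$, and the
actin fraction at which the cytoskeletal and nuclear-region predictions
cross, $(E_{0,NR} - E_{0,CSK})/(\alpha_{CSK} - \alpha_{NR})$.

# Synthetic data: what it emulates and what it does not

`render_fiber_image()` composites (i) a smooth background — a
projected-thickness dome, a linear ramp, or a constant — minus a
Gaussian nucleus dip, (ii) straight fibers with Gaussian cross-section
(default $\sigma = 1.5$ px: the diffraction PSF at 20×/0.5 µm-px
convolved with a 0.5–1 µm bundle), (iii) optional round bright-dot
artifacts excluded from the nucleus region, and (iv) Gaussian noise
(default sd 4 AU against fiber peaks of 150 AU), clipped at zero.  The
ground truth (fiber mask at one cross-section sigma, per-pixel
orientation, the painted fiber layer and its sums) is returned with the
image.  `fibers_families()` arranges fibers as parallel families in
disjoint angular sectors — the fan-like domains seen in serum-deprived
fibroblasts; `fibers_annulus()` places a peripheral or central band at a
programmed radius.  The simulated cells are deliberately *favourable*
scenes: straight, well-separated fibers with known width.  Passing the
recovery tests shows the chain is faithful on data satisfying the
method's own premises; it does not certify performance on dense
isotropic meshworks (where crossing fibers violate the
orientation-consistency assumption of the trim step and are removed at
crossings), on curved fibers, or on out-of-focus imagery.

`render_force_curve()` solves the force balance $k d = F(\delta)$ by
bisection at every post-contact piezo position (residuals below
$10^{-9}$ of the force scale) of a 5 µm, 300-sample ramp, and adds
deflection noise and optional baseline offset/tilt.

`synthesize_cohort()` draws per-cell filamentous fractions log-uniformly
(1.5 decades around the published medians: 5.9% actin, 3.4% myosin),
architecture descriptors from truncated normal / log-uniform
distributions around the published means, and stiffness from the linear
model.  The per-cell noise is calibrated so that a binned fit reproduces
a target binned $r^2$
($\sigma^2 = n_{bin}\,\alpha^2\,\mathrm{var}(F)\,(1/r^2 - 1)$);
modulation residuals are likewise calibrated to a target modulation
$r^2$.  Under that faithful calibration two published-scale checks are
*not* attainable and are reported as such by the test suite: the
standardized actin-versus-myosin slope difference is only ≈2.4 (power
≈0.7, not ≥0.9), and the radial-location modulation term's expected
|t| at 100 cells is ≈1.1, so the alignment+location pair cannot be
selected reliably at the 0.05 level — the corresponding single-sample
p-values in the source data (0.02–0.03) were borderline events.

# Numerical choices and degenerate inputs

* Convolution uses reflective padding (no spurious edge ridges); all
  kernels are odd-sized and symmetric.
* A constant image produces an empty fiber mask (guarded against
  numerical round-off), and an empty mask passes through enhancement
  untouched; alignment and thickness on an empty map raise errors
  rather than returning zeros.
* Background windows fully covered by fibers grow until 10 non-fiber
  pixels are available; an image with no non-fiber pixels at all falls
  back to the global median.
* The contact-point search requires 50+ samples, a baseline region, and
  at least `max(10, 0.1 n)` contact samples; a curve that never builds
  force (zero variance) raises "no contact found".
* Radial-location ties (e.g. an all-zero F-protein map) resolve to the
  periphery deterministically.
* Cell masks thinner than two erosion rings, empty cell masks, and
  non-positive $P_{GFP}$ all raise informative errors.

# Problem sizes used by the validation suite

The bundled tests render 320×320 scenes with 30 fibers and 20 bright
dots (three seeds, metrics pooled), 100 noisy force curves for the
Monte-Carlo modulus check, and 200 seeded cohorts of 80–100 cells for
coverage, power and model-selection checks.  These sizes give stable
pass/fail behaviour at sub-minute-to-few-minute runtimes and match the
scale of the experiments the package models (tens of fibers per cell,
hundreds of curves per session, 60–100 cells per cohort).

# Limitations

* The imaging model is 2-D: orientations are in-plane projections, so
  alignment is a lower bound; vertical fiber position is not assessed.
* Only fibrillar structures are measured; dendritic actin layers do not
  segment.
* The BECC geometry is a cone on a bonded incompressible layer;
  spherical or blunt tips and viscoelastic responses are out of scope.
* $P_{endo}$ calibration is batch-specific; it must be re-estimated for
  a different cell line, construct, or imaging configuration.
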