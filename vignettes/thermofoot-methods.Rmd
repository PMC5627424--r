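---
title: "Detecting plantar hyperthermia in mobile thermograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting plantar hyperthermia in mobile thermograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofoot)
```

## Why skin temperature?

A neuropathic diabetic foot ulcer announces itself thermally before it breaks
the skin: the affected region runs warm, and a local elevation of more than
**2.2 °C** — relative either to the surrounding plantar surface or to the
mirror-corresponding site on the other foot — is the conventional criterion
for *hyperthermia*, an ulcer-risk indicator. Low-cost thermal cameras that
clip onto a phone (160 × 120 px, 0.1 °C sensitivity, −20…120 °C scene range)
make frequent self-checks feasible, provided the image analysis is automatic.
`thermofoot` implements that analysis for radiometric thermograms, i.e.
images whose pixel values are temperatures in °C.

The pipeline has three stages: segment the feet from a cold background,
optionally clean the segmentation, then flag hyperthermic regions by two
independent detectors whose agreement can be audited.

## Foot segmentation

Under the intended acquisition protocol (bare plantar feet in front of a
cold, homogeneous backdrop such as a wet towel, feet centred in the frame)
the gray-level histogram is bimodal: a cold background mode and a warm skin
mode. The threshold between them is chosen by Otsu's criterion. With the
histogram probabilities $p_i = n_i/N$ over levels $0\ldots L-1$, a candidate
threshold $t$ splits the scale into $R_1 = [0..t]$ and $R_2 = [t+1..L-1]$
with masses $w_1, w_2$, means $u_1, u_2$ and total mean
$u_T = w_1 u_1 + w_2 u_2$. The selected threshold maximizes the
between-region variance

$$\sigma_B^2(t) \;=\; w_1 (u_1 - u_T)^2 + w_2 (u_2 - u_T)^2,$$

equivalently minimizes the within-region variance
$\sigma_W^2(t) = w_1\sigma_1^2 + w_2\sigma_2^2$, since
$\sigma_W^2 + \sigma_B^2$ is the total variance for every $t$. The region
variances use deviations of the *level index* from the region mean,
$\sigma_k^2 = \sum_i (i - u_k)^2 p_i / w_k$; this is the form required for
the decomposition identity to hold (a transcription that squares
$(t - u_k)$ instead circulates in the literature, and the identity itself
rules it out). The test suite verifies the identity to $10^{-9}$ for every
candidate threshold of randomized histograms and checks the selected
threshold against an exhaustive-search oracle.

Numerical choices, fixed for determinism:

* **Quantization.** Cameras report continuous °C while the selection
  operates on a discrete histogram, so images are quantized to $L = 256$
  levels over the per-image (or per-mask) min–max range — the conventional
  8-bit Otsu setting. The normalized threshold $t/(L-1)$ is reported
  alongside the integer level.
* **Plateau ties.** When $\sigma_B^2$ is flat over a gap between modes, the
  smallest maximizing $t$ is returned.
* **Empty regions.** A split with $w_k = 0$ gets mean and variance 0, making
  $\sigma_B^2 = 0$, so degenerate thresholds can never win.

The raw binary image (foreground = warm = above threshold) is then smoothed
in a fixed order: **border clearing** (every 8-connected foreground
component touching the frame is removed — hands, legs or radiators
protruding into the field of view), **erosion** with a radius-1 diamond (the
4-neighbour cross), and **hole filling** (4-connected background pockets
become foreground). The 8/4 connectivity pairing for foreground/background
is the standard duality that avoids topological paradoxes at
corner-touching pixels. An empty or implausibly small result (< 0.5 % of
the frame) is an error, not a silent "no feet": every downstream statistic
would be meaningless.

## Detector 1: second-stage Otsu mean difference

Within the feet mask only, Otsu thresholding runs again — the feet now play
the background role and any warmer region is foreground. With $\mu_h$ the
mean temperature of the suspected (foreground) region, $\mu_n$ the mean of
the remaining foot pixels and $\mu_d = \mu_h - \mu_n$, the region is called
*ulcer-suspected* when all three of the following hold:

1. $\mathrm{round}(\mu_d, 1) \ge \delta$ with $\delta = 2.2$ °C. The
   comparison happens after rounding to one decimal — the precision at which
   such measurements are reported — so a difference printing as 2.2 counts.
2. A one-sided Welch two-sample $t$-test finds the two pixel populations
   statistically different at $\alpha = 0.05$. The null shift defaults to
   0 ("are the means different?") rather than $\delta$: published
   classifications of this procedure flag regions whose mean difference
   *equals* the threshold, which a test of $H_0: \mu_d \le \delta$ could
   never do (its $p$-value is ≈ 0.5 at $\mu_d = \delta$). A `null_shift`
   argument restores the stricter test for sensitivity analyses.
3. The suspected class covers at most half of the feet (*minority rule*).
   A lesion is a localized warm minority; when the histogram split instead
   isolates a small **cool** tail (shaded toe notches, residual boundary
   pixels), the "warm" class is nearly the whole foot and its mean
   difference, however large, does not indicate hyperthermia. Without this
   guard a handful of cool pixels in the mask produces confident false
   positives.

All three criteria, the test statistic and the localized region mask are
reported separately, so a reviewer can see *why* a decision was made.
$\mu_n$ excludes the suspected region's pixels; the alternative (mean over
all feet pixels) changes $\mu_d$ only marginally and is recoverable from
the reported masks.

## Detector 2: contralateral point-to-point difference

The second detector uses the opposite foot as the reference. The image is
cut at the vertical midline (an odd middle column is dropped), the right
half is mirrored so both feet occupy corresponding pixels, and the flipped
right half is aligned onto the left by intensity-based rigid registration.
The pixelwise absolute temperature difference over the overlap of both foot
masks, with the feet's Sobel contour bands excised, is thresholded at
$\delta = 2.2$ °C. The reported mean difference averages over the detected
pixels and is 0 when nothing exceeds the threshold — the only convention
consistent with a healthy image reading exactly 0. The mean over the whole
foot overlap is reported alongside.

Design choices that needed deciding:

* **Transform family.** Rigid (translation + rotation), found by a coarse
  grid search (±8 px in 2 px steps, ±10° in 2° steps) followed by
  Nelder-Mead refinement of the mean-squared-difference objective. Flipped
  contralateral feet are already roughly aligned, so a rigid model with a
  modest search range suffices; no external optimizer or multi-scale
  pyramid is needed, and recovery of planted transforms is sub-0.1 px in
  practice (the acceptance script measures it).
* **Objective domain.** The MSE is evaluated over the fixed foot mask plus
  a 2-px collar, using whatever temperatures the transform samples. A
  strictly overlap-restricted MSE is degenerate: the optimizer can slide
  one foot along its own long axis, shrink the scored overlap to flat
  plateau pixels, and score better than the true alignment. Scoring
  fixed-mask pixels against the sampled values instead makes any
  misalignment pay the full foot-versus-cold-background penalty. Samples
  falling outside the image frame are dropped, with a floor of 50 %
  coverage; if no transform improves on the identity, the identity is
  returned with a warning flag.
* **Edge exclusion.** Any residual (sub-pixel) registration error meets its
  steepest temperature gradients at the foot outline, which would read as a
  ring of spurious > 2.2 °C differences. The pipeline therefore excises the
  Sobel contour band of each foot *silhouette* (the segmentation mask),
  dilated by 1 px. Running Sobel on the silhouettes rather than on the raw
  temperatures is deliberate: a temperature-gradient edge map would also
  flag the margins of small hot lesions and delete them — a 0.5 cm lesion
  is all margin. The general temperature-based `sobel_edges()` (3×3
  kernels, Otsu-thresholded gradient magnitude, 1 px dilation) is exported
  for inspection work.
* **Direction.** The absolute difference is thresholded, so hyperthermia on
  either foot is flagged; the signed map is retained in the result. The
  left foot is the reference by default; swapping the reference changes the
  mean difference by well under 0.2 °C on phantoms (tested).

Detections are reported in half-frame coordinates and mapped back to the
full frame at both the reference location and the mirror-corresponding
source location, since the asymmetry criterion is direction-agnostic.

## The phantom generator

No public corpus of radiometric plantar thermograms with ground truth
exists, so the package ships a generator that emulates the acquisition
protocol and returns every geometric element as a mask. It is first-class,
tested code — the power, specificity, registration and shape-generality
results below are all measured against it.

A phantom is built as

$$T = T_{bg} + (T_{foot} - T_{bg})\, S_{feet} + \Delta T\, S_{hot} + \varepsilon,$$

where $S$ are *soft silhouette indicators* and
$\varepsilon \sim N(0, \sigma^2)$ is i.i.d. sensor noise. Defaults mirror
the target hardware and protocol: 160 × 120 px, background 18 °C (cold wet
towel, room 20–25 °C), plantar skin 33–37 °C, $\sigma = 0.1$ °C (the
sensor's stated sensitivity), 0.25 cm/px so the standard heated-object
sizes (0.5–3.5 cm coins, rectangles, a half-ring) span 2–14 px. Feet are a
sole ellipse fused with five toe disks placed along the sole's upper arc,
morphologically closed so the outline has no single-pixel notches, and
mirrored exactly about the midline; per-foot baseline offsets are available
via the `asymmetry` parameter (default 0).

Two modelling points deserve emphasis:

* **Boundary softening is outward-only.** $S_{feet}$ equals 1 on the
  silhouette and decays over a 3-px skirt outside it (0.7, 0.2, 0.03 of the
  contrast on successive rings). This keeps interior ground-truth
  statistics exact — the mean over a lesion mask is exactly
  $T_{foot} + \Delta T$ up to noise — while still giving edge detection and
  sub-pixel registration a smooth transition to work against. The profile
  is also chosen so that first-stage thresholding plus the radius-1 erosion
  provably recovers the exact silhouette: the raw mask is the silhouette
  plus the first ring, and erosion removes precisely that ring. Lesion
  margins get a sub-pixel Gaussian skirt ($\sigma = 0.5$ px, no dilation)
  so that even 5-px lesions keep their plateau statistics.
* **What the phantom does not model.** Real plantar surfaces have smooth
  within-foot temperature structure (arch cooler than forefoot), emissivity
  and reflected-temperature error (~±5 % for this camera class), motion
  blur, and anatomical left/right differences. Passing the phantom suite
  therefore demonstrates the *algorithmic* correctness of the chain —
  thresholds, morphology, registration, statistics — not clinical
  performance. In particular the healthy-feet second-stage mean difference
  is ≈ 0.2 °C on flat phantoms but ≈ 1.8 °C on real healthy feet, whose
  natural nonuniformity the second-stage split picks up.

`make_fixture_suite()` writes the standard eight-image set (one healthy
image plus seven lesions covering the six standard shapes, with baseline
temperatures and elevations taken from the bundled
`reference_measurements()` table) as matrix CSVs with mask PNGs and a JSON
manifest that round-trips to identical specifications.

## Problem sizes and determinism

All simulation-backed checks run at the acquisition resolution
(160 × 120): 50 seeded phantoms per condition for power/specificity and the
contralateral null, 20 planted transforms (|d| ≤ 5 px, |θ| ≤ 5°) for
registration recovery, 200 random histograms (L ≤ 64) for threshold
correctness, and the six lesion shapes at +2.5 °C for shape generality.
Phantoms are deterministic given their seed; the RNG state of the caller is
saved and restored around generation.

## Known limitations

* The 2.2 °C rule is applied to pixel means over Otsu-defined regions; no
  spatial statistics (cluster size, contiguity weighting) refine the call.
  Multi-lesion images are treated as a single suspected foreground.
* The contralateral detector presumes both feet are present and roughly
  centred; amputations or strongly asymmetric poses violate the split
  convention.
* Registration is rigid; it will not compensate pose differences that bend
  the foot.
* Decisions on real images inherit the camera's absolute accuracy (~±5 %
  for the target class); within-image *differences*, which the method uses,
  are considerably more reliable than absolute readings.
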