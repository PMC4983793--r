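---
title: "Quantifying fluorescence immunoprecipitation images"
author: "FLIPimage authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluorescence immunoprecipitation images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FLIPimage)
```

## The measurement problem

A fluorescence immunoprecipitation (FLIP) assay scores an IP reaction by
microscopy instead of immunoblotting: the target protein is expressed as a
YFP fusion, captured from lysate by the antibody under test, and bound to
protein A/G agarose beads. When the IP works, the captured fluorophore
accumulates at the bead surface and each bead shows a sharp bright ring at
its perimeter. When it does not, beads either stay dark or glow uniformly
from nonspecific background binding — occasionally quite brightly, which is
exactly why a whole-image fluorescence mean is a fragile readout.

The quantity this package computes exploits that geometry. For every bead,
treated as a single entity:

$$s_{\mathrm{bead}} = \bar{I}_{\mathrm{ring}} - \bar{I}_{\mathrm{body}}$$

the mean raw intensity of the perimeter ring minus that of the bead body.
The image-level signal is the unweighted mean of $s_{\mathrm{bead}}$ over
retained beads, and the reported ("true") FLIP signal subtracts the same
quantity measured on the matched IgG-control IP:

$$S = \frac{1}{n}\sum_{b=1}^{n} s_b^{\mathrm{test}} \;-\;
      \frac{1}{m}\sum_{b=1}^{m} s_b^{\mathrm{IgG}}.$$

Three properties follow. The signal is independent of how many beads lie in
the frame (each bead contributes once, regardless of area). Uniformly
glowing background beads contribute $\approx 0$. And IgG-control beads,
whose edges are slightly *darker* than their bodies, give small negative
signals — so the control subtraction typically raises the corrected value.
The legacy whole-image readout (`globalMeanFlip()`), the difference of
whole-image pixel means, is retained for comparison; it scales with bead
count and is inflated by any bright contaminant.

## Segmentation and shape filtering

`detectBeads()` uses the simplest pipeline adequate for bright beads on a
dark background: Gaussian smoothing (default $\sigma = 2$ px), Otsu
threshold computed over the *occupied* intensity range (micrographs often
use a sliver of the 16-bit range), hole filling, and connected-component
labelling. The threshold is found on the smoothed image but every
statistic is measured on the raw image, so the rim is never blurred into
the numbers.

Each component is then scored:

* **circularity** $4\pi A / P^2$, with the perimeter $P$ measured along the
  traced boundary chain (diagonal steps count $\sqrt2$). Components below
  0.80 are rejected as `non_spherical`.
* **solidity** $A / A_{\mathrm{hull}}$ against the rasterised convex hull;
  below 0.90 the object is rejected as a `clump`.
* **size**: equivalent radius $\sqrt{A/\pi}$ outside 5–100 px rejects as
  `too_small` / `too_large`.
* **border**: beads touching the frame edge have an incomplete rim and are
  rejected by default.

Merged beads are rejected, never split: an overlapping bead has no
complete rim, so a watershed separation would still not yield a valid
measurement. Two practical notes on the filter's resolution. The chain
estimator under-reports circularity by roughly 0.05 (a clean disc scores
$\approx 0.91$–0.95, not 1), which effectively tightens the 0.80 threshold.
An ideal 2:1 ellipse has true circularity $\approx 0.85$, so aspect ratios
right at 2 sit within the estimator's margin and may survive;
rejection is reliable from aspect $\approx 2.3$ upward, and likewise for
bead pairs whose centres are at least $\approx 1.4\,r$ apart. Physically
touching beads in a settled monolayer (centres near $2r$) are far inside
the reliable region; only strongly stacked beads approach the convex blob
that no shape score can distinguish from a large bead — which is one
reason the bead-distribution QC (`checkBeadDistribution()`) exists, and
why a visual check of the monolayer remains advisable.

### Radial mask refinement

Smoothing plus thresholding systematically biases the mask boundary: for
bright-rimmed beads the mask dilates by $\sim$0.5 px into the background,
and for dark-edged IgG-control beads the rim can fall below the global
threshold entirely, truncating the mask to the bead body. Both failure
modes corrupt the ring band — the first mixes background pixels into the
ring, the second measures the "ring" inside the body.

Because retained beads have already passed the circularity filter, the
refinement step (`refineRadius = TRUE`) treats each as a disc: intensities
are averaged over integer-radius shells around the component centroid, and
the mask is snapped to the largest contiguous shell whose mean raw
intensity stays above $\mathrm{bg} + 0.25(\mathrm{thr} - \mathrm{bg})$,
where bg is the median background intensity and thr the Otsu threshold.
The 0.25 factor sits far (many standard errors of a shell mean) from both
the background and the dimmest structure of interest, and recovers dark
rims whose intensity lies between background and threshold. On synthetic
discs the refined mask reproduces the true bead pixel-for-pixel
(Jaccard 1.0 noiseless, $\ge 0.95$ under realistic noise).

## Ring-band geometry

`rimParams()` fixes the two-region geometry. With bead outer radius $R$
(largest centroid distance in the mask) and ring depth
$d = \max(d_{\min},\, f\,r_{\mathrm{eq}})$ — default floor
$d_{\min} = 2$ px and fraction $f = 0.15$ of the equivalent radius —

$$\text{ring}: R - d + m < \delta \le R - m, \qquad
  \text{body}: \delta \le R - d - g,$$

where $\delta$ is a pixel's distance from the bead centroid, $g$ the guard
band (default 1 px) keeping the regions disjoint, and $m$ a *sub-pixel edge
margin* (default 0.5 px) applied at both edges of the ring band. The
margin exists because mask and centroid estimates carry rasterisation
error of a fraction of a pixel; without it, single lattice pixels of body
or background leak into the ring and leave a deterministic bias of several
intensity units that no amount of averaging removes. On ideal noiseless
beads the margin changes nothing — the worked example below still returns
the construction values exactly. Defaults keep the body non-empty for
radii $\ge 5$ px; a bead too small for ring + guard + body raises a
`degenerate bead` error naming the label rather than returning a silent
number.

Aggregation is the unweighted per-bead mean, not a pixel pool, so large
beads do not dominate. No intensity normalisation is applied across
images: the assay holds microscope settings constant within an experiment,
and raw units are only comparable under that assumption — the pipeline
records it rather than hiding it.

Replicates (duplicate pictures from separate bead aliquots) are merged by
`replicateMerge()`: the merged signal is the replicate mean and the
reported variability ("var.") is the range, max − min. By default
replicates are merged before the merged control is subtracted
(`mergeOrder = "merge_then_subtract"`); with pairwise matched replicate
indices the subtraction can instead be done per replicate first. The two
orders give identical point estimates (both are differences of means);
they differ only in what the replicate spread describes.

## The synthetic scene generator

Every quantitative claim above is testable because `renderScene()` draws
micrographs with exact ground truth. Beads are ideal filled discs with an
annulus of uniform rim intensity — the idealisation the shape filter
itself assumes; contaminants are elongated ellipses or free-form polygons;
overlapping objects combine with per-pixel maximum intensity. Noise is
additive zero-mean Gaussian read noise plus optional signal-dependent shot
noise (variance equal to the noiseless intensity), clipped to the bit
depth and rounded; the seed fully determines the render.

The default test conditions mirror a plausible field of view at 20×: a
160–256 px frame, beads of radius 15–25 px with a 3–4 px rim, background
$\approx 20$, bead bodies $\approx 300$, positive rims $\approx 1000$, and
IgG-control rims slightly below body ($240$ vs $300$, i.e. a $-60$ control
signal) — chosen once as round numbers on the 16-bit scale with the
control's dark-edge sign taken from the assay's observed behaviour. The
"5% of rim" noise level used in the recovery suites is $\sigma = 50$.

What the generator deliberately does **not** emulate: optics (no PSF, no
defocus), multi-layer bead stacks, photobleaching, spatially varying
background, or camera fixed-pattern noise. Passing the synthetic suites
therefore demonstrates the *arithmetic and geometric* correctness of the
pipeline and its noise robustness — not performance on arbitrary real
micrographs, where focus quality and monolayer formation still matter and
where the manual QC step is irreplaceable.

Fixture sizes throughout the test-suite (128–256 px frames, 3-bead scenes,
50-seed Monte-Carlo batches, 100 simulated standard curves) are the
package's chosen balance of statistical resolution against a test suite
that stays pleasant to run; the Monte-Carlo assertions use 3-standard-error
bands computed from the same runs they test.

## Calibration and assay planning

`fitStandardCurve()` is an ordinary least-squares line through known
recombinant-YFP masses (typically 0–500 ng), blank point included rather
than subtracted. A linear model is adequate over this range; no 4PL term
is fitted. Plate-reader autogain makes readings comparable only within a
plate, so curves carry a plate identifier and refuse cross-plate
quantification. `quantifyLysate()` inverts the curve for a measured
aliquot (default 10 µl), flagging extrapolation beyond the fitted range
and flooring negative implied masses at zero with a flag.
`planAssay()` applies the format rules: a large-volume FLIP wants 700 µl
of lysate at ≥ 0.5 ng/µl YFP (≥ 350 ng per IP); the miniaturised format
wants 100–120 µl at ≥ 0.3 ng/µl; exceeding the minimum is recommended for
weak-affinity antibodies.

## Screening reports

`percentTotalLysate()` makes the immunoblot efficiency index explicit:
both band intensities are scaled to whole-reaction equivalents by the
fraction loaded before taking their ratio, so the index is invariant to
gel exposure. The loaded fractions are required inputs — guessing them is
the one thing the function refuses to do. `classifyScreen()` applies the
reporting conventions: negative FLIP values display as zero, the call is
positive iff the signed signal exceeds zero, and tier annotations mark the
empirically observed separation (high > 1.0, low < 0.6). The
immunoblot pass/fail is itself an input call, since the underlying
criterion (a visible band) is visual; where a numeric threshold on the %
index is preferred, the operator applies it upstream.
`concordanceSummary()` and `screenCorrelation()` summarise a panel as a
2×2 confusion table with concordance rate and as the squared Pearson
correlation between the two assays.

## Worked example

```{r example}
spec <- sceneSpec(
  imageShape = c(160, 160), backgroundIntensity = 20,
  beads = rbind(beadSpec(50, 50, 18, bodyIntensity = 300,
                         rimIntensity = 1000, rimThickness = 3),
                beadSpec(50, 115, 18, 300, 1000, 3),
                beadSpec(115, 80, 18, 300, 1000, 3)),
  gaussianSigma = 50, seed = 42L)
test <- renderScene(spec)
ctl <- renderControlScene(sceneSpec(
  imageShape = c(160, 160), backgroundIntensity = 20,
  beads = rbind(beadSpec(50, 50, 18, 300, 240, 3),
                beadSpec(50, 115, 18, 300, 240, 3),
                beadSpec(115, 80, 18, 300, 240, 3)),
  gaussianSigma = 50, seed = 43L))

tRes <- imageFlipSignal(sceneImage(test), detectBeads(sceneImage(test)))
cRes <- imageFlipSignal(sceneImage(ctl), detectBeads(sceneImage(ctl)))
controlSubtract(tRes, cRes)
```

The ground truth here is $+700$ for the test image, $-60$ for the control,
hence $760$ corrected; the printed values land within a few intensity
units under 5% noise.

## Known limitations

* Two-region model only: no radial profiles, no sub-pixel rim
  localisation, no spectral unmixing.
* Shape filtering excludes rather than resolves overlaps; heavily stacked
  beads reduce usable bead count and eventually trip the monolayer QC.
* Raw intensities are only comparable within one acquisition-settings
  context; nothing rescales across experiments.
* The synthetic generator validates geometry and statistics, not optics;
  real-image performance depends on focus and monolayer quality.
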