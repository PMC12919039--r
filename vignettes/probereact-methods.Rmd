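---
title: "Methods: quantifying probe-induced tissue reactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying probe-induced tissue reactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probereact)
```

This vignette is the package's own account of its methods: the models and
procedures it implements, the parameters that matter and why their defaults
look the way they do, what the synthetic-data generator does and does not
emulate, and the numerical conventions adopted where a definition left room.

## The measurement model

Chronic implantation of a cortical probe provokes a foreign-body response:
a lesion track, loss of neurons around it, reactive astrogliosis (GFAP) and
microglial activation (IBA1). The package quantifies this from
three-channel 8-bit immunofluorescence sections in five steps.

**Geometry.** All geometry is defined in pixels, with row 1 at the pial
surface and rows increasing with depth. Per-shank crops are 800 px wide,
centred on the annotated track column (half-open span `[c-400, c+400)`;
out-of-bounds area is zero-padded and flagged). Three 800 × 700 px depth
ROIs are anchored on biology: upper cortex starts at the pia, lower cortex
ends at the cortex/white-matter boundary, white matter starts there. The
physical ROI extent (~461 × 404 µm at the default 0.576 µm/px) is
reporting metadata only; every downstream rule operates on pixels. When
the cortex is shallower than 1400 px the two cortical ROIs overlap; both
are returned and the overlap is flagged rather than excluding data. When a
section has no white matter below the boundary, the white-matter ROI is
absent, not zero-filled.

**Binarization.** Each stain is thresholded with the moment-preserving
(Tsai) method: the gray level is chosen so that a two-level image keeps
the first three moments of the input histogram. The implementation follows
the convention of the widely used Moments implementation: the preserved
background fraction `p0` is mapped to the first gray level whose
cumulative histogram fraction reaches `p0` (tolerance 1e-9), that bin
counting as background; pixels strictly above the threshold are
foreground. A single-valued histogram is degenerate: the level itself is
returned, with an all-background result and a warning.

**Mask filtering.** Binary masks are cleaned by removing 8-connected
components that fail stain-specific morphology criteria. The criteria are
free parameters; the defaults — NeuN: area ≥ 20 px and solidity ≥ 0.7
(compact somata); GFAP: area ≥ 5 px (keep filaments, drop single-pixel
noise); IBA1: area ≥ 8 px — were chosen so that the synthetic shapes each
stain renders are retained while speckle noise is removed, and are
config-overridable (`stain_filter_profile()`, `read_stain_profiles()`).
Component labeling is 8-connected (a 4-connected labeling pass plus a
diagonal-merge union step); eccentricity uses the standard
second-moment ellipse with the 1/12 pixel-extent term, and solidity
approximates the pixelated convex-hull area by the shoelace area of the
hull through pixel centres plus half the hull perimeter plus one.

**Downsampling.** Each 800 × 700 mask becomes an 11 × 10 grid (11 bins
across the width, 10 across the depth) by *exact area weighting*: 800/11
and 700/10 are not both integral, so bins receive fractional pixel
overlaps rather than cropping the ROI. A cell stores 255 × its foreground
fraction, which makes total foreground mass exactly conserved — a property
the tests assert to floating-point precision.

**Tissue loss.** Tissue integrity uses the *raw* (unsegmented) signal:
per pixel `(NeuN + GFAP)^2`, computed in a widened integer range, is
thresholded at < 50 — the threshold is applied to the squared signal, as
the rule is stated — to classify non-tissue; the binary map is inverted
(loss = high) and downsampled, so a cell's value is 255 × its lost-tissue
fraction.

## Delta signals and the tissue-reaction index

Signals are expressed relative to non-implanted control cortex. The
control reference is the cell-wise mean over all control sections, per
stain and region; each experimental map is subtracted cell-wise. Two
exclusion rules apply before averaging:

* cells with tissue-loss intensity > 190 (more than 75 % lost tissue)
  carry no interpretable stain signal and are excluded — the value 190
  itself is *not* excluded;
* for NeuN in the upper cortex, the top 3 of the 10 grid rows are
  excluded in experimental and control conditions alike. This is layer 1,
  which has few neurons; the "first 3 rows" rule is interpreted on the
  downsampled grid (≈ 210 px ≈ 120 µm, a plausible layer-1 thickness at
  this scale), since 3 raw pixel rows (< 2 µm) could not represent a
  cortical layer, and every other exclusion also operates on grid cells.

Per sample image and region the two mean deltas combine into the
tissue-reaction index

$$\mathrm{Idx} = \frac{|\min(\Delta \mathrm{NeuN}, 0)| +
\max(\Delta \mathrm{GFAP}, 0)}{510},$$

which is 0 for no reaction and 1 for complete neuronal loss plus maximal
astrocytic response. Positive ΔNeuN and negative ΔGFAP are zeroed before
the addition: implantation does not cause neurogenesis or astrocyte loss,
so those signs reflect biological variation. The normative form operates
on the two scalar region means; a cell-wise variant (matrix input,
averaged) is available. ΔIBA1 does not enter the index, and the
white-matter index is reported but flagged non-statistical: NeuN is
non-informative there, so the index would mainly restate GFAP.

## The statistics layer

The sampling unit is the ROI image (shank × region) — deliberately no
mouse-level random effect, mirroring the design this pipeline reproduces;
that is a known limitation, not an oversight. ΔNeuN uses factorial ANOVA
with type-II sums of squares (the conventional unbalanced main-effects
choice; the SS type and interaction inclusion are arguments), followed by
Bonferroni-corrected equal-variance t-tests. ΔGFAP, ΔIBA1 and the index
are analyzed non-parametrically: tie-corrected Kruskal–Wallis (via
`stats::kruskal.test`) and a Dunn post-hoc test implemented from the
mean-rank formula

$$z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} -
\frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
\frac{1}{n_j}\right)}}$$

with two-sided normal p values and Bonferroni adjustment. The tie
correction always applies because downsampled intensities tie often. Both
rank statistics are cross-checked in the test suite against independent
oracles over exhaustive small-sample enumerations, and their type-I error
is verified at α = .05 over 5000 null simulations. Cross-section effects
use OLS of the index on material, tethering, ROI and width × thickness,
restricted to cortical ROIs.

## Electrophysiology

Recordings (24 kHz) are common-average referenced — the per-sample mean
across electrodes is subtracted, cancelling shared running/muscle
artifacts exactly. The MUA envelope is a zero-phase 3rd-order Butterworth
band-pass 750–5000 Hz, full-wave rectification, and a zero-phase 200 Hz
low-pass; zero-phase filtering preserves response latencies, which the
band definition alone would not guarantee. The envelope is decimated to
1 kHz (no content remains near the new Nyquist) and epoched from −0.25 to
+1.25 s around each stimulus onset.

SNR per electrode: the trial-mean envelope is smoothed with a Gaussian
kernel (σ = 5 ms, config-overridable — the amount of smoothing is a free
choice); baseline is its mean over `[-250, 0)` ms; noise is the SD across
trials of the per-trial baseline means (this reading makes the SD over
trials well defined; the alternative — the time-resolved mean trace — has
no across-trial variance); the response is the largest absolute deviation
from baseline within the onset (0–250 ms), reversal (500–750 ms) and
offset (1–1.25 s) windows, the largest of the three being reported. The
absolute value admits suppressed responses. SNR = response/noise;
electrodes with SNR > 1 count as useful, multiple sessions within a week
average to one value, and weeks group into 4-week bins for rank tests.

Note that this statistic is a maximum over ~750 samples of a noisy trace:
under pure i.i.d. noise its null level is positive (typically between 1
and 2.5 at a few dozen trials) rather than 0. The package does not
correct for this — the statistic is reproduced as defined — but the test
suite characterizes the null level by simulation and checks that evoked
responses sit far above it.

## The synthetic-data generator

The generator exists to validate the pipeline, so it reproduces the
*occupancy statistics* the pipeline consumes, not microscopy realism.
Somata are soft-edged disks (radius 4 px); astrocytic processes are short
curvilinear strokes (random walks, ~18 steps, ~1.5 px thick); microglia
are small irregular blobs. Strokes versus disks versus blobs exist
precisely so the three stain-filter profiles act on different shapes.
Intensities sit near 160–180 on a background of 12, with additive
Gaussian noise (SD 4) clipped to [0, 255]; this suffices to exercise the
thresholding, not to model a real point-spread function, bleed-through,
uneven illumination or staining variability. Conclusions from passing
tests are therefore about the *pipeline's correctness and sensitivity*,
not about how real sections will segment.

Control conditions (defaults chosen once; no numerical control-tissue
occupancies are reported anywhere, so these are free parameters): cortex
depth 1400 px at 0.576 µm/px (≈ 806 µm, and the two cortical ROIs tile
without overlap), NeuN 15 somata per 100 × 100 px in cortex and 2 in
layer 1 (top 10 % of the cortical depth), GFAP occupancy 0.12 in cortex
and 0.30 in white matter, IBA1 0.05 throughout.

An implant adds, per the phenomenology the pipeline must recover:

* a lesion void (all channels suppressed) of width 1.2 × shank width,
  with a configurable probability of a widened (3×) void through the
  upper cortex emulating complete local tissue loss;
* peri-track neuronal depletion: soma *i* at column distance *d* from the
  track is lost when *d* < *r·u_i* with *u_i* ~ U(0,1), which makes the
  loss count provably non-decreasing in the radius *r*;
* a GFAP depth gain of 1 + uniform + two Gaussian bumps centred at the
  pial entry and at the white-matter boundary, each with σ = 1/6 of the
  cortical depth — the simplest shape with the two observed foci;
* an IBA1 gain bump at the white-matter boundary.

The default effect map ties these to probe design: silicon multiplies the
glial gains, depletion radius and upper-loss probability by 2.5 relative
to polyimide, untethered probes by 1.3 — strong effects, consistent with
a design factor that separates groups clearly — and the lesion scales with
shank width. Every generator is a pure function of its parameters and
seed.

Evoked recordings: 1 s checkerboard (onset, reversal at 500 ms) + 1 s
inter-trial interval, 24 kHz, broadband Gaussian noise per electrode plus
variance transients (Gaussian envelope, σ = 30 ms) at the configured
latency in each response window, scaled by `amplitude × decay^week`, and
a common-mode artifact (8 Hz sinusoid plus broadband 50 ms bursts) added
identically to all electrodes so that the benefit of common-average
referencing is observable.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based in R; crops are half-open pixel intervals.
* Moments threshold ties: the cut bin goes to background (above).
* Downsampling uses exact fractional bin overlaps; grids are clamped to
  [0, 255] against floating-point spill.
* The tissue-loss exclusion threshold is a strict `> 190`.
* A fully excluded ROI yields `NA` with a warning, never a silent 0.
* All-tied rank inputs return H = 0, p = 1; a constant ANOVA response
  reports F = 0, p = 1; zero baseline noise flags the SNR invalid rather
  than returning infinity.
* ANOVA drops interactions when design cells are empty, and single-level
  factors with a message.

## Validation scale

The end-to-end tests run the full pipeline on cohorts at the sizes the
recovery claims are stated for — 10 seeds per shank width for the
tissue-loss monotonicity, 20 shanks per replicate for the GFAP depth
signs, 10 shanks per material group for the index comparison, with six
replicate cohorts against a shared pool of five control sections, and
5000 simulations for the rank-test calibration. These sizes were chosen
as the package's validation conditions; the generator parameters were
fixed before the recovery tests were evaluated and are not tuned to them.

## Known limitations

* Segmentation realism: thresholds and filter defaults are validated on
  synthetic morphology only; real sections need profile tuning.
* No mouse-level random effects; inference treats ROI images as
  independent.
* The SNR maximum statistic has a positive null level (above); SNR > 1
  is a lenient usefulness cutoff under i.i.d. noise.
* Sections are single 2-D planes; no 3-D reconstruction or vascular
  modeling.
* Landmark annotation (pia, white-matter boundary, track columns) is an
  input, not a detection task.
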