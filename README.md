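# probereact

Quantifying the cortical foreign-body response to chronically implanted
microelectrode probes — and the recording quality those probes retain — from
three-channel immunofluorescence sections and visually evoked extracellular
recordings.

`probereact` is aimed at groups comparing probe designs (material, tethering,
shank width/thickness) by their histological footprint. It implements the
full quantification chain from registered section images to group
statistics, plus a synthetic-data generator with known ground truth so that
every stage can be validated without animal data.

## What it computes

**Histology.** Sections stained for NeuN (neurons), GFAP (reactive
astrocytes) and IBA1 (microglia) are oriented, cropped to 800-px-wide
per-shank images, and cut into three anatomically anchored 800 × 700 px
depth ROIs: *upper cortex* (from the pial surface), *lower cortex* (ending
at the cortex/white-matter boundary) and *white matter* (below it). Each
stain is binarized with the moment-preserving (Tsai) automatic threshold,
cleaned with stain-specific morphology filters on 8-connected components,
and downsampled to an 11 × 10 occupancy grid by exact area weighting.

Tissue integrity uses the raw signal: per pixel, (NeuN + GFAP)² is
thresholded at < 50 to classify non-tissue, inverted and downsampled so
that cell intensity = 255 × the lost-tissue fraction.

All signals are expressed relative to non-implanted control cortex
(ΔNeuN, ΔGFAP, ΔIBA1, ΔTissueLoss). Cells with > 75 % tissue loss
(loss intensity > 190) are excluded, and layer 1 (top 3 grid rows of the
upper-cortex ROI) is excluded from NeuN. The headline summary is the
tissue-reaction index

```
Idx_TissueReaction = ( |min(ΔNeuN, 0)| + max(ΔGFAP, 0) ) / 510
```

which runs from 0 (no reaction) to 1 (complete neuronal loss plus maximal
astrocytic response); positive ΔNeuN and negative ΔGFAP are treated as
biological variation and zeroed before the sum.

**Statistics.** Factorial ANOVA (type-II) with Bonferroni-corrected
post-hoc t-tests for ΔNeuN; tie-corrected Kruskal–Wallis and Dunn tests
for ΔGFAP/ΔIBA1/Idx; OLS of the index on material, tethering, ROI and
shank cross-section; trend fits for the weekly useful-electrode fraction.

**Electrophysiology.** Common-average referencing, MUA envelope
(zero-phase 750–5000 Hz band-pass → rectification → 200 Hz low-pass),
epoching around checkerboard stimulus onsets, and a per-electrode SNR:
the largest absolute deviation of the smoothed trial-mean envelope from
baseline across the onset (0–250 ms), reversal (500–750 ms) and offset
(1–1.25 s) windows, divided by the SD across trials of the per-trial
baseline means. Electrodes with SNR > 1 count as useful.

**Synthetic data.** `generate_control_section()` /
`generate_implanted_section()` render sections with known ground truth
(soma positions, lesion mask, per-row glial occupancy): a lesion void
scaling with shank width, peri-track neuronal depletion, GFAP bumps at the
pial entry and the white-matter boundary, and an IBA1 peak at that
boundary. `generate_mua_recording()` produces evoked multi-electrode
traces with weekly amplitude decay and a common-mode artifact.

## Worked example

Simulate a small cohort (3 polyimide and 3 silicon shanks, tethered,
35/70/105 µm wide) with 3 control sections, quantify it, and test the
material effect on the index:

```r
library(probereact)

design <- data.frame(
  material = rep(c("PI", "Si"), each = 3),
  tether = "T",
  width_um = rep(c(35, 70, 105), 2),
  thickness_um = 15
)
cohort <- generate_cohort(design, n_control = 3, seed = 7)
tab <- summarize_cohort(cohort, stains = c("NeuN", "GFAP"))
cortical <- subset(tab, statistical)   # drop white-matter rows
cortical[, c("material", "width_um", "region", "delta_gfap",
             "delta_tissue_loss", "idx_tissue_reaction")]
#>    material width_um       region delta_gfap delta_tissue_loss idx
#> 1        PI       35 upper_cortex       23.3              20.5 0.046
#> 4        PI       70 upper_cortex       18.4              40.8 0.043
#> 7        PI      105 upper_cortex       24.5              61.7 0.048
#> 10       Si       35 upper_cortex       59.0              20.5 0.125
#> 13       Si       70 upper_cortex       51.3              40.8 0.106
#> 16       Si      105 upper_cortex       59.4              61.6 0.119
#> ...      (lower-cortex rows omitted here)

dunn_test(cortical$idx_tissue_reaction, cortical$material)
#>   comparison statistic value df  n   p_raw   p_adj
#> 1   PI vs Si         z -2.88 NA 12 0.00395 0.00395
```

Reading the output: ΔTissueLoss tracks the lesion width (20 → 41 → 62
intensity units for 35/70/105 µm shanks) identically for both materials,
while ΔGFAP — and through it the index — separates silicon (≈ 0.11–0.12)
from polyimide (≈ 0.04–0.05), the direction the generator encodes; the
negative Dunn z means the first-named group (PI) has the lower mean rank.

For recordings:

```r
ep <- ephys_model_params(n_electrodes = 4, n_trials = 20, weekly_decay = 0.9)
rec <- generate_mua_recording(ep, week = 4)
process_recording(rec)   # per-electrode SNR, chosen window, useful flag
```

## Scope and limits

Sections are treated as single 2-D planes with annotated anchors (pia,
white-matter boundary, lesion columns); anatomical landmark detection,
spike sorting and LFP analysis are out of scope. The synthetic generator
reproduces occupancy statistics, not microscopy realism — see the methods
vignette (`vignettes/probereact-methods.Rmd`) for what that does and does
not validate.
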