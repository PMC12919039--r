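Package: probereact
Title: Quantification of Cortical Tissue Reactions to Implanted Neural Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the foreign-body response of cortical tissue to
    chronically implanted microelectrode probes from three-channel
    immunofluorescence sections (NeuN, GFAP, IBA1), and to track recording
    quality of the same implants over time. The histology pipeline orients and
    crops per-shank images, extracts anatomically anchored depth regions of
    interest, binarizes each stain with the moment-preserving (Tsai) automatic
    threshold, cleans the binary masks with stain-specific morphology filters,
    downsamples to coarse occupancy maps, and derives tissue-loss maps, delta
    signals against non-implanted control cortex, and a bounded
    tissue-reaction index combining neuronal loss with astrocytic reactivity.
    A statistics layer provides factorial ANOVA with Bonferroni-corrected
    t-tests, Kruskal-Wallis and Dunn post-hoc tests with tie correction, and
    linear models for probe cross-section and longitudinal electrode-yield
    trends. The electrophysiology module computes visually evoked multi-unit
    activity envelopes, per-electrode signal-to-noise ratios and weekly
    useful-electrode fractions. A synthetic-data generator emulates stained
    sections and evoked recordings with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    signal,
    jsonlite,
    car,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
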