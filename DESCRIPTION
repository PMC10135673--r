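Package: ecotip
Title: Trait-Based Biomonitoring Response Curves and Ecological Tipping Points
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for trait-based biomonitoring of stream macroinvertebrate
    communities along environmental gradients. Translates family-level taxa
    counts into trait abundances through fuzzy-coded affinity scores, computes
    abundance-based functional diversity indices (Shannon-Weaver, Simpson,
    inverse Simpson, trait richness, Pielou's evenness), fits per-trait
    negative-binomial and per-metric Gaussian response curves with predictor
    centering and backward elimination of polynomial terms, and detects
    ecological tipping points by segmented (broken-line) regression with
    Davies and score tests for the existence of a breakpoint. A synthetic
    survey generator produces communities with known response structure so
    every stage of the pipeline can be validated against ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
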