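Package: glycopotency
Title: Site-Specific Glycosylation Metrics and Parallel-Line Potency for
    Recombinant FSH Comparability
Version: 0.1.0
Authors@R:
    person("Analytical", "Development", email = "devel@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparability assessment of recombinant human
    follicle-stimulating hormone (r-hFSH) products. Implements site-specific
    N-glycopeptide quantitation from LC-MS peak lists (in-silico chymotryptic
    digestion, glycopeptide ion matching, extracted-ion-chromatogram ion
    counts, relative glycan distributions), compositional glycosylation
    metrics (hypothetical charge number Z, antennarity index A, antennarity/
    fucosylation/sialylation class summaries, whole-molecule glycan-release
    simulation), compendial 3x3 parallel-line bioassay analysis (validity
    ANOVA, relative potency with Fieller fiducial limits, weighted
    combination, specific activity), batch-comparison statistics (one-way
    ANOVA with Fisher LSD, Bartlett's variance check, CV, randomized
    cross-validation), and seedable generators of synthetic peak lists and
    bioassay datasets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
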