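Package: ecohof
Title: HOF Response Curves and pH Niche Traits for Soil Bacterial OTUs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models operational taxonomic unit (OTU) abundance responses along
    soil pH gradients with the five Huisman-Olff-Fresco (HOF) response shapes
    fitted by Poisson maximum likelihood, selects among shapes by AIC hardened
    with a bootstrap vote, extracts pH optima and assigns taxa to pH response
    groups. Around that core it provides OTU count-table import and filtering,
    a synthetic gradient-community generator with known response truths,
    BLAST-style hit criteria and abundance-rank coverage curves for matching
    query sequences to a reference set, indicator species analysis with a
    permutation test, sample-based species accumulation curves, and prediction
    of query community structure from fitted response curves validated by NMDS
    ordination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
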