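Package: dtsynth
Title: Linking Cancer Treatment Biomarkers with Drug-Target Bioactivities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Synthesizes two kinds of curated oncology tables -- cancer
    treatment biomarkers (drug, mutation, responsive/resistant effect,
    clinical evidence level) and measured drug-target bioactivities
    (Kd/Ki/IC50 in nanomolar) -- into a single linked store keyed by
    canonical (drug, target) pairs. Replicate bioactivities are aggregated
    by their median and binned into potency classes (highly potent, potent,
    weakly potent, inactive). The linked store exposes three data
    uncertainties: missing cells, cross-source consistency states
    (including machine-readable conflict reports), and ordinal evidence
    credibility. A drug-by-target matrix model with tumor-type rows
    supports three drug-sorting procedures and deterministic SVG rendering
    with layered visual encodings. A fixture generator produces synthetic
    source tables with controlled cardinalities and planted conflicts for
    fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
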