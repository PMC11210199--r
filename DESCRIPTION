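Package: escapesel
Title: Selection Landscapes of Immune-Escaped and Non-Escaped Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares somatic selection between tumors that have escaped
    immune surveillance (carrying non-silent point mutations in antigen
    presentation and immune-evasion genes) and tumors that have not.
    Implements trinucleotide-context maximum-likelihood dN/dS with
    gene-level and pooled (global / driver-set) estimates, confidence
    intervals and driver calling; a randomized escape-gene null; hotspot
    site-concentration contingency tests with downsampling and hotspot
    exclusion controls; mutational-signature refitting by constrained
    forward selection; variant-allele-frequency clonality contrasts;
    Kaplan-Meier and log-rank survival comparisons stratified by immune
    category; and protein-to-genome mapping of immunopeptidome regions
    for region-masked dN/dS. A fully seeded synthetic cohort generator
    produces mutation catalogs, gene models, clinical, expression and
    copy-number tables with the statistical structure the analysis
    assumes, so the whole pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    IRanges,
    Biostrings,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
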