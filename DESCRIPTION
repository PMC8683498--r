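Package: clonevolve
Title: Clonal Evolution, Survival and Drug-Synergy Analysis for Multi-Region Tumor Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to track subclonal evolution of solid tumors from multi-region
    sequencing data and to score therapeutic interventions against the resistant
    clones. Converts somatic variant allele fractions into cancer cell fractions
    (CCF) corrected for tumor purity, local copy number and mutation multiplicity;
    deconvolutes CCF distributions into mutation clusters by weighted kernel
    density mode seeking; reconstructs rooted clone trees under the subclonal
    sum rule with per-biopsy cellular compositions and inter-lesion genetic
    distances; estimates Kaplan-Meier survival curves and medians; classifies
    PET metabolic response; scores drug resistance by relative dose-response AUC
    and drug-combination synergy by the zero interaction potency (ZIP) model in
    two and three dimensions. A synthetic-data generator simulates multi-region
    biopsies from a known clone tree with binomial read sampling, so every stage
    of the pipeline is testable end to end without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
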