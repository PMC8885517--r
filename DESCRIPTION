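Package: silia
Title: Quantitative Proteomics for 15N Metabolic Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Relative protein quantification for 15N metabolic-labeling
    experiments (SILIA-style whole-organism labeling). Computes theoretical
    isotopologue envelopes of peptides at arbitrary 15N enrichment, estimates
    labeling efficiency from the M-1/M satellite-peak ratio of heavy peptides,
    extracts efficiency-corrected light/heavy ratios from centroided MS1
    spectra in mzML, scores isotope-pattern quality by cosine similarity,
    aggregates peptide ratios into protein-level median and interquartile
    statistics with top-N normalization, and splits target-decoy FDR per
    search channel. Includes a synthetic-experiment simulator with known
    ground truth and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mzR,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
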