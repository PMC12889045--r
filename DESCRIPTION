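Package: dispenseQC
Title: Quality Control and Strain Clustering for Single-Cell Dispensing
    Culturomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative quality control of single-cell
    dispensing culturomics experiments. Simulates dispensing runs with
    known ground truth; normalizes and thresholds dual-channel
    plate-reader fluorescence to classify wells as empty, single-signal
    or dual-signal; estimates the multi-cell (doublet) dispensing
    fraction from two-color collision statistics with bootstrap
    confidence intervals; fits geometric decay to cartridge-wash
    carryover; summarizes per-plate culture success rates and
    mock-community abundance shifts; and clusters isolate genomes into
    strain- and lineage-level groups from pairwise average nucleotide
    identity with aligned-fraction filtering and novelty calling
    against reference genomes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
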