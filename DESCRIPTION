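Package: neovax
Title: Neoepitope Prioritization and Multi-Epitope DNA Vaccine Insert Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested pipeline for in-silico personalized cancer-vaccine
    design. Extracts neoepitope windows around somatic missense variants in
    tumor-specific protein sequences, scores candidates on four probability
    factors (somatic evidence, clonality from purity-corrected variant allele
    frequencies, MHC ligand presentation, and immunogenicity from amino-acid
    physicochemical distance), selects a vaccine panel under redundancy and
    expression exclusion rules, and optimizes a multi-epitope DNA insert by
    weighted-codon reverse translation, codon adaptation index and GC-content
    thresholding, sequence-hazard screening, and RNA minimum-free-energy
    ranking. Includes a synthetic-data generator emulating the statistical
    structure of tumor/normal sequencing-derived inputs so the whole chain is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
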