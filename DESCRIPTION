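Package: seminalMS
Title: Identification, Quantification and Evolutionary Analysis of
    Ejaculated Proteins from 15N-Labeled Reproductive-Tract Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing unlabeled (male-derived) ejaculated
    proteins from 15N metabolically labeled female proteins in
    reproductive-tract mass-spectrometry experiments. Provides a synthetic
    peptide-spectrum-match generator with the labeling structure of such
    experiments, peptide isotope-envelope modeling under arbitrary 15N
    enrichment, target-decoy false-discovery-rate filtering, two-peptide
    protein inference with fractional spectral counting, normalized
    spectral abundance factors (NSAF), term-for-term Gene Ontology
    overrepresentation with Bonferroni correction, inclusion-list directed
    acquisition simulation, and dN/dS-based tests for recurrent positive
    selection (M7/M8/M8a likelihood-ratio criteria plus FEL site counts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
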