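Package: vhhscreen
Title: Multiplexed Phage-Display NGS Selection and Pharmacology of Modulatory VHHs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end toolkit for selecting candidate modulatory VHHs
    (single-domain camelid antibodies) from multiplexed phage-display
    next-generation sequencing experiments, and for the downstream
    pharmacological characterisation of selected binders. Covers
    paired-end amplicon merging, reading-frame detection from a conserved
    framework-1 label, CDR annotation, signature collapsing into
    non-redundant clusters with per-condition counts, counts-per-million
    normalisation, enrichment selection against negative controls, kmer
    encoding with UMAP embedding of repertoires, epitope overlap /
    similarity / incoherence matrices for virtual binning, biolayer
    interferometry 1:1 Langmuir kinetic fitting, BRET kinetic-trace
    normalisation with AUC summaries, and four-parameter logistic
    dose-response fitting. A synthetic-data module simulates panning
    dynamics, amplicon reads, epitope predictions and assay traces with a
    known ground-truth manifest for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ShortRead,
    Matrix,
    minpack.lm,
    uwot,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
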