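Package: phagedeconv
Title: Deconvolution of Deep-Sequenced Phage-Display Peptide Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to deconvolute pooled amplicon deep-sequencing runs of
    combinatorial phage-display peptide libraries (Ph.D.-12 style 12-mer NNK
    inserts). Reads paired FASTA/QUAL (Roche 454 convention) or FASTQ input,
    demultiplexes reads by inline trinucleotide barcodes, extracts and
    quality-repairs the variable-region insert, validates NNK codons,
    translates to peptides, filters nickel-plate poly-histidine binders and
    parental-library propagation artifacts, and tabulates per-sample peptide
    enrichment across panning rounds and wash stringencies. Includes a
    454-style amplicon read simulator with ground truth so every pipeline
    stage can be verified offline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
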