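Package: baseEditR
Title: Guide Design and Deep-Sequencing Analysis for CRISPR Base Editors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline toolkit for CRISPR base-editing experiments. Designs
    base-editor guide RNAs for a registry of Cas9/Cpf1 nuclease variants
    with degenerate (IUPAC) PAM recognition, annotates editable bases in
    the deaminase editing window, and scans genome FASTA files for
    off-target sites within a mismatch bound. Analyzes targeted amplicon
    deep-sequencing FASTQ data: merges paired-end reads by overlap
    consensus, filters reads on 15-nt indicator sequences, aligns unique
    reads to the reference amplicon by global affine-gap alignment,
    classifies outcomes as wild type, insertion, deletion or substitution,
    and quantifies intended base-conversion rates, per-position
    substitution profiles and amino-acid reading frames, optionally
    overlaid with an untreated control. A simulator generates toy genomes
    and base-edited read sets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
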