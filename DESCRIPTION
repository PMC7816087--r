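Package: silentsites
Title: Engineer Restriction-Enzyme Sites into Coding DNA with Silent Substitutions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scans an in-frame DNA coding sequence and reports every way a
    minimal set of synonymous ("silent") nucleotide substitutions creates a
    new restriction-endonuclease recognition site, preserving the encoded
    peptide exactly. Recognition motifs may contain IUPAC degenerate symbols
    and are matched on both strands; palindromic motifs are reported once as
    double-stranded sites. Includes enzyme-library readers (plain TSV and a
    REBASE-style flat file), summary statistics over reported sites
    (distinct engineered sequences, total reported enzymes, palindromic
    fraction), segmented scans, an exhaustive brute-force oracle for
    verification, a seedable synthetic coding-sequence generator, and a
    command-line interface. Intended for CRISPR homology-directed-repair
    template design and RFLP genotyping screens.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
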