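Package: ervfossil
Title: Comparative Genomics of Endogenous Retrovirus Fossils
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing the history of endogenous retrovirus
    (ERV) families from genome assemblies and repeat annotations: parsing of
    RepeatMasker positional output into classified loci (putative full-length
    proviruses and complete solo LTRs), cross-species orthologous-insertion
    calling from flanking-sequence search hits, insertion dating from 5'-3'
    LTR divergence with CpG masking and Kimura two-parameter correction,
    sliding-window identity profiles, detection of inter-LTR gene conversion
    by a distance-based quartet topology test, per-domain selection analysis
    (Nei-Gojobori dN/dS with a codon-bootstrap test of neutrality), open
    reading frame integrity statistics with exact Poisson confidence
    intervals, and shared deletion-breakpoint clustering. A two-species
    genome simulator with fully known ground truth (insertion ages, orthology
    status, solo-LTR formation, gene conversion, envelope deletions, ORF
    disruptions) supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
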