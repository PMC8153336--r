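Package: clampdesign
Title: Host-Blocking Clamp Oligonucleotide Design and Amplicon Community
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs blocker (clamp) oligonucleotides, such as peptide
    nucleic acids (PNA) and locked nucleic acids (LNA), that suppress PCR
    amplification of an over-represented host 18S rDNA template while
    sparing other eukaryotes.  Provides IUPAC degenerate sequence
    arithmetic, primer-site location, flanking-haplotype collapsing and
    conservation profiling, nearest-neighbor melting temperature and
    self-complementarity screening, candidate-window enumeration under
    four selection criteria, in-silico (including nested) PCR and blocking
    prediction over labelled communities, and the downstream statistics
    used to evaluate host-depletion experiments: non-host read
    proportions, per-individual enrichment values, pairwise proportion
    tests, alpha diversity (Shannon, Faith's phylogenetic diversity,
    observed variants), intensity normalization, and detection and
    top-taxa summaries.  A deterministic synthetic-data generator plants
    ground truth for every step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    picante,
    vegan,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
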