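Package: ervwtools
Title: Annotation, Classification, Phylogeny and Molecular-Clock Dating of
    ERV-W-Like Proviruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for characterizing endogenous retrovirus (ERV-W-like)
    insertions in primate genomes: structural annotation of proviral loci
    (LTR detection, primer binding site assignment against a tRNA library,
    Gag nucleocapsid zinc-finger and Pol integrase GPY/F motif scanning,
    nucleotide composition, pre-gag leader and ORF analysis), k-mer based
    genome scanning and classification of loci into proviruses, solitary
    LTRs and processed pseudogenes, detection of orthologous insertions
    shared between species via flanking-sequence identity, LTR phylogeny
    (p-distance and Kimura 2-parameter distances with pairwise deletion,
    neighbor-joining, nonparametric bootstrap, majority-rule consensus,
    bootstrap-supported subgroup extraction), and molecular-clock insertion
    dating from LTR-LTR and gene-versus-consensus divergence with CpG
    removal and dispersion-based method exclusion. Includes a synthetic
    provirus and genome generator with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
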