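Package: cladon
Title: Comparative Molecular Evolution of Clade-Structured Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative molecular-evolution toolkit for clade-structured
    gene families such as the octocoral terpene cyclases: per-gene codon
    usage statistics (RSCU, Wright's effective number of codons, GC3s,
    parity-rule-2 asymmetries), population-genetic and selection statistics
    (nucleotide diversity, Watterson's theta, Tajima's D, Nei-Gojobori
    pairwise dN/dS), clade divergence normalised to a slowly evolving
    mitochondrial-like reference, marginal ancestral sequence reconstruction
    by Felsenstein pruning, rank-based between-clade and between-order
    screens with Benjamini-Hochberg FDR control, and a synthetic
    codon-evolution generator (Kingman coalescent and MG94-style codon
    substitution) that makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    phangorn
Config/testthat/edition: 3
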