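Package: mitocomp
Title: Comparative Analysis of Animal Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated animal mitochondrial
    genomes: nucleotide composition and AT/GC strand skews, codon usage and
    relative synonymous codon usage (RSCU) under the invertebrate
    mitochondrial genetic code, start/stop-codon classification including
    incomplete stop codons, template-based tRNA cloverleaf folding with
    per-arm mismatch profiling, Kimura 2-parameter genetic distances,
    Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction,
    codon-aware alignment and supermatrix construction, neighbor-joining
    trees with bootstrap support, gene-order comparison, and a seeded
    mitogenome simulator so the full pipeline runs on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
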