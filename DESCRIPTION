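Package: halomark
Title: Composition-Based Haloadaptation Analysis of Marker-Gene Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for detecting "salt-in" haloadaptation
    signals in functional marker-gene fragments (such as aprA and mcrA)
    recovered from hypersaline sediments. Provides six-frame translation
    with best-frame selection, greedy identity clustering of redundant
    phylotypes, alignment column masking with codon bookkeeping,
    amino-acid composition with the PAB and AB haloadaptation indicators,
    GC content by codon position, relative synonymous codon usage (RSCU)
    with correspondence analysis, Tajima's D neutrality test,
    neighbor-joining phylogenies from JTT+Gamma maximum-likelihood
    protein distances with bootstrap majority-rule consensus, DGGE
    band-pattern clustering with a seasonal permutation test, and
    synthetic-data generators (codon sets with controlled positional GC
    and acidic excess, sequence evolution on trees, neutral coalescent
    alignments, band tables) so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    MASS,
    Matrix,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
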