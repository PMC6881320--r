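Package: mitocomp
Title: Comparative Characterization of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative characterization of circular animal
    mitochondrial genomes from their annotations and sequences: coordinate
    arithmetic on circular gene maps (feature lengths, signed intergenic
    spacers including the origin-spanning junction, overlap and non-coding
    scans), strand-aware nucleotide composition with AT/GC skews, codon usage
    and relative synonymous codon usage (RSCU) under the invertebrate
    mitochondrial genetic code, start/stop codon comparison across genomes,
    Kimura 2-parameter and p-distances with pairwise deletion, rotation- and
    strand-invariant gene-order comparison with breakpoint distances, and a
    synthetic mitogenome generator with a K2P sequence-evolution simulator for
    ground-truth testing. Ships the full annotation tables of two strombid
    gastropod mitogenomes (Harpago chiragra, Lambis lambis) as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ape,
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
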