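Package: rankindel
Title: Rank and Rank-Indel Rearrangement Distances for Genomes with
    Unequal Marker Content
Version: 0.1.0
Authors@R:
    person("Rankindel", "Developers", email = "rankindel@example.org",
           role = c("aut", "cre"))
Description: Genome rearrangement distances for multi-chromosomal genomes
    whose marker (gene, synteny block) content may differ, but without
    duplications.  Genomes are modeled as symmetric binary matrices over
    marker extremities; the rank distance between two genomes is the rank
    of the difference of their matrices and is computed in linear time
    from the augmented breakpoint graph.  The rank-indel variant restricts
    content changes to insertions and deletions of whole chromosomes.
    Includes construction of optimal sorting scenarios from the six basic
    operations (cut, join, double swap, chromosome insertion/deletion,
    extremity substitution), a gene-order evolution simulator with
    DCJ-type rearrangements and Zipf-sized indels along a phylogeny, and
    distance-based phylogenetic inference (neighbor joining) with
    Robinson-Foulds and quartet tree comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
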