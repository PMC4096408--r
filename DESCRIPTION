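Package: mlsadelim
Title: Multilocus Sequence Analysis for Bacterial Species Delimitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for delimiting bacterial species from multilocus sequence
    data. Reads per-locus nucleotide alignments, computes per-locus diversity
    statistics (alleles, polymorphic sites, G+C content, p-distance ranges),
    concatenates loci, infers neighbor-joining phylogenies with nonparametric
    bootstrap support, clusters strains into species hypotheses at percent
    identity cutoffs, quantifies the intraspecies/interspecies similarity gap,
    and calibrates per-gene species-boundary similarity cutoffs against a
    pairwise digital DNA-DNA hybridization matrix at the 70 percent species
    boundary. Includes a seeded multilocus sequence simulator (Jukes-Cantor
    substitution along a species tree) with matched synthetic DDH matrices for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    graphics,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
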