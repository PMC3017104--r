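Package: stabcons
Title: Linking Protein Thermodynamic Stability to Evolutionary Conservation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating per-position thermodynamic stability of
    a protein complex to its evolutionary conservation. Provides dot-surface
    solvent-accessible surface area and buried/interface residue classification
    from PDB structures; Boltzmann amino-acid propensities and positional
    sequence entropies from free-energy (ddG) mutational scans; Henikoff-weighted
    evolutionary entropies from multiple sequence alignments; entropy-entropy
    correlation and three-set partitioning of positions; normalized
    mutual-information coevolution scores with a phylogenetic (tree-based)
    shuffling null model; Kimura-corrected distances, neighbor-joining trees and
    per-node conservation profiles; and a stability-based lethality classifier
    for mutant phenotypes. Includes seeded synthetic-data generators for every
    input class so the full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
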