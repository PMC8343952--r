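Package: lineagekit
Title: Forensic Lineage-Marker Ancestry Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ancestry assessment from uniparental forensic markers.
    Parses and compares mitochondrial DNA profiles coded as differences to the
    revised Cambridge Reference Sequence, performs range-adjusted haplotype
    database matching with augmented-count (x+1)/(n+1) frequency estimation and
    a two-population probability contrast, assigns mtDNA haplogroups from
    diagnostic-variant trees and builds haplogroup frequency profiles, infers
    maximum-likelihood phylogenies under the Tamura 3-parameter model from
    neighbour-joining and BioNJ starting topologies, and scores Y-STR
    haplotypes against the extended Cohen Modal Haplotype. Includes a seeded
    synthetic two-population generator so the full analysis can be exercised
    end to end without access to case data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
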