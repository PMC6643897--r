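Package: orthopop
Title: Population Genetics of Multi-Species Orthologous Gene Alignments
Version: 0.1.0
Authors@R:
    person("orthopop", "developers", email = "orthopop@example.org",
           role = c("aut", "cre"))
Description: Tools for population-genetic analysis of per-gene multiple
    sequence alignments sampled across several closely related species,
    as in multi-accession amplicon or transcriptome ortholog panels.
    Reads per-gene aligned multi-FASTA plus a sample sheet, classifies
    alignment columns within and across species, and computes Watterson's
    theta and nucleotide diversity pi with missing data, Tajima-Nei
    ("equal input") divergence with between-group means and a
    neighbor-joining tree, trans-specific (shared ancestral) polymorphism
    detection and classification, and the multilocus Hudson-Kreitman-Aguade
    neutrality test. Includes a multispecies-coalescent simulator with
    known per-species theta, split times, and missing-data structure so
    every stage is verifiable against theory without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
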