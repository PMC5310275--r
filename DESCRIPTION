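Package: lbdtrace
Title: Ancestry Reconstruction for Plant LBD Gene Families
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the ancestry of the plant-specific Lateral Organ
    Boundaries Domain (LBD) transcription-factor family, and of gene families
    with a comparable single-domain architecture, from standard comparative
    genomics inputs. Detects family members from profile-HMM domain hits with
    an E-value gate, a minimum domain-coverage gate and one-representative-
    per-locus isoform collapse; classifies gene duplication types (whole-genome,
    tandem, proximal, dispersed, singleton) from gene order, homology pairs and
    collinear blocks; recursively merges family genes linked by collinear
    anchors into inter-species ortholog groups; infers ancestral gene lineages
    at three evolutionary depths (early land plant, seed-plant ancestor,
    angiosperm ancestor) from a species-annotated gene tree by minimal
    taxon-complete clade search, with collinearity cross-support; computes
    branch-model likelihood-ratio tests on codeml log-likelihoods; profiles
    per-column conservation of protein alignments and scans class-diagnostic
    motifs; and simulates gene-family evolution along a species phylogeny with
    full ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    pracma
Config/testthat/edition: 3
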