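Package: nsephylo
Title: Profile-HMM Classification and Phylogenomics of Nucleotide-Sugar Interconversion Enzyme Families
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds, calibrates and scores simplified glocal (global-in-model,
    local-in-sequence) profile hidden Markov models for protein domain families;
    harvests domain envelopes from protein databases at a Gumbel E-value cutoff;
    competitively classifies domains into families and tabulates family-by-taxon
    count matrices; detects single- versus bi-domain (fusion) protein
    architectures from paired N- and C-terminal domain profiles; builds
    neighbor-joining trees with bootstrap supports and extracts seed-anchored
    subclades from any Newick tree; scans ordered gene tables for synteny of
    labeled gene families within a fixed gene-span window; and simulates
    ground-truth-labeled protein families, fusions, decoys and genomes for
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
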