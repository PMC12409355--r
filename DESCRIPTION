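Package: ringscan
Title: Annotation of Ring Nucleases in Type III CRISPR-Cas Loci
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and characterizes ring nucleases (RNs) and
    cyclic-oligoadenylate effectors in type III CRISPR-Cas loci. Assembles
    Cas10-anchored loci from genome annotations and profile-HMM hit tables,
    bounds the RN/effector search to a 6 kbp neighborhood around the cas
    operon, applies a 250 amino-acid length cutoff and a conserved-residue
    screen to RN candidates, infers the signalling molecule of each locus
    from its effector content, and summarizes RN/effector co-occurrence as
    tables and a bipartite network. Ships a synthetic-genome generator with
    planted ground truth so the whole pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
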