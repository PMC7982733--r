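Package: tbpfinger
Title: Tubulin-Based Polymorphism and AFLP Fingerprint Genotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of multilocus DNA fingerprints from capillary
    electrophoresis, centred on tubulin-based polymorphism (TBP) profiling
    of duckweed (Lemnaceae) clones.  Reads fragment-analysis peak tables,
    filters and annotates peaks (including SSR stutter artifacts), bins
    peak sizes into binary marker matrices and computes panel statistics
    (total/monomorphic markers, percentage polymorphism, mean detected
    loci, fixed private markers, marker-count inflation).  Implements
    Jaccard, Dice and p-distance dissimilarities, neighbor-joining and
    UPGMA tree building with column bootstrap, Mantel matrix correlation
    and Newick serialization.  Predicts beta-tubulin amplicons in silico
    with IUPAC degenerate primers and assigns observed peaks to loci by
    size.  Infers interspecific hybrids from codominant marker profiles
    (subgenome partitioning, union coverage, diagnostic-locus genotyping).
    A synthetic-data generator emulates beta-tubulin intron length
    polymorphism, stutter peaks, clonal variants, hybrids and AFLP panels
    so that the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
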