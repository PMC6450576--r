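Package: probetax
Title: Probe-Based Taxonomic Profiling of 16S rRNA Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-tier oligonucleotide-probe classification of 16S rRNA gene
    amplicon reads (species-level probes first, then genus-level probes), with
    the surrounding comparison framework: paired-end read joining and quality
    filtering, a closed-reference identity classifier, abundance-table
    filtering and genus aggregation, rarefaction alpha diversity, UniFrac and
    principal-coordinates beta diversity with Procrustes congruence testing,
    and a seeded mock-community simulator that provides ground truth for
    validating both classification arms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    biomformat,
    ape,
    vegan,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phyloseq,
    jsonlite
Config/testthat/edition: 3
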