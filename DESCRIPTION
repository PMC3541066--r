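Package: refcomp
Title: Block-Based Referential Compression of Genome Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Lossless referential compression of genome sequences against a
    block-partitioned reference. The reference genome is split into
    fixed-size blocks, each indexed with a suffix array supporting longest
    prefix-suffix match queries. An input genome is greedily encoded as a
    stream of block-change, relative-match and raw entries, using a bounded
    local-neighbourhood search to absorb SNP- and indel-sized differences
    and a global block search as fallback. Includes a versioned binary
    container format, a parallel compression driver, a command-line
    interface, and a seeded mutation simulator for generating synthetic
    reference/mutant genome pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    tools,
    utils,
    stats,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
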