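Package: kmersim
Title: Alignment-Free Sequence Similarity by Shared k-mer Counting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Alignment-free pairwise similarity for protein and nucleotide
    sequences by shared k-mer counting, optionally over compressed
    (reduced) amino-acid alphabets such as SE-V(10), Murphy(10) and
    Dayhoff(6). Builds the all-pairs lower-triangular similarity matrix
    either sequentially or with a deterministic master-worker scheme that
    distributes matrix rows cyclically across workers, each worker
    returning a single packed result vector. Includes FASTA input, TSV and
    lower-triangular PHYLIP-style matrix output, a synthetic
    sequence-family generator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
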