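Package: codonDecipher
Title: Benchmarking Neural Decoders that Rediscover the Genetic Code
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmark framework for measuring how much training data a
    neural network needs to rediscover the standard genetic code from
    codon/amino-acid pairs. Builds training corpora either by extracting and
    validating open reading frames from transcript FASTA files or by
    synthesizing ORFs from a codon-usage table; encodes codons as 64-bit or
    12-bit one-hot vectors, learnable embeddings, or per-nucleotide timesteps;
    trains linear multilayer perceptrons, embedding perceptrons, and recurrent
    readers (Elman, GRU, LSTM) with class-imbalance-weighted cross-entropy and
    Adam; and reports data efficiency as the cumulated number of training
    pairs presented before the 64-codon decoding table is recovered
    unequivocally, stop codons included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    cluster,
    grDevices,
    graphics,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
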