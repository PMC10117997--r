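# Shared fixtures.  The benchmark corpus (5,000 ORFs, bundled human-like
# usage, median 400 codons) is generated once per session and reused by the
# corpus statistics tests and the acceptance suite.
.fixture_cache <- new.env(parent = emptyenv())

cache_fixture <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

benchmark_corpus <- function() {
  cache_fixture("corpus", function() generate_corpus(5000, seed = 101))
}

benchmark_dataset <- function() {
  cache_fixture("dataset", function() {
    split_and_batch(benchmark_corpus(), seed = 202)
  })
}

benchmark_weights <- function() {
  cache_fixture("weights", function() {
    orfs <- benchmark_corpus()
    ds <- benchmark_dataset()
    class_weights(aa_frequencies(orfs[orfs$id %in% ds$train_ids, ]))
  })
}

# deep two-hidden-layer linear MLP trained on the benchmark corpus at the
# default configuration; reused by several acceptance checks
benchmark_deep_trace <- function() {
  cache_fixture("deep_trace", function() {
    spec <- model_spec("MLP-LINEAR", scheme = "OHE64",
                       hidden_sizes = c(64L, 1024L), seed = 1303)
    train(build_model(spec), benchmark_dataset(), train_config(seed = 1404))
  })
}

# a small quick corpus for pipeline smoke tests (short ORFs -> frequent stops)
small_corpus <- function(n = 200, seed = 11) {
  generate_corpus(n, seed = seed, length_model = list(median = 30, max = 100))
}

# 4-record FASTA: one valid ORF and three single-filter violations
write_toy_fasta <- function(path) {
  writeLines(c(
    ">ok",      "ATGGCTTAA",
    ">nostop",  "ATGGCTGCT",
    ">instop",  "ATGTAAGCTTAA",
    ">badlen",  "ATGGCTTA"
  ), path)
  path
}

# linear model whose logits are exactly log(probs): lets tests decode a table
# with arbitrary prescribed probabilities
model_from_probs <- function(probs) {
  spec <- model_spec("MLP-LINEAR", scheme = "OHE64",
                     hidden_sizes = integer(0), seed = 0L)
  structure(list(spec = spec,
                 params = list(W1 = log(probs + 1e-300), b1 = numeric(21L))),
            class = "decoder_model")
}
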