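# codonDecipher

Benchmarking how much training data a neural network needs to rediscover the
standard genetic code.

## The problem

The genetic code is a fixed many-to-one map from the 64 RNA codons to the 20
amino acids plus a stop mark `*` — 21 target classes.  `codonDecipher` turns
*re-deciphering* this map into a measurable benchmark for data efficiency in
deep learning on omics data: a decoder network is shown (codon, amino-acid)
pairs harvested from open reading frames and their translated proteins, and
the package measures the cumulated number of pairs presented before the
network's decoded 64-codon table is **unequivocally complete** — every codon
called correctly by argmax, no exact probability ties, rare stop codons
included.

Accuracy is the wrong yardstick here: because codon usage is heavily biased,
any decoder reaches ~100% translation accuracy long before it has resolved
the stop codons, which occur only about once per four hundred pairs.  The
benchmark quantity is the *minimal cumulated pair count to unequivocal
deciphering*, resolved at a configurable checkpoint cadence, and the package
lets you compare it across:

* **linear MLPs** on 64-bit or 12-bit (3 × 4) one-hot codon encodings, with
  0–2 hidden layers and no activation except the final softmax;
* **embedding MLPs** with a learnable dense 64 × d codon embedding (d = 2,
  10) and ReLU/tanh hidden layers;
* **recurrent readers** (Elman RNN, GRU, LSTM; two stacked tanh cells) that
  read a codon as three nucleotide timesteps and emit one output per codon;
* unweighted versus inverse-class-frequency-weighted cross-entropy, the
  classic correction for the unbalanced amino-acid distribution.

Training corpora are either extracted from real transcript FASTA (with the
four ORF filters: `AUG` start, terminal stop, length ≡ 0 mod 3, no internal
in-frame stop) or synthesized from a codon-usage table; a human-like usage
table is bundled, so no downloads are needed.  Optimization is Adam
(lr 0.05 for MLPs, 0.005 for recurrent readers), batch 64, 90/10 ORF-level
split, epochs of 561,600 randomly subsampled pairs, a 40-epoch cap.  The MLP
training loop is compiled (RcppArmadillo); everything is seed-deterministic.

## Worked example

```r
library(codonDecipher)

orfs    <- generate_corpus(2000, seed = 1)            # synthetic human-like ORFs
dataset <- split_and_batch(orfs, seed = 2)            # 90/10 split, batch 64
spec    <- model_spec("MLP-LINEAR", scheme = "OHE64",
                      hidden_sizes = c(64, 1024), seed = 3)
model   <- build_model(spec)
model
#> decoder_model: MLP-LINEAR OHE64 64x64x1024x21
#>   parameters: 92245

trace <- train(model, dataset, train_config(seed = 4))
trace
#> training_trace: 150 iterations, 9,600 pairs presented
#>   unequivocally deciphered at 9,600 pairs (epoch 1)
#>   final test accuracy: 1.0000

data_efficiency(trace)
#> deciphered at 9,600 cumulated pairs (epoch 1, cadence 3,200 pairs)

tab <- decode_table(trace$model)
tab
#> deciphered_table: 64/64 codons correct
tab$calls[c("AUG", "UGG", "UAA", "UAG", "UGA")]
#> AUG UGG UAA UAG UGA
#> "M" "W" "*" "*" "*"
```

The trace says the two-hidden-layer linear perceptron saw 9,600
codon/amino-acid pairs (150 batches of 64) before its decoded table first
matched the standard genetic code on all 64 codons without ties, at which
point test-set translation accuracy is exactly 100%.  The rarest classes are
what this metric is gated by; inverse-frequency weights concentrate the loss
on them:

```r
w <- class_weights(aa_frequencies(orfs))
round(sort(w, decreasing = TRUE)[1:3], 2)
#>    *    W    C
#> 9.76 1.69 0.96
```

`export_snapshots(trace, "snapshots")` writes the per-checkpoint 64 × 21
probability tables as CSV and PNG heatmaps, replaying how the code's block
pattern emerges during training.

A command-line front end covering extract / run / report is installed at
`system.file("scripts", "codon-decipher.R", package = "codonDecipher")`;
runs are declared in YAML (corpus, model, training sections plus seeds) and
produce self-describing run directories.

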