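test_that("MLP layer shapes follow the spec and init is seed-deterministic", {
  spec <- model_spec("MLP-LINEAR", scheme = "OHE64",
                     hidden_sizes = c(64L, 1024L), seed = 4)
  m <- build_model(spec)
  expect_identical(dim(m$params$W1), c(64L, 64L))
  expect_identical(dim(m$params$W2), c(64L, 1024L))
  expect_identical(dim(m$params$W3), c(1024L, 21L))
  expect_identical(lengths(m$params[c("b1", "b2", "b3")]),
                   c(b1 = 64L, b2 = 1024L, b3 = 21L))
  expect_identical(m$params, build_model(spec)$params)
  spec2 <- spec; spec2$seed <- 5L
  expect_false(identical(m$params, build_model(spec2)$params))

  # 12-bit input width for the OHE12 variant
  m12 <- build_model(model_spec("MLP-LINEAR", scheme = "OHE12",
                                hidden_sizes = c(64L, 1024L)))
  expect_identical(dim(m12$params$W1), c(12L, 64L))

  # embedding variant prepends the learnable 64 x d matrix
  me <- build_model(model_spec("MLP-EMBED", embedding_d = 10,
                               hidden_sizes = c(64L, 1024L)))
  expect_identical(dim(me$params$E), c(64L, 10L))
  expect_identical(dim(me$params$W1), c(10L, 64L))
})

test_that("inconsistent specs are configuration errors", {
  expect_error(model_spec("MLP-EMBED", scheme = "OHE12", embedding_d = 2),
               "embedding")
  expect_error(model_spec("MLP-EMBED"), "embedding_d")
  expect_error(model_spec("MLP-LINEAR", activation = "relu"), "linear")
  expect_error(model_spec("MLP-LINEAR", scheme = "NUC4-SEQ3"), "recurrent")
  expect_error(model_spec("RNN", activation = "relu"), "tanh")
  expect_error(model_spec("GRU", hidden_sizes = c(8L, 8L, 8L),
                          stacked_cells = 2L), "per stacked cell")
  expect_error(forward(build_model(model_spec("MLP-LINEAR")), 99L),
               "out of range")
})

test_that("recurrent state-transition matrices are orthogonal at init", {
  for (fam in c("RNN", "GRU", "LSTM")) {
    m <- build_model(model_spec(fam, hidden_sizes = 64L, seed = 2))
    whs <- m$params[grepl("^Wh", names(m$params))]
    expect_gt(length(whs), 0)
    for (W in whs) {
      expect_lt(max(abs(crossprod(W) - diag(64))), 1e-5)
    }
  }
  # feed-forward matrices are semi-orthogonal
  m <- build_model(model_spec("MLP-LINEAR", hidden_sizes = c(64L, 1024L)))
  expect_lt(max(abs(crossprod(m$params$W3) - diag(21))), 1e-5)
})

test_that("every forward output is a probability simplex row", {
  set.seed(31)
  idx <- sample(64, 32, replace = TRUE)
  specs <- list(
    model_spec("MLP-LINEAR", scheme = "OHE64", hidden_sizes = 64L),
    model_spec("MLP-LINEAR", scheme = "OHE12", hidden_sizes = c(64L, 128L)),
    model_spec("MLP-EMBED", embedding_d = 2, hidden_sizes = 64L,
               activation = "tanh"),
    model_spec("MLP-EMBED", embedding_d = 10, hidden_sizes = c(64L, 1024L)),
    model_spec("RNN", hidden_sizes = 16L),
    model_spec("GRU", hidden_sizes = 16L),
    model_spec("LSTM", hidden_sizes = 16L))
  for (spec in specs) {
    p <- forward(build_model(spec), idx)
    expect_identical(dim(p), c(32L, 21L))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(unname(rowSums(p)), rep(1, 32), tolerance = 1e-6)
  }
})

test_that("the hand-built oracle reproduces the code and zero weights give uniform output", {
  p <- forward(oracle_model(), 1:64)
  expect_identical(amino_acids()[max.col(p, ties.method = "first")],
                   unname(standard_code()))
  zero <- oracle_model()
  zero$params$W1[] <- 0
  expect_equal(unname(forward(zero, 1:10)),
               matrix(1 / 21, 10, 21), tolerance = 1e-12)
})

test_that("softmax is invariant under per-row logit shifts", {
  m <- oracle_model()
  shifted <- m
  shifted$params$b1 <- shifted$params$b1 + 123.4
  expect_equal(forward(m, 1:64), forward(shifted, 1:64), tolerance = 1e-9)
})

test_that("a linear MLP collapses to a single 64 -> 21 affine map", {
  m <- build_model(model_spec("MLP-LINEAR", scheme = "OHE64",
                              hidden_sizes = c(64L, 1024L), seed = 12))
  p <- m$params
  A <- p$W1 %*% p$W2 %*% p$W3
  b <- drop((p$b1 %*% p$W2 + p$b2) %*% p$W3) + p$b3
  logits <- sweep(A, 2, b, "+")   # basis inputs: row c is codon c's logits
  probs <- exp(logits - apply(logits, 1, max))
  probs <- probs / rowSums(probs)
  expect_equal(unname(forward(m, 1:64)), unname(probs), tolerance = 1e-5)
})

test_that("recurrent readers reset state per codon and emit one output after 3 steps", {
  for (fam in c("RNN", "GRU", "LSTM")) {
    m <- build_model(model_spec(fam, hidden_sizes = 12L, seed = 3))
    p <- forward(m, c(17L, 17L, 5L))
    expect_equal(p[1, ], p[2, ], tolerance = 1e-12)
    # permuting the batch permutes the outputs identically
    idx <- c(1L, 33L, 64L, 12L)
    perm <- c(3L, 1L, 4L, 2L)
    expect_equal(unname(forward(m, idx)[perm, ]),
                 unname(forward(m, idx[perm])), tolerance = 1e-12)
    # raw timestep interface agrees with the codon interface
    ts <- encode_codon("AUG", "NUC4-SEQ3")
    expect_equal(unname(recurrent_read(m, ts)),
                 unname(forward(m, codonDecipher:::codon_index("AUG"))),
                 tolerance = 1e-12)
    expect_error(recurrent_read(m, matrix(0, 2, 4)), "3 timesteps")
  }
})

test_that("recurrent backpropagation matches numerical gradients", {
  loss_of <- function(model, idx, y, cw) {
    p <- forward(model, idx)
    mean(-cw[y] * log(p[cbind(seq_along(y), y)] + 1e-12))
  }
  set.seed(9)
  idx <- sample(64, 5, TRUE)
  y <- sample(21, 5, TRUE)
  cw <- runif(21, 0.5, 2)
  for (fam in c("RNN", "GRU", "LSTM")) {
    m <- build_model(model_spec(fam, hidden_sizes = 6L, seed = 7))
    fb <- codonDecipher:::rnn_forward_backward(m, idx, y, cw)
    for (nm in names(m$params)) {
      for (k in seq_len(min(3, length(m$params[[nm]])))) {
        eps <- 1e-5
        up <- m; up$params[[nm]][k] <- up$params[[nm]][k] + eps
        dn <- m; dn$params[[nm]][k] <- dn$params[[nm]][k] - eps
        num <- (loss_of(up, idx, y, cw) - loss_of(dn, idx, y, cw)) / (2 * eps)
        expect_equal(fb$grads[[nm]][k], num, tolerance = 1e-3)
      }
    }
  }
})

test_that("checkpoints round-trip spec and weights", {
  m <- build_model(model_spec("MLP-EMBED", embedding_d = 4, hidden_sizes = 8L,
                              seed = 13))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$spec, m$spec)
  expect_equal(m2$params, m$params, tolerance = 0)
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, other)
  expect_error(load_model(other), "checkpoint")
})
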