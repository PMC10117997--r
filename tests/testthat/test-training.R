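test_that("weighted cross-entropy matches its closed forms", {
  # probability 1 on the true class: zero loss
  perfect <- diag(21)[1:4, ]
  expect_equal(weighted_cross_entropy(perfect, 1:4), 0, tolerance = 1e-9)
  # uniform prediction: log(21)
  unif <- matrix(1 / 21, 3, 21)
  expect_equal(weighted_cross_entropy(unif, c(2L, 5L, 21L)), log(21),
               tolerance = 1e-9)
  # two-sample batch with weights 1 and 4 on the true classes
  w <- rep(1, 21); w[7] <- 1; w[9] <- 4
  expect_equal(weighted_cross_entropy(matrix(1 / 21, 2, 21), c(7L, 9L), w),
               (1 + 4) / 2 * log(21), tolerance = 1e-9)
  # all-ones weights equal the unweighted loss exactly
  set.seed(5)
  p <- matrix(stats::rexp(10 * 21), 10)
  p <- p / rowSums(p)
  y <- sample(21, 10, TRUE)
  expect_identical(weighted_cross_entropy(p, y, rep(1, 21)),
                   weighted_cross_entropy(p, y))
  # one-hot targets and index targets agree
  Y <- diag(21)[y, ]
  expect_identical(weighted_cross_entropy(p, Y), weighted_cross_entropy(p, y))
})

test_that("accuracy counts argmax matches with lowest-index tie-breaking", {
  t4 <- diag(21)[c(1, 2, 3, 4), ]
  expect_identical(accuracy(t4, 1:4), 1)
  expect_identical(accuracy(t4, c(5L, 6L, 7L, 8L)), 0)
  expect_identical(accuracy(t4, c(1L, 2L, 3L, 9L)), 0.75)
  tie <- matrix(0, 1, 21); tie[1, 1] <- 0.5; tie[1, 2] <- 0.5
  expect_identical(accuracy(tie, 1L), 1)   # tie resolved to class 1
  expect_identical(accuracy(tie, 2L), 0)
})

test_that("the C++ training kernel reproduces a reference R implementation", {
  r_reference <- function(params, idx, y, starts, cw, lr, act) {
    m <- lapply(params, function(p) p * 0); v <- m; t <- 0
    for (it in seq_len(length(starts) - 1L)) {
      sel <- (starts[it] + 1L):(starts[it + 1L]); B <- length(sel)
      E <- params[[1]]
      X <- E[idx[sel], , drop = FALSE]
      H <- sweep(X %*% params[[2]], 2, params[[3]], "+")
      Ha <- if (act == "relu") pmax(H, 0) else tanh(H)
      Z <- sweep(Ha %*% params[[4]], 2, params[[5]], "+")
      P <- exp(Z - apply(Z, 1, max)); P <- P / rowSums(P)
      G <- P; G[cbind(1:B, y[sel])] <- G[cbind(1:B, y[sel])] - 1
      G <- G * cw[y[sel]] / B
      dW2 <- crossprod(Ha, G); db2 <- colSums(G)
      dH <- tcrossprod(G, params[[4]]) *
        (if (act == "relu") (Ha > 0) + 0 else 1 - Ha^2)
      dW1 <- crossprod(X, dH); db1 <- colSums(dH)
      dX <- tcrossprod(dH, params[[2]])
      dE <- matrix(0, 64, ncol(E))
      for (i in 1:B) dE[idx[sel][i], ] <- dE[idx[sel][i], ] + dX[i, ]
      g <- list(dE, dW1, db1, dW2, db2)
      t <- t + 1
      for (j in 1:5) {
        m[[j]] <- 0.9 * m[[j]] + 0.1 * g[[j]]
        v[[j]] <- 0.999 * v[[j]] + 0.001 * g[[j]]^2
        params[[j]] <- params[[j]] -
          lr * (m[[j]] / (1 - 0.9^t)) / (sqrt(v[[j]] / (1 - 0.999^t)) + 1e-8)
      }
    }
    params
  }
  set.seed(11)
  params <- list(matrix(stats::rnorm(64 * 3), 64),
                 matrix(stats::rnorm(3 * 8), 3), numeric(8),
                 matrix(stats::rnorm(8 * 21), 8), numeric(21))
  zero <- lapply(params, function(p) p * 0)
  n <- 4L; B <- 6L
  idx <- sample(64, n * B, TRUE); y <- sample(21, n * B, TRUE)
  starts <- seq(0L, n * B, by = B)
  cw <- stats::runif(21, 0.5, 2)
  res <- codonDecipher:::.nn_train_chunk_cpp(
    params, zero, zero, 0L, idx, y, starts, matrix(0, 1, 1), TRUE, 1L, cw,
    0.05, 0.9, 0.999, 1e-8)
  ref <- r_reference(params, idx, y, starts, cw, 0.05, "relu")
  for (j in 1:5) expect_equal(res$params[[j]], ref[[j]], tolerance = 1e-12)
})

test_that("the oracle decoder is a training fixed point at zero pairs", {
  ds <- split_and_batch(small_corpus(), seed = 2)
  tr <- train(oracle_model(), ds,
              train_config(max_epochs = 1L, epoch_pairs = 640L,
                           check_every = 5L, seed = 3))
  expect_true(tr$deciphered)
  expect_identical(tr$pairs_at_deciphering, 0)
  eff <- data_efficiency(tr)
  expect_true(eff$deciphered)
  expect_identical(eff$pairs_at_deciphering, 0)
  expect_identical(tr$test_accuracy, 1)
  expect_identical(nrow(tr$log), 0L)  # stopped before any update

  # trained past the fixed point: accuracy 1 and near-zero loss at iteration 1
  tr2 <- train(oracle_model(), ds,
               train_config(max_epochs = 1L, epoch_pairs = 640L,
                            check_every = 5L, seed = 3,
                            stop_when_deciphered = FALSE))
  expect_identical(tr2$log$train_accuracy[1], 1)
  expect_lt(tr2$log$loss[1], 1e-8)
})

test_that("a zero learning rate leaves the model untouched", {
  ds <- split_and_batch(small_corpus(), seed = 2)
  m <- build_model(model_spec("MLP-LINEAR", hidden_sizes = 16L, seed = 8))
  tr <- train(m, ds, train_config(learning_rate = 0, max_epochs = 1L,
                                  epoch_pairs = 1280L, check_every = 10L,
                                  seed = 4))
  expect_equal(tr$model$params, m$params, tolerance = 0)
  expect_false(tr$deciphered)
})

test_that("cumulated pair accounting matches the iteration ledger", {
  ds <- split_and_batch(small_corpus(), seed = 2)
  m <- build_model(model_spec("MLP-LINEAR", hidden_sizes = 16L, seed = 8))
  cfg <- train_config(max_epochs = 2L, epoch_pairs = 1280L, check_every = 7L,
                      seed = 4, stop_when_deciphered = FALSE)
  tr <- train(m, ds, cfg)
  expect_identical(nrow(tr$log), 2L * 1280L %/% 64L)
  expect_identical(tr$log$iteration, seq_len(nrow(tr$log)))
  expect_identical(tr$log$cumulated_pairs, tr$log$iteration * 64L)
  expect_identical(tr$cumulated_pairs, 2 * 1280)
  expect_true(all(diff(tr$checks$cumulated_pairs) > 0))
  expect_identical(tr$checks$iteration[1], 0L)
  # epoch cap arithmetic: 40 epochs x 561,600 pairs would cumulate 22,464,000
  expect_identical(40L * train_config()$epoch_pairs, 22464000L)
  # max_pairs cap truncates the run
  tr2 <- train(m, ds, train_config(max_epochs = 2L, epoch_pairs = 1280L,
                                   check_every = 7L, seed = 4,
                                   stop_when_deciphered = FALSE,
                                   max_pairs = 700))
  expect_lt(abs(tr2$cumulated_pairs - 704), 65)  # next batch boundary
})

test_that("identical seeds reproduce the whole trace", {
  ds <- split_and_batch(small_corpus(), seed = 2)
  run <- function() {
    m <- build_model(model_spec("MLP-EMBED", embedding_d = 4,
                                hidden_sizes = 16L, seed = 5))
    train(m, ds, train_config(max_epochs = 1L, epoch_pairs = 640L,
                              check_every = 5L, seed = 6,
                              stop_when_deciphered = FALSE))
  }
  a <- run(); b <- run()
  expect_identical(a$log, b$log)
  expect_equal(a$model$params, b$model$params, tolerance = 0)
  expect_identical(a$checks, b$checks)
})

test_that("recurrent training reduces the loss", {
  ds <- split_and_batch(small_corpus(), seed = 2)
  m <- build_model(model_spec("GRU", hidden_sizes = 16L, seed = 5))
  tr <- train(m, ds, train_config(max_epochs = 1L, epoch_pairs = 12800L,
                                  check_every = 50L, seed = 6,
                                  stop_when_deciphered = FALSE))
  n <- nrow(tr$log)
  expect_identical(n, 200L)
  expect_lt(mean(tr$log$loss[(n - 39):n]), mean(tr$log$loss[1:40]))
  # the default recurrent learning rate is the small one
  expect_identical(tr$learning_rate, 0.005)
})
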