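#' Training configuration
#'
#' Collects the optimization settings.  The learning-rate default depends on
#' the model family (0.05 for the MLPs, 0.005 for the recurrent readers) and
#' is resolved inside [train()] when left `NULL`.  An *epoch* is one pass over
#' a fixed-size random subsample of `epoch_pairs` training pairs, resampled
#' every epoch; with the defaults (561,600 pairs, batch 64) an epoch is 8,775
#' iterations, so 40 epochs present 22,464,000 cumulated pairs.
#'
#' @param learning_rate Adam step size, or `NULL` for the family default.
#' @param max_epochs Training cap in epochs (default 40).
#' @param batch_size Pairs per batch (default 64).
#' @param epoch_pairs Pairs presented per epoch (default 561,600; must be a
#'   multiple of `batch_size`).
#' @param class_weights Optional 21-vector of loss weights (see
#'   [class_weights()]); `NULL` means unweighted.
#' @param seed Integer seed driving epoch subsampling and batch order.
#' @param check_every Iterations between deciphering checks (default 50, i.e.
#'   every 3,200 pairs at batch 64); the data-efficiency metric is resolved at
#'   this granularity.
#' @param snapshot_every Keep a full 64 x 21 probability snapshot every this
#'   many checks (default 20); the first complete table and the final table
#'   are always kept.
#' @param stop_when_deciphered Stop as soon as the decoded table is
#'   unequivocally complete (default `TRUE`).
#' @param max_pairs Optional cap on cumulated training pairs (default `Inf`).
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer
#'   (conventional defaults).
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = NULL, max_epochs = 40L,
                         batch_size = 64L, epoch_pairs = 561600L,
                         class_weights = NULL, seed = 1L, check_every = 50L,
                         snapshot_every = 20L, stop_when_deciphered = TRUE,
                         max_pairs = Inf, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8) {
  stopifnot(is.null(learning_rate) || learning_rate >= 0,
            max_epochs >= 0, batch_size >= 1, epoch_pairs >= 1,
            check_every >= 1, snapshot_every >= 1, max_pairs > 0)
  if (epoch_pairs %% batch_size != 0) {
    stop("epoch_pairs must be a multiple of batch_size", call. = FALSE)
  }
  if (!is.null(class_weights)) {
    stopifnot(is.numeric(class_weights), length(class_weights) == 21L,
              all(is.finite(class_weights)), all(class_weights > 0))
  }
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 epoch_pairs = as.integer(epoch_pairs),
                 class_weights = class_weights, seed = as.integer(seed),
                 check_every = as.integer(check_every),
                 snapshot_every = as.integer(snapshot_every),
                 stop_when_deciphered = isTRUE(stop_when_deciphered),
                 max_pairs = max_pairs, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon),
            class = "train_config")
}

#' Weighted multinomial cross-entropy
#'
#' Mean over the batch of `-w[class] * log p[class]`, where `class` is the
#' true class of each row; `w` defaults to all ones.  Predicted probabilities
#' are guarded by an epsilon of `1e-12` inside the log.
#'
#' @param pred Numeric matrix (batch x 21) of predicted probabilities.
#' @param target One-hot matrix (batch x 21) or integer class indices.
#' @param weights Optional 21-vector of class weights.
#' @return Scalar loss.
#' @export
#' @examples
#' p <- matrix(1 / 21, 1, 21)
#' weighted_cross_entropy(p, 1L)  # log(21)
weighted_cross_entropy <- function(pred, target, weights = NULL) {
  pred <- as.matrix(pred)
  y <- target_index(target, nrow(pred))
  w <- if (is.null(weights)) rep(1, 21) else weights
  mean(-w[y] * log(pred[cbind(seq_len(nrow(pred)), y)] + 1e-12))
}

#' Argmax translation accuracy
#'
#' Fraction of rows whose predicted argmax class equals the target class;
#' probability ties are broken toward the lowest class index.
#'
#' @inheritParams weighted_cross_entropy
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(pred, target) {
  pred <- as.matrix(pred)
  y <- target_index(target, nrow(pred))
  mean(max.col(pred, ties.method = "first") == y)
}

target_index <- function(target, n) {
  if (is.matrix(target)) {
    y <- max.col(target, ties.method = "first")
  } else {
    y <- as.integer(target)
  }
  stopifnot(length(y) == n, all(y >= 1L), all(y <= 21L))
  y
}

# one Adam step on a named parameter list (R-side path, recurrent families)
adam_step_r <- function(params, grads, state, lr, b1, b2, eps) {
  t <- state$t + 1L
  c1 <- 1 / (1 - b1^t)
  c2 <- 1 / (1 - b2^t)
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] * c1) / (sqrt(state$v[[nm]] * c2) + eps)
  }
  state$t <- t
  list(params = params, state = state)
}

#' Train a decoder and log the deciphering trajectory
#'
#' Runs Adam on weighted multinomial cross-entropy over batches of
#' codon/amino-acid pairs.  Every `check_every` iterations (and once at
#' iteration 0, before any update) the full 64-codon table is decoded and
#' judged against the standard code; training stops at the first unequivocally
#' complete table (when `stop_when_deciphered`), at `max_epochs`, or at
#' `max_pairs` cumulated pairs, whichever comes first.  Identical seeds
#' (corpus, split, model, config) reproduce the trace exactly.
#'
#' @param model A `decoder_model` from [build_model()].
#' @param dataset A `pair_dataset` from [split_and_batch()].
#' @param config A [train_config()].
#' @return A `training_trace` with the per-iteration `log` (iteration, epoch,
#'   cumulated pairs, loss, training accuracy), the deciphering `checks`
#'   table, retained probability `snapshots`, per-epoch test accuracy, the
#'   trained `model`, and the deciphering outcome.
#' @export
train <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "decoder_model"),
            inherits(dataset, "pair_dataset"),
            inherits(config, "train_config"))
  spec <- model$spec
  mlp <- spec$family %in% c("MLP-LINEAR", "MLP-EMBED")
  lr <- config$learning_rate %||% if (mlp) 0.05 else 0.005
  cw <- config$class_weights %||% rep(1, 21)
  reference <- standard_code()
  batch <- config$batch_size
  n_pool <- length(dataset$train_codon)
  if (n_pool < 1L) stop("empty training set", call. = FALSE)
  test_counts <- tabulate(dataset$test_codon, nbins = 64L)

  params <- model$params
  zero <- lapply(params, function(x) x * 0)
  state <- list(m = zero, v = zero, t = 0L)
  enc <- if (!mlp || spec$family == "MLP-EMBED") matrix(0, 1, 1) else
    codon_encoding_matrix(spec$scheme$name)
  embed <- spec$family == "MLP-EMBED"
  act <- act_code(spec$activation)

  cur_model <- function() {
    model$params <- params
    model
  }
  test_acc_of <- function(calls_ok) {
    if (sum(test_counts) == 0L) return(NA_real_)
    sum(test_counts[calls_ok]) / sum(test_counts)
  }

  log_it <- list(); log_ep <- list(); log_loss <- list(); log_acc <- list()
  checks <- list()
  snapshots <- list()
  epoch_test <- list()
  iteration <- 0L
  pairs <- 0
  deciphered <- FALSE
  pairs_at <- NA_real_
  epoch_at <- NA_integer_
  diverged <- FALSE
  n_checks <- 0L

  run_check <- function(epoch) {
    tab <- decode_table(cur_model())
    uneq <- is_unequivocal(tab, reference)
    n_checks <<- n_checks + 1L
    checks[[n_checks]] <<- data.frame(
      iteration = iteration, epoch = epoch, cumulated_pairs = pairs,
      unequivocal = uneq, n_mismatches = nrow(tab$mismatches))
    first_hit <- uneq && !deciphered
    if (first_hit) {
      deciphered <<- TRUE
      pairs_at <<- pairs
      epoch_at <<- epoch
    }
    if (first_hit || (n_checks - 1L) %% config$snapshot_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <<-
        list(iteration = iteration, cumulated_pairs = pairs, table = tab)
    }
    tab
  }

  tab <- run_check(0L)
  done <- deciphered && config$stop_when_deciphered

  epoch <- 0L
  with_seed(config$seed, {
    while (!done && epoch < config$max_epochs) {
      epoch <- epoch + 1L
      sampled <- sample.int(n_pool, config$epoch_pairs,
                            replace = config$epoch_pairs > n_pool)
      ep_codon <- dataset$train_codon[sampled]
      ep_aa <- dataset$train_aa[sampled]
      n_iter_epoch <- config$epoch_pairs %/% batch
      it_done <- 0L
      while (it_done < n_iter_epoch && !done) {
        n_it <- min(config$check_every, n_iter_epoch - it_done)
        if (is.finite(config$max_pairs)) {
          n_it <- min(n_it, ceiling((config$max_pairs - pairs) / batch))
        }
        lo <- it_done * batch
        starts <- seq.int(0L, n_it * batch, by = batch)
        sel <- (lo + 1L):(lo + n_it * batch)
        if (mlp) {
          res <- .nn_train_chunk_cpp(unname(params), unname(state$m),
                                     unname(state$v), state$t,
                                     ep_codon[sel], ep_aa[sel], starts, enc,
                                     embed, act, cw, lr, config$beta1,
                                     config$beta2, config$epsilon)
          params <- stats::setNames(res$params, names(params))
          state$m <- stats::setNames(res$m, names(params))
          state$v <- stats::setNames(res$v, names(params))
          state$t <- state$t + n_it
          loss_vec <- res$loss
          acc_vec <- res$acc
        } else {
          loss_vec <- numeric(n_it)
          acc_vec <- numeric(n_it)
          for (k in seq_len(n_it)) {
            rows <- (lo + (k - 1L) * batch + 1L):(lo + k * batch)
            fb <- rnn_forward_backward(cur_model(), ep_codon[rows],
                                       ep_aa[rows], cw)
            upd <- adam_step_r(params, fb$grads, state, lr, config$beta1,
                               config$beta2, config$epsilon)
            params <- upd$params
            state <- upd$state
            loss_vec[k] <- fb$loss
            acc_vec[k] <- fb$acc
          }
        }
        it_done <- it_done + n_it
        iteration <- iteration + n_it
        pairs <- pairs + n_it * batch
        log_it[[length(log_it) + 1L]] <- iteration - rev(seq_len(n_it)) + 1L
        log_ep[[length(log_ep) + 1L]] <- rep.int(epoch, n_it)
        log_loss[[length(log_loss) + 1L]] <- loss_vec
        log_acc[[length(log_acc) + 1L]] <- acc_vec
        if (any(!is.finite(loss_vec))) {
          diverged <- TRUE
          warning(sprintf("training diverged (non-finite loss) at iteration %d",
                          iteration), call. = FALSE)
          done <- TRUE
        }
        tab <- run_check(epoch)
        if (deciphered && config$stop_when_deciphered) done <- TRUE
        if (pairs >= config$max_pairs) done <- TRUE
      }
      ok <- tab$calls == reference
      epoch_test[[length(epoch_test) + 1L]] <-
        data.frame(epoch = epoch, test_accuracy = test_acc_of(ok))
    }
  })

  # final snapshot if the last check was not retained
  if (length(snapshots) == 0L ||
      snapshots[[length(snapshots)]]$iteration != iteration) {
    snapshots[[length(snapshots) + 1L]] <-
      list(iteration = iteration, cumulated_pairs = pairs, table = tab)
  }

  structure(list(
    log = data.frame(
      iteration = unlist(log_it) %||% integer(0),
      epoch = unlist(log_ep) %||% integer(0),
      cumulated_pairs = (unlist(log_it) %||% integer(0)) * batch,
      loss = unlist(log_loss) %||% numeric(0),
      train_accuracy = unlist(log_acc) %||% numeric(0)),
    checks = do.call(rbind, checks),
    snapshots = snapshots,
    epoch_test = if (length(epoch_test)) do.call(rbind, epoch_test) else
      data.frame(epoch = integer(0), test_accuracy = numeric(0)),
    test_accuracy = test_acc_of(tab$calls == reference),
    model = cur_model(),
    config = config,
    learning_rate = lr,
    deciphered = deciphered,
    pairs_at_deciphering = pairs_at,
    epoch_at_deciphering = epoch_at,
    cumulated_pairs = pairs,
    diverged = diverged
  ), class = "training_trace")
}

#' @export
print.training_trace <- function(x, ...) {
  cat(sprintf("training_trace: %d iterations, %s pairs presented\n",
              nrow(x$log), format(x$cumulated_pairs, big.mark = ",")))
  if (x$deciphered) {
    cat(sprintf("  unequivocally deciphered at %s pairs (epoch %d)\n",
                format(x$pairs_at_deciphering, big.mark = ","),
                x$epoch_at_deciphering))
  } else {
    cat("  not unequivocally deciphered within the cap\n")
  }
  cat(sprintf("  final test accuracy: %s\n",
              ifelse(is.na(x$test_accuracy), "NA",
                     sprintf("%.4f", x$test_accuracy))))
  invisible(x)
}

#' Write the per-iteration training log as CSV
#'
#' @param trace A `training_trace`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace$log, path, row.names = FALSE)
  invisible(path)
}
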