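#' Specify a decoder architecture
#'
#' Declares one member of the model zoo behind a single forward-pass
#' contract: every model maps one codon to a 21-class probability simplex.
#'
#' * `MLP-LINEAR` — fully connected perceptron on `OHE64` or `OHE12` inputs
#'   with no activation function anywhere except the final softmax;
#' * `MLP-EMBED` — learnable 64 x d codon embedding feeding hidden layers
#'   with `relu` or `tanh` activations;
#' * `RNN`, `GRU`, `LSTM` — recurrent readers consuming the three nucleotide
#'   one-hot timesteps of a codon through `stacked_cells` stacked cells
#'   (`tanh` by construction) and emitting one output after the third step.
#'
#' @param family One of `"MLP-LINEAR"`, `"MLP-EMBED"`, `"RNN"`, `"GRU"`,
#'   `"LSTM"`.
#' @param scheme Input encoding for `MLP-LINEAR` (`"OHE64"` or `"OHE12"`).
#'   Recurrent families always read `NUC4-SEQ3`; supplying a one-hot scheme
#'   together with `MLP-EMBED` is a configuration error.
#' @param hidden_sizes Integer vector of hidden-layer widths for the MLP
#'   families (e.g. `c(64, 1024)`), or the per-cell hidden size(s) for the
#'   recurrent families.
#' @param activation `"none"` (forced for `MLP-LINEAR`), `"relu"` or `"tanh"`
#'   for `MLP-EMBED`; recurrent cells are `tanh` by construction.
#' @param embedding_d Embedding dimensionality for `MLP-EMBED` (e.g. 2 or 10).
#' @param stacked_cells Number of stacked recurrent cells (default 2).
#' @param seed Integer seed for deterministic initialization.
#' @return A `model_spec` object.
#' @export
#' @examples
#' model_spec("MLP-LINEAR", hidden_sizes = c(64, 1024))
#' model_spec("MLP-EMBED", embedding_d = 10, hidden_sizes = c(64, 1024))
model_spec <- function(family = c("MLP-LINEAR", "MLP-EMBED", "RNN", "GRU", "LSTM"),
                       scheme = NULL, hidden_sizes = 64L, activation = NULL,
                       embedding_d = NULL, stacked_cells = 2L, seed = 1L) {
  family <- match.arg(family)
  hidden_sizes <- as.integer(hidden_sizes)
  stopifnot(all(hidden_sizes >= 1))
  recurrent <- family %in% c("RNN", "GRU", "LSTM")

  if (family == "MLP-LINEAR") {
    if (!is.null(activation) && activation != "none") {
      stop("MLP-LINEAR is fully linear: activation must be 'none'", call. = FALSE)
    }
    activation <- "none"
    scheme <- encoding_scheme(scheme %||% "OHE64")
    if (scheme$name == "NUC4-SEQ3") {
      stop("NUC4-SEQ3 is the recurrent input format; MLP-LINEAR needs OHE64 or OHE12",
           call. = FALSE)
    }
    if (!is.null(embedding_d)) {
      stop("embedding_d applies to MLP-EMBED only", call. = FALSE)
    }
  } else if (family == "MLP-EMBED") {
    if (!is.null(scheme)) {
      stop("MLP-EMBED replaces the one-hot scheme with a learnable embedding; do not set 'scheme'",
           call. = FALSE)
    }
    if (is.null(embedding_d)) {
      stop("MLP-EMBED requires embedding_d", call. = FALSE)
    }
    embedding_d <- as.integer(embedding_d)
    stopifnot(embedding_d >= 1)
    activation <- match.arg(activation %||% "relu", c("relu", "tanh"))
  } else {
    if (!is.null(activation) && activation != "tanh") {
      stop(sprintf("%s cells use tanh by construction", family), call. = FALSE)
    }
    activation <- "tanh"
    scheme <- encoding_scheme("NUC4-SEQ3")
    stacked_cells <- as.integer(stacked_cells)
    stopifnot(stacked_cells >= 1)
    if (length(hidden_sizes) == 1L) {
      hidden_sizes <- rep(hidden_sizes, stacked_cells)
    }
    if (length(hidden_sizes) != stacked_cells) {
      stop("hidden_sizes must give one size per stacked cell", call. = FALSE)
    }
  }
  structure(list(family = family, scheme = scheme,
                 hidden_sizes = hidden_sizes, activation = activation,
                 embedding_d = embedding_d,
                 stacked_cells = if (recurrent) stacked_cells else NULL,
                 seed = as.integer(seed)),
            class = "model_spec")
}

# (semi-)orthogonal init: orthonormal columns when nr >= nc, orthonormal rows
# otherwise; sign-fixed so the result is a deterministic function of the RNG
# draw.
orth_init <- function(nr, nc) {
  n <- max(nr, nc)
  a <- matrix(stats::rnorm(n * min(nr, nc)), nrow = n)
  qr_ <- qr(a)
  q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))), min(nr, nc))
  if (nr >= nc) q[seq_len(nr), , drop = FALSE] else t(q)[seq_len(nr), , drop = FALSE]
}

#' Build a decoder with initialized weights
#'
#' Weight matrices are initialized (semi-)orthogonally — in particular the
#' square recurrent state-transition matrices are exactly orthogonal, the
#' usual guard against vanishing/exploding gradients through time — biases at
#' zero, and embedding rows i.i.d. normal with sd `1/sqrt(d)`.  Initialization
#' is a deterministic function of `spec$seed`.
#'
#' @param spec A [model_spec()].
#' @return A `decoder_model` object (fields `spec` and `params`).
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  recurrent <- spec$family %in% c("RNN", "GRU", "LSTM")
  params <- with_seed(spec$seed, {
    p <- list()
    if (spec$family %in% c("MLP-LINEAR", "MLP-EMBED")) {
      in_w <- if (spec$family == "MLP-EMBED") spec$embedding_d else spec$scheme$width
      if (spec$family == "MLP-EMBED") {
        p$E <- matrix(stats::rnorm(64L * in_w, sd = 1 / sqrt(in_w)), nrow = 64L)
      }
      widths <- c(in_w, spec$hidden_sizes, 21L)
      for (l in seq_len(length(widths) - 1L)) {
        p[[paste0("W", l)]] <- orth_init(widths[l], widths[l + 1L])
        p[[paste0("b", l)]] <- numeric(widths[l + 1L])
      }
    } else {
      gates <- switch(spec$family, RNN = "", GRU = c("z", "r", "n"),
                      LSTM = c("i", "f", "g", "o"))
      in_w <- 4L
      for (l in seq_len(spec$stacked_cells)) {
        h <- spec$hidden_sizes[l]
        for (g in gates) {
          p[[paste0("Wx", g, l)]] <- orth_init(in_w, h)
          p[[paste0("Wh", g, l)]] <- orth_init(h, h)
          p[[paste0("b", g, l)]] <- numeric(h)
        }
        in_w <- h
      }
      p$Wy <- orth_init(in_w, 21L)
      p$by <- numeric(21L)
    }
    p
  })
  structure(list(spec = spec, params = params), class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("decoder_model: %s\n", architecture_label(x)))
  cat(sprintf("  parameters: %d\n",
              sum(vapply(x$params, length, integer(1)))))
  invisible(x)
}

#' Human-readable architecture label
#'
#' @param model A `decoder_model`.
#' @return A single string such as `"MLP-LINEAR OHE64 64x64x1024x21"`.
#' @export
architecture_label <- function(model) {
  s <- model$spec
  if (s$family == "MLP-EMBED") {
    sprintf("MLP-EMBED d=%d %s (%s)", s$embedding_d,
            paste(c(s$embedding_d, s$hidden_sizes, 21L), collapse = "x"),
            s$activation)
  } else if (s$family == "MLP-LINEAR") {
    sprintf("MLP-LINEAR %s %s", s$scheme$name,
            paste(c(s$scheme$width, s$hidden_sizes, 21L), collapse = "x"))
  } else {
    sprintf("%s %d cells 12x%sx21", s$family, s$stacked_cells,
            paste(s$hidden_sizes, collapse = "x"))
  }
}

# ---- forward pass -----------------------------------------------------------

act_code <- function(activation) {
  switch(activation, none = 0L, relu = 1L, tanh = 2L)
}

#' Forward pass: codons to class probabilities
#'
#' @param model A `decoder_model`.
#' @param x Codon strings or canonical codon indices (1..64).
#' @return Numeric matrix (length(x) x 21) of row-stochastic probabilities,
#'   columns named by [amino_acids()].
#' @export
#' @examples
#' m <- oracle_model()
#' p <- forward(m, c("AUG", "UAA"))
#' colnames(p)[max.col(p)]  # "M" "*"
forward <- function(model, x) {
  stopifnot(inherits(model, "decoder_model"))
  idx <- if (is.character(x)) codon_index(x) else as.integer(x)
  if (any(idx < 1L | idx > 64L)) stop("codon index out of range", call. = FALSE)
  s <- model$spec
  if (s$family %in% c("MLP-LINEAR", "MLP-EMBED")) {
    embed <- s$family == "MLP-EMBED"
    enc <- if (embed) matrix(0, 1, 1) else codon_encoding_matrix(s$scheme$name)
    p <- .nn_forward_cpp(unname(model$params), idx, enc, embed,
                         act_code(s$activation))
  } else {
    p <- rnn_apply(model, idx)$probs
  }
  dimnames(p) <- list(codons()[idx], amino_acids())
  p
}

#' @rdname forward
#' @param object,newdata,... standard [stats::predict()] arguments; `newdata`
#'   is passed to `forward()` as `x`.
#' @export
predict.decoder_model <- function(object, newdata, ...) forward(object, newdata)

#' Read one codon as three nucleotide timesteps
#'
#' The recurrent interface: the hidden state is freshly initialized, the three
#' 4-bit nucleotide vectors are read in order, and a single 21-class
#' distribution is emitted after the third timestep only.
#'
#' @param model A recurrent `decoder_model` (`RNN`, `GRU` or `LSTM`).
#' @param timesteps A 3 x 4 matrix (one codon) or a B x 3 x 4 array of
#'   per-nucleotide one-hot rows.
#' @return Numeric matrix (B x 21) of probabilities.
#' @export
recurrent_read <- function(model, timesteps) {
  stopifnot(inherits(model, "decoder_model"),
            model$spec$family %in% c("RNN", "GRU", "LSTM"))
  if (is.matrix(timesteps)) {
    timesteps <- array(timesteps, dim = c(1L, dim(timesteps)))
  }
  d <- dim(timesteps)
  if (length(d) != 3L || d[2] != 3L || d[3] != 4L) {
    stop("recurrent input must be 3 timesteps of 4-bit nucleotide vectors",
         call. = FALSE)
  }
  xs <- lapply(1:3, function(t) matrix(timesteps[, t, ], ncol = 4L))
  p <- rnn_stack_forward(model$spec, model$params, xs)$probs
  colnames(p) <- amino_acids()
  p
}

# gather the 3 x 4 timesteps for a batch of codon indices
gather_timesteps <- function(idx) {
  ts <- codon_timesteps()
  lapply(1:3, function(t) matrix(ts[idx, t, ], ncol = 4L))
}

rnn_apply <- function(model, idx) {
  rnn_stack_forward(model$spec, model$params, gather_timesteps(idx))
}

sigm <- function(x) 1 / (1 + exp(-x))

# Forward through the stacked recurrent cells; returns probs plus the caches
# needed for backpropagation through the 3 timesteps.
rnn_stack_forward <- function(spec, params, xs) {
  B <- nrow(xs[[1]])
  caches <- vector("list", spec$stacked_cells)
  inputs <- xs
  for (l in seq_len(spec$stacked_cells)) {
    h <- matrix(0, B, spec$hidden_sizes[l])
    cache <- list(inputs = inputs, steps = vector("list", 3L))
    if (spec$family == "RNN") {
      Wx <- params[[paste0("Wx", l)]]; Wh <- params[[paste0("Wh", l)]]
      b <- params[[paste0("b", l)]]
      for (t in 1:3) {
        h_prev <- h
        h <- tanh(sweep(inputs[[t]] %*% Wx + h_prev %*% Wh, 2, b, "+"))
        cache$steps[[t]] <- list(h = h, h_prev = h_prev)
      }
    } else if (spec$family == "GRU") {
      g <- function(nm) params[[paste0(nm, l)]]
      for (t in 1:3) {
        h_prev <- h
        x <- inputs[[t]]
        z <- sigm(sweep(x %*% g("Wxz") + h_prev %*% g("Whz"), 2, g("bz"), "+"))
        r <- sigm(sweep(x %*% g("Wxr") + h_prev %*% g("Whr"), 2, g("br"), "+"))
        hn <- h_prev %*% g("Whn")
        n <- tanh(sweep(x %*% g("Wxn") + r * hn, 2, g("bn"), "+"))
        h <- (1 - z) * n + z * h_prev
        cache$steps[[t]] <- list(h = h, h_prev = h_prev, z = z, r = r,
                                 n = n, hn = hn)
      }
    } else {  # LSTM
      g <- function(nm) params[[paste0(nm, l)]]
      cst <- matrix(0, B, spec$hidden_sizes[l])
      for (t in 1:3) {
        h_prev <- h; c_prev <- cst
        x <- inputs[[t]]
        i_ <- sigm(sweep(x %*% g("Wxi") + h_prev %*% g("Whi"), 2, g("bi"), "+"))
        f_ <- sigm(sweep(x %*% g("Wxf") + h_prev %*% g("Whf"), 2, g("bf"), "+"))
        gg <- tanh(sweep(x %*% g("Wxg") + h_prev %*% g("Whg"), 2, g("bg"), "+"))
        o_ <- sigm(sweep(x %*% g("Wxo") + h_prev %*% g("Who"), 2, g("bo"), "+"))
        cst <- f_ * c_prev + i_ * gg
        tc <- tanh(cst)
        h <- o_ * tc
        cache$steps[[t]] <- list(h = h, h_prev = h_prev, c_prev = c_prev,
                                 i = i_, f = f_, g = gg, o = o_, tc = tc)
      }
    }
    caches[[l]] <- cache
    inputs <- lapply(cache$steps, `[[`, "h")
  }
  h3 <- inputs[[3]]
  z <- sweep(h3 %*% params$Wy, 2, params$by, "+")
  z <- z - apply(z, 1, max)
  p <- exp(z)
  p <- p / rowSums(p)
  list(probs = p, h3 = h3, caches = caches)
}

# Full forward + backward for the recurrent families.  y: class indices 1..21;
# class_w: 21 loss weights.  Returns loss, accuracy and gradients named like
# the parameter list.
rnn_forward_backward <- function(model, idx, y, class_w = rep(1, 21)) {
  spec <- model$spec; params <- model$params
  fw <- rnn_stack_forward(spec, params, gather_timesteps(idx))
  p <- fw$probs
  B <- nrow(p)
  w <- class_w[y]
  picked <- p[cbind(seq_len(B), y)]
  loss <- mean(-w * log(picked + 1e-12))
  acc <- mean(max.col(p, ties.method = "first") == y)

  grads <- lapply(params, function(x) x * 0)
  G <- p
  G[cbind(seq_len(B), y)] <- G[cbind(seq_len(B), y)] - 1
  G <- G * w / B
  grads$Wy <- crossprod(fw$h3, G)
  grads$by <- colSums(G)
  dh_out <- list(0, 0, G %*% t(params$Wy))

  for (l in rev(seq_len(spec$stacked_cells))) {
    cache <- fw$caches[[l]]
    dX <- vector("list", 3L)
    dh_acc <- 0; dc_acc <- 0
    for (t in 3:1) {
      st <- cache$steps[[t]]
      x <- cache$inputs[[t]]
      dh <- dh_out[[t]] + dh_acc
      if (spec$family == "RNN") {
        da <- dh * (1 - st$h^2)
        grads[[paste0("Wx", l)]] <- grads[[paste0("Wx", l)]] + crossprod(x, da)
        grads[[paste0("Wh", l)]] <- grads[[paste0("Wh", l)]] + crossprod(st$h_prev, da)
        grads[[paste0("b", l)]] <- grads[[paste0("b", l)]] + colSums(da)
        dX[[t]] <- da %*% t(params[[paste0("Wx", l)]])
        dh_acc <- da %*% t(params[[paste0("Wh", l)]])
      } else if (spec$family == "GRU") {
        gp <- function(nm) params[[paste0(nm, l)]]
        add <- function(nm, v) grads[[paste0(nm, l)]] <<- grads[[paste0(nm, l)]] + v
        dz <- dh * (st$h_prev - st$n)
        dn <- dh * (1 - st$z)
        dh_prev <- dh * st$z
        dan <- dn * (1 - st$n^2)
        dhn <- dan * st$r
        dr <- dan * st$hn
        daz <- dz * st$z * (1 - st$z)
        dar <- dr * st$r * (1 - st$r)
        add("Wxn", crossprod(x, dan)); add("Whn", crossprod(st$h_prev, dhn))
        add("bn", colSums(dan))
        add("Wxz", crossprod(x, daz)); add("Whz", crossprod(st$h_prev, daz))
        add("bz", colSums(daz))
        add("Wxr", crossprod(x, dar)); add("Whr", crossprod(st$h_prev, dar))
        add("br", colSums(dar))
        dX[[t]] <- dan %*% t(gp("Wxn")) + daz %*% t(gp("Wxz")) + dar %*% t(gp("Wxr"))
        dh_acc <- dh_prev + dhn %*% t(gp("Whn")) + daz %*% t(gp("Whz")) +
          dar %*% t(gp("Whr"))
      } else {  # LSTM
        gp <- function(nm) params[[paste0(nm, l)]]
        add <- function(nm, v) grads[[paste0(nm, l)]] <<- grads[[paste0(nm, l)]] + v
        do_ <- dh * st$tc
        dc <- dc_acc + dh * st$o * (1 - st$tc^2)
        di <- dc * st$g
        dg <- dc * st$i
        df <- dc * st$c_prev
        dc_acc <- dc * st$f
        dai <- di * st$i * (1 - st$i)
        daf <- df * st$f * (1 - st$f)
        dag <- dg * (1 - st$g^2)
        dao <- do_ * st$o * (1 - st$o)
        add("Wxi", crossprod(x, dai)); add("Whi", crossprod(st$h_prev, dai))
        add("bi", colSums(dai))
        add("Wxf", crossprod(x, daf)); add("Whf", crossprod(st$h_prev, daf))
        add("bf", colSums(daf))
        add("Wxg", crossprod(x, dag)); add("Whg", crossprod(st$h_prev, dag))
        add("bg", colSums(dag))
        add("Wxo", crossprod(x, dao)); add("Who", crossprod(st$h_prev, dao))
        add("bo", colSums(dao))
        dX[[t]] <- dai %*% t(gp("Wxi")) + daf %*% t(gp("Wxf")) +
          dag %*% t(gp("Wxg")) + dao %*% t(gp("Wxo"))
        dh_acc <- dai %*% t(gp("Whi")) + daf %*% t(gp("Whf")) +
          dag %*% t(gp("Whg")) + dao %*% t(gp("Who"))
      }
    }
    dh_out <- dX
  }
  list(loss = loss, acc = acc, grads = grads, probs = p)
}

#' A hand-built perfect decoder
#'
#' A direct linear model (`OHE64`, no hidden layer) whose output logits hold
#' `+margin` at each codon's reference class and `-margin` elsewhere, so its
#' argmax reproduces the standard genetic code exactly.  Useful as a known
#' fixed point: it scores accuracy 1, decodes a complete table, and
#' deciphers at 0 training pairs.
#'
#' @param margin Logit margin (default 20).
#' @return A `decoder_model`.
#' @export
oracle_model <- function(margin = 20) {
  spec <- model_spec("MLP-LINEAR", scheme = "OHE64",
                     hidden_sizes = integer(0), seed = 0L)
  W <- matrix(-margin, 64L, 21L)
  W[cbind(seq_len(64L), aa_index(unname(standard_code())))] <- margin
  structure(list(spec = spec, params = list(W1 = W, b1 = numeric(21L))),
            class = "decoder_model")
}

#' Save / load a decoder checkpoint
#'
#' A checkpoint is a single-file archive of the model: its `model_spec`
#' (architecture, activation, init seed) together with the current weights,
#' so a run can be resumed or a trained decoder shipped.
#'
#' @param model A `decoder_model`.
#' @param path Checkpoint file path (conventionally `.rds`).
#' @return `save_model()` returns the path invisibly; `load_model()` the
#'   restored `decoder_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "decoder_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "decoder_model")) {
    stop(sprintf("'%s' is not a decoder checkpoint", path), call. = FALSE)
  }
  model
}
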