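#' Nucleotide one-hot basis
#'
#' One-hot encodes a single nucleotide over the fixed basis order A, U, C, G:
#' `A = (1,0,0,0)`, `U = (0,1,0,0)`, `C = (0,0,1,0)`, `G = (0,0,0,1)`.  Note
#' that this basis order (A, U, C, G) is a separate convention from the
#' alphabetical codon ordering of [codons()]; the two are documented and
#' tested independently.
#'
#' @param n Single character, one of `A`, `U`, `C`, `G`.
#' @return Numeric vector of length 4.
#' @export
#' @examples
#' ohe_nucleotide("A")  # 1 0 0 0
ohe_nucleotide <- function(n) {
  i <- match(n, nuc_basis())
  if (length(n) != 1L || is.na(i)) {
    stop(sprintf("invalid nucleotide '%s': expected one of A, U, C, G",
                 paste(n, collapse = "")), call. = FALSE)
  }
  v <- numeric(4)
  v[i] <- 1
  stats::setNames(v, nuc_basis())
}

nuc_basis <- function() c("A", "U", "C", "G")

#' Codon encoding schemes
#'
#' Declares one of the three fixed input representations:
#' * `OHE64` — each codon as a 64-bit one-hot vector indexed by [codons()];
#' * `OHE12` — each codon as the concatenation of its three nucleotide
#'   one-hot vectors (3 x 4 = 12 bits);
#' * `NUC4-SEQ3` — each codon as 3 timesteps of 4-bit nucleotide vectors, the
#'   input format of the recurrent readers.
#'
#' @param name One of `"OHE64"`, `"OHE12"`, `"NUC4-SEQ3"`.
#' @return An `encoding_scheme` object with fields `name` and `width`.
#' @export
encoding_scheme <- function(name = c("OHE64", "OHE12", "NUC4-SEQ3")) {
  name <- match.arg(name)
  width <- switch(name, OHE64 = 64L, OHE12 = 12L, `NUC4-SEQ3` = 4L)
  structure(list(name = name, width = width), class = "encoding_scheme")
}

#' Encode one codon under a scheme
#'
#' @param codon Codon string (RNA alphabet) or canonical index in 1..64.
#' @param scheme An [encoding_scheme()] or its name.
#' @return For `OHE64` a 64-vector, for `OHE12` a 12-vector, for `NUC4-SEQ3` a
#'   3 x 4 matrix whose rows are the per-nucleotide timesteps.
#' @export
#' @examples
#' encode_codon("AUG", "OHE12")  # (1,0,0,0, 0,1,0,0, 0,0,0,1)
encode_codon <- function(codon, scheme = "OHE64") {
  if (is.character(scheme)) scheme <- encoding_scheme(scheme)
  i <- if (is.numeric(codon)) as.integer(codon) else codon_index(codon)
  stopifnot(length(i) == 1L, i >= 1L, i <= 64L)
  if (scheme$name == "NUC4-SEQ3") {
    m <- codon_timesteps()[i, , ]
    dimnames(m) <- list(step = 1:3, nuc = nuc_basis())
    return(m)
  }
  codon_encoding_matrix(scheme$name)[i, ]
}

#' Full 64-row encoding matrix for a dense scheme
#'
#' Row `i` is the encoding of the `i`-th canonical codon; this is the matrix
#' the network kernels gather their inputs from.
#'
#' @param scheme `"OHE64"` or `"OHE12"`.
#' @return A 64 x 64 or 64 x 12 numeric matrix with codon row names.
#' @export
codon_encoding_matrix <- function(scheme = c("OHE64", "OHE12")) {
  scheme <- match.arg(scheme)
  if (scheme == "OHE64") {
    m <- diag(64)
  } else {
    ts <- codon_timesteps()
    m <- cbind(ts[, 1, ], ts[, 2, ], ts[, 3, ])
  }
  rownames(m) <- codons()
  m
}

# 64 x 3 x 4 array: timestep one-hot rows for every codon
codon_timesteps <- function() {
  arr <- array(0, dim = c(64L, 3L, 4L))
  cdn <- codons()
  for (i in seq_len(64L)) {
    for (t in 1:3) {
      arr[i, t, match(substr(cdn[i], t, t), nuc_basis())] <- 1
    }
  }
  arr
}

#' Encode an amino-acid symbol as a 21-bit one-hot vector
#'
#' @param a Single character: one of the 20 amino-acid letters or `*`.
#' @return Numeric 21-vector with a single 1 at the canonical class index.
#' @export
encode_amino_acid <- function(a) {
  i <- aa_index(a)
  stopifnot(length(i) == 1L)
  v <- numeric(21)
  v[i] <- 1
  stats::setNames(v, amino_acids())
}

#' Learnable codon-embedding specification
#'
#' A dense, trainable 64 x d real matrix replacing the fixed one-hot input.
#' Rows are initialized i.i.d. normal with standard deviation `1/sqrt(d)`,
#' reproducibly from `seed`.
#'
#' @param d Embedding dimensionality (the study uses 2 and 10).
#' @param seed Integer seed for the initialization.
#' @return An `embedding_spec` object with fields `d` and `matrix`.
#' @export
embedding_spec <- function(d, seed = 1L) {
  stopifnot(is.numeric(d), length(d) == 1L, d >= 1)
  d <- as.integer(d)
  mat <- with_seed(seed, matrix(stats::rnorm(64L * d, sd = 1 / sqrt(d)),
                                nrow = 64L, ncol = d))
  rownames(mat) <- codons()
  structure(list(d = d, matrix = mat), class = "embedding_spec")
}

#' Look up embedding rows for a batch of codons
#'
#' @param idx Integer codon indices in 1..64 (or codon strings).
#' @param spec An [embedding_spec()] or a bare 64 x d matrix.
#' @return Numeric matrix, one embedding row per input codon.
#' @export
embed_codons <- function(idx, spec) {
  m <- if (inherits(spec, "embedding_spec")) spec$matrix else as.matrix(spec)
  stopifnot(nrow(m) == 64L)
  if (is.character(idx)) idx <- codon_index(idx)
  idx <- as.integer(idx)
  if (any(idx < 1L | idx > 64L)) {
    stop("codon index out of range 1..64", call. = FALSE)
  }
  m[idx, , drop = FALSE]
}

#' Export an embedding matrix as TSV
#'
#' Writes the 64 codon-labeled embedding rows (plus the amino acid each codon
#' maps to under the standard code) for plotting synonym clusters.
#'
#' @param spec An [embedding_spec()] or 64 x d matrix.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_embedding_tsv <- function(spec, path) {
  m <- if (inherits(spec, "embedding_spec")) spec$matrix else as.matrix(spec)
  df <- data.frame(codon = codons(), amino_acid = unname(standard_code()),
                   m, check.names = FALSE)
  colnames(df)[-(1:2)] <- paste0("e", seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
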