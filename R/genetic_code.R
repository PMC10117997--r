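#' Canonical codon ordering
#'
#' The 64 RNA codons in lexicographic order over the alphabet A < C < G < U.
#' Every 64-long vector in the package (one-hot encodings, usage tables,
#' embedding matrices, decoded tables) is indexed in this order, so `AAA` is
#' position 1 and `UUU` is position 64.
#'
#' @return Character vector of length 64.
#' @export
#' @examples
#' codons()[1]   # "AAA"
codons <- function() {
  b <- c("A", "C", "G", "U")
  g <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' Canonical amino-acid class ordering
#'
#' The 21 target classes of the decoding task: the 20 single-letter amino-acid
#' codes in alphabetical order followed by the stop mark `*` at position 21.
#'
#' @return Character vector of length 21.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "*")
}

#' The standard genetic code
#'
#' The canonical many-to-one mapping from the 64 codons to the 20 amino acids
#' plus the stop mark `*`.  Taken from [Biostrings::GENETIC_CODE] with DNA
#' codons rewritten over the RNA alphabet and reordered canonically (see
#' [codons()]).  This table is the ground truth used both to synthesize
#' protein sequences and to judge whether a trained decoder has recovered the
#' code.
#'
#' @return Named character vector of length 64; names are RNA codons in
#'   canonical order, values are single-letter amino-acid symbols or `*`.
#' @export
#' @examples
#' standard_code()[c("GAU", "GAC")]  # both aspartate "D"
#' standard_code()[c("UAA", "UAG", "UGA")]  # the three stop codons
standard_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("T", "U", names(gc))
  code <- gc[codons()]
  storage.mode(code) <- "character"
  code
}

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Accepts DNA or RNA in any case, returns uppercase RNA (`T` rewritten as
#' `U`).  Any character outside `A`, `C`, `G`, `T`, `U` (either case) is an
#' error that names the offending position.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector over `{A,U,C,G}`, same lengths as the input.
#' @export
#' @examples
#' normalize_sequence("atggct")  # "AUGGCU"
normalize_sequence <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("acgtuT", "ACGUUU", x)
  bad <- regexpr("[^ACGU]", out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid nucleotide '%s' at position %d of sequence %d",
                 substr(out[i], bad[i], bad[i]), bad[i], i),
         call. = FALSE)
  }
  out
}

#' Translate an in-frame RNA sequence
#'
#' Applies a genetic code to each successive non-overlapping triplet.  The
#' terminal stop codon, if present, is rendered as `*`.
#'
#' @param rna Character vector of RNA sequences whose lengths are multiples
#'   of 3 (see [normalize_sequence()]).
#' @param code Genetic code as returned by [standard_code()].
#' @return Character vector of protein sequences (one third the input length).
#' @export
#' @examples
#' translate_rna("AUGGAUUAA")  # "MD*"
translate_rna <- function(rna, code = standard_code()) {
  stopifnot(is.character(rna))
  n <- nchar(rna)
  if (any(n %% 3L != 0L)) {
    i <- which(n %% 3L != 0L)[1L]
    stop(sprintf("frame error: sequence %d has length %d, not a multiple of 3",
                 i, n[i]), call. = FALSE)
  }
  vapply(rna, function(s) {
    if (nchar(s) == 0L) return("")
    cdn <- codon_split(s)
    aa <- code[cdn]
    if (anyNA(aa)) {
      stop(sprintf("unknown codon '%s'", cdn[which(is.na(aa))[1L]]),
           call. = FALSE)
    }
    paste0(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split one in-frame sequence into its codons
codon_split <- function(s) {
  first <- seq.int(1L, nchar(s), by = 3L)
  substring(s, first, first + 2L)
}

# codon strings -> canonical indices 1..64 (errors on unknown codons)
codon_index <- function(cdn) {
  i <- match(cdn, codons())
  if (anyNA(i)) {
    stop(sprintf("unknown codon '%s'", cdn[which(is.na(i))[1L]]), call. = FALSE)
  }
  i
}

# amino-acid symbols -> canonical indices 1..21
aa_index <- function(aa) {
  i <- match(aa, amino_acids())
  if (anyNA(i)) {
    stop(sprintf("unknown amino-acid symbol '%s'", aa[which(is.na(i))[1L]]),
         call. = FALSE)
  }
  i
}
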