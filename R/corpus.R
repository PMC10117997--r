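#' Read transcript sequences from FASTA
#'
#' Reads DNA or RNA transcripts (plain or gzip-compressed FASTA) as a named
#' character vector, without validating the alphabet; validation is the job of
#' [extract_orfs()].
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read FASTA '%s'", path), call. = FALSE)
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write ORF records to FASTA
#'
#' @param orfs ORF data frame (columns `id`, `rna`, `protein`).
#' @param path Output FASTA path for the RNA sequences.
#' @param what `"rna"` or `"protein"` — which column to write.
#' @return The path, invisibly.
#' @export
write_orf_fasta <- function(orfs, path, what = c("rna", "protein")) {
  what <- match.arg(what)
  x <- Biostrings::BStringSet(stats::setNames(orfs[[what]], orfs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Extract and validate open reading frames
#'
#' Applies the four ORF filters used to build training corpora: the sequence
#' must start with `AUG`, end with one of `UAA`/`UAG`/`UGA`, have a length
#' that is a multiple of 3, and contain no internal in-frame stop codon.
#' Sequences are normalized to the RNA alphabet first; characters outside the
#' DNA/RNA alphabet reject the record rather than raising an error.  When a
#' record violates several filters, the reported reason follows the fixed
#' priority `invalid-alphabet` > `bad-length` > `no-start` >
#' `no-terminal-stop` > `internal-stop`.
#'
#' @param records Named character vector of nucleotide sequences (names are
#'   record ids), e.g. from [read_transcripts()].
#' @return A list with `kept` (data frame `id`, `rna`, `protein`) and
#'   `rejected` (data frame `id`, `reason`).
#' @export
#' @examples
#' extract_orfs(c(a = "AUGGCUUAA", b = "AUGGCUGCU"))
extract_orfs <- function(records) {
  stopifnot(is.character(records))
  ids <- names(records) %||% as.character(seq_along(records))
  ids[ids == ""] <- as.character(which(ids == ""))
  code <- standard_code()
  stops <- c("UAA", "UAG", "UGA")

  kept_id <- character(0); kept_rna <- character(0); kept_prot <- character(0)
  rej_id <- character(0); rej_reason <- character(0)
  for (k in seq_along(records)) {
    s <- chartr("acgtuT", "ACGUUU", records[[k]])
    reason <- NULL
    if (grepl("[^ACGU]", s)) {
      reason <- "invalid-alphabet"
    } else if (nchar(s) %% 3L != 0L || nchar(s) < 6L) {
      reason <- "bad-length"
    } else if (substr(s, 1L, 3L) != "AUG") {
      reason <- "no-start"
    } else if (!substr(s, nchar(s) - 2L, nchar(s)) %in% stops) {
      reason <- "no-terminal-stop"
    } else {
      cdn <- codon_split(s)
      if (any(cdn[-length(cdn)] %in% stops)) reason <- "internal-stop"
    }
    if (is.null(reason)) {
      kept_id <- c(kept_id, ids[k])
      kept_rna <- c(kept_rna, s)
      kept_prot <- c(kept_prot, paste0(code[codon_split(s)], collapse = ""))
    } else {
      rej_id <- c(rej_id, ids[k])
      rej_reason <- c(rej_reason, reason)
    }
  }
  list(
    kept = data.frame(id = kept_id, rna = kept_rna, protein = kept_prot,
                      stringsAsFactors = FALSE),
    rejected = data.frame(id = rej_id, reason = rej_reason,
                          stringsAsFactors = FALSE)
  )
}

#' Read a codon-usage table from TSV
#'
#' Expects a header line and two columns, `codon` and `frequency` (DNA or RNA
#' codons, any case).  Frequencies may be on any scale (counts, per-1000,
#' fractions); they are renormalized to sum to 1 over the 64 codons.
#'
#' @param path TSV file.
#' @return Named numeric 64-vector in canonical codon order summing to 1.
#' @export
read_codon_usage <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("codon", "frequency") %in% names(df))) {
    stop("usage table must have header columns 'codon' and 'frequency'",
         call. = FALSE)
  }
  cdn <- normalize_sequence(df$codon)
  freq <- stats::setNames(rep(0, 64), codons())
  freq[cdn] <- df$frequency
  if (any(freq < 0) || sum(freq) <= 0) {
    stop("usage frequencies must be non-negative with positive total",
         call. = FALSE)
  }
  freq / sum(freq)
}

#' Bundled human-like codon-usage table
#'
#' The default usage distribution for the synthetic-corpus generator: standard
#' published human codon frequencies (per-1000 scale in the shipped TSV,
#' renormalized at load), whose most frequent codon is GAG as in the human
#' transcriptome.  Replace via the `usage` arguments or edit a copy of the
#' TSV (`system.file("extdata", "human_codon_usage.tsv", package =
#' "codonDecipher")`).
#'
#' @return Named numeric 64-vector summing to 1.
#' @export
default_codon_usage <- function() {
  read_codon_usage(system.file("extdata", "human_codon_usage.tsv",
                               package = "codonDecipher", mustWork = TRUE))
}

#' Synthesize an ORF corpus from a codon-usage distribution
#'
#' Generates ORFs with the structure of mature coding sequences: each record
#' is `AUG`, then `L - 2` body codons drawn i.i.d. from the usage distribution
#' restricted and renormalized to the 61 sense codons, then one stop codon
#' drawn from the usage distribution restricted to `UAA`/`UAG`/`UGA`.  Every
#' generated record passes [extract_orfs()] by construction.  Codon counts `L`
#' are drawn from a log-normal length model (right-skewed like real transcript
#' lengths) with configurable median, log-sd and clamp range.
#'
#' @param n_orfs Number of ORFs to generate.
#' @param usage Codon-usage table (named 64-vector, see
#'   [default_codon_usage()]).
#' @param length_model List with `median` (codons, default 400), `sdlog`
#'   (default 0.45), `min` (default 10) and `max` (default 3000).
#' @param seed Integer seed; identical seeds give identical corpora.
#' @return Data frame with columns `id`, `rna`, `protein`.
#' @export
#' @examples
#' orfs <- generate_corpus(3, seed = 1, length_model = list(median = 20))
#' extract_orfs(stats::setNames(orfs$rna, orfs$id))$rejected  # empty
generate_corpus <- function(n_orfs, usage = default_codon_usage(),
                            length_model = list(), seed = 1L) {
  stopifnot(is.numeric(n_orfs), n_orfs >= 0)
  n_orfs <- as.integer(n_orfs)
  lm <- utils::modifyList(list(median = 400, sdlog = 0.45, min = 10,
                               max = 3000), length_model)
  usage <- check_usage(usage)
  cdn <- codons()
  stop_i <- which(cdn %in% c("UAA", "UAG", "UGA"))
  sense_i <- setdiff(seq_len(64L), stop_i)
  if (sum(usage[stop_i]) <= 0) {
    stop("usage table has zero mass on the stop codons", call. = FALSE)
  }
  if (sum(usage[sense_i]) <= 0) {
    stop("usage table has zero mass on the sense codons", call. = FALSE)
  }
  if (n_orfs == 0L) {
    return(data.frame(id = character(0), rna = character(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  code <- standard_code()
  with_seed(seed, {
    lens <- round(stats::rlnorm(n_orfs, meanlog = log(lm$median),
                                sdlog = lm$sdlog))
    lens <- as.integer(pmin(pmax(lens, lm$min), lm$max))
    n_body <- lens - 2L
    body <- sample(sense_i, sum(n_body), replace = TRUE,
                   prob = usage[sense_i])
    ends <- sample(stop_i, n_orfs, replace = TRUE, prob = usage[stop_i])
    grp <- rep.int(seq_len(n_orfs), n_body)
    body_cdn <- split(cdn[body], grp)
    body_aa <- split(unname(code[body]), grp)
    rna <- vapply(seq_len(n_orfs), function(i) {
      paste0("AUG", paste0(body_cdn[[i]], collapse = ""), cdn[ends[i]])
    }, character(1))
    prot <- vapply(seq_len(n_orfs), function(i) {
      paste0("M", paste0(body_aa[[i]], collapse = ""), "*")
    }, character(1))
    data.frame(id = sprintf("orf%05d", seq_len(n_orfs)), rna = rna,
               protein = prot, stringsAsFactors = FALSE)
  })
}

check_usage <- function(usage) {
  stopifnot(is.numeric(usage), length(usage) == 64L)
  if (is.null(names(usage))) names(usage) <- codons()
  usage <- usage[codons()]
  if (anyNA(usage) || any(usage < 0)) {
    stop("usage must be a non-negative 64-vector named by codons", call. = FALSE)
  }
  usage / sum(usage)
}

#' Empirical codon frequencies of a corpus
#'
#' @param orfs ORF data frame (columns `id`, `rna`, `protein`).
#' @return Named numeric 64-vector of relative frequencies summing to 1.
#' @export
codon_frequencies <- function(orfs) {
  if (NROW(orfs) == 0L) stop("empty corpus", call. = FALSE)
  counts <- integer(64L)
  for (s in orfs$rna) {
    i <- codon_index(codon_split(s))
    counts <- counts + tabulate(i, nbins = 64L)
  }
  stats::setNames(counts / sum(counts), codons())
}

#' Empirical amino-acid frequencies of a corpus
#'
#' Frequencies over the 21 target classes (stop mark included) of the ground
#' truth protein sequences.  Numerically identical to pushing
#' [codon_frequencies()] through [standard_code()].
#'
#' @param orfs ORF data frame (columns `id`, `rna`, `protein`).
#' @return Named numeric 21-vector summing to 1.
#' @export
aa_frequencies <- function(orfs) {
  if (NROW(orfs) == 0L) stop("empty corpus", call. = FALSE)
  aa <- unlist(strsplit(orfs$protein, ""), use.names = FALSE)
  counts <- tabulate(aa_index(aa), nbins = 21L)
  stats::setNames(counts / sum(counts), amino_acids())
}

#' Inverse-frequency class weights
#'
#' Loss weights proportional to the inverse of the class frequency
#' distribution, so that misclassifying a rare amino acid (or the stop mark)
#' is penalized more than misclassifying a frequent one.  A small floor guards
#' classes of zero observed frequency; weights are normalized to mean 1.
#'
#' @param dist Amino-acid distribution (named 21-vector, see
#'   [aa_frequencies()]).
#' @param floor Minimum frequency substituted for smaller (or zero) entries.
#' @return Named numeric 21-vector of positive weights with mean 1.
#' @export
#' @examples
#' class_weights(stats::setNames(rep(1 / 21, 21), amino_acids()))  # all 1
class_weights <- function(dist, floor = 1e-6) {
  stopifnot(is.numeric(dist), length(dist) == 21L, floor > 0)
  w <- 1 / pmax(dist, floor)
  w <- w / mean(w)
  stats::setNames(w, names(dist) %||% amino_acids())
}

#' Split a corpus into train/test pairs and batches
#'
#' Randomly partitions the ORFs (at ORF level, so no sequence contributes to
#' both sides), then unrolls each side into (codon, amino-acid) index pairs in
#' sequence order.  Training iterates over these pairs in batches of
#' `batch_size` (the final batch of an epoch may be short).
#'
#' @param orfs ORF data frame.
#' @param train_frac Fraction of ORFs assigned to the training side
#'   (default 0.9).
#' @param batch_size Pairs per batch (default 64).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A `pair_dataset` object.
#' @export
split_and_batch <- function(orfs, train_frac = 0.9, batch_size = 64L,
                            seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1, batch_size >= 1)
  n <- NROW(orfs)
  if (n < 2L) stop("need at least 2 ORFs to split", call. = FALSE)
  n_train <- min(n - 1L, max(1L, round(train_frac * n)))
  train_rows <- with_seed(seed, sample.int(n, n_train))
  unroll <- function(rows) {
    cdn_idx <- integer(0); orf <- character(0)
    cdn_list <- lapply(orfs$rna[rows], function(s) codon_index(codon_split(s)))
    list(codon = unlist(cdn_list, use.names = FALSE),
         orf = rep.int(orfs$id[rows], lengths(cdn_list)))
  }
  tr <- unroll(train_rows)
  te <- unroll(setdiff(seq_len(n), train_rows))
  code_idx <- aa_index(unname(standard_code()))
  structure(list(
    train_codon = tr$codon, train_aa = code_idx[tr$codon], train_orf = tr$orf,
    test_codon = te$codon, test_aa = code_idx[te$codon], test_orf = te$orf,
    train_ids = orfs$id[train_rows],
    test_ids = orfs$id[setdiff(seq_len(n), train_rows)],
    batch_size = as.integer(batch_size)
  ), class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf(
    "pair_dataset: %d train pairs (%d ORFs), %d test pairs (%d ORFs), batch %d\n",
    length(x$train_codon), length(x$train_ids),
    length(x$test_codon), length(x$test_ids), x$batch_size))
  invisible(x)
}

#' Export a frequency vector as TSV
#'
#' Writes a two-column table (`symbol`, `frequency`) for codon or amino-acid
#' frequency histograms.
#'
#' @param freq Named numeric vector (64 codons or 21 classes).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_frequency_tsv <- function(freq, path) {
  utils::write.table(
    data.frame(symbol = names(freq), frequency = unname(freq)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
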