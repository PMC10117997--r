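#' Decode the model's current 64-codon table
#'
#' Feeds all 64 codons directly to the model (exact enumeration, rather than
#' harvesting whichever codons occur in a batch) and tabulates the softmax
#' output for each.  The argmax call uses lowest-class-index tie-breaking; a
#' row whose maximum probability is attained by more than one class is flagged
#' as tied.
#'
#' @param model A `decoder_model`.
#' @param reference Genetic code to diff the calls against (default
#'   [standard_code()]).
#' @return A `deciphered_table`: 64 x 21 probability matrix `probs`, argmax
#'   `calls`, logical `tied`, `mismatches` data frame (codon, predicted,
#'   reference) and `complete` (no mismatches).
#' @export
decode_table <- function(model, reference = standard_code()) {
  p <- forward(model, seq_len(64L))
  rownames(p) <- codons()
  top <- max.col(p, ties.method = "first")
  calls <- stats::setNames(amino_acids()[top], codons())
  tied <- vapply(seq_len(64L), function(i) {
    sum(p[i, ] == p[i, top[i]]) > 1L
  }, logical(1))
  bad <- which(calls != reference)
  mismatches <- data.frame(codon = codons()[bad],
                           predicted = unname(calls[bad]),
                           reference = unname(reference[bad]),
                           stringsAsFactors = FALSE)
  structure(list(probs = p, calls = calls, tied = tied,
                 mismatches = mismatches,
                 complete = nrow(mismatches) == 0L),
            class = "deciphered_table")
}

#' @export
print.deciphered_table <- function(x, ...) {
  cat(sprintf("deciphered_table: %d/64 codons correct%s\n",
              64L - nrow(x$mismatches),
              if (any(x$tied)) sprintf(", %d tied", sum(x$tied)) else ""))
  if (nrow(x$mismatches) > 0L && nrow(x$mismatches) <= 10L) {
    print(x$mismatches, row.names = FALSE)
  }
  invisible(x)
}

#' Is a decoded table unequivocally complete?
#'
#' `TRUE` iff the argmax call matches the reference code for all 64 codons
#' *and* no row attains its maximum probability at more than one class.  A
#' codon whose top probability is exactly tied (e.g. split between the stop
#' mark and an amino acid) is not considered deciphered, whichever class the
#' tie-break would pick.
#'
#' @param table A `deciphered_table`.
#' @param reference Genetic code (default [standard_code()]).
#' @return Logical scalar.
#' @export
is_unequivocal <- function(table, reference = standard_code()) {
  stopifnot(inherits(table, "deciphered_table"))
  all(table$calls == reference) && !any(table$tied)
}

#' Data efficiency: pairs to first unequivocal deciphering
#'
#' Scans a training trace's deciphering checks for the earliest check whose
#' table was unequivocally complete and reports the cumulated number of
#' codon/amino-acid training pairs presented by then.  The result is resolved
#' at the check cadence (`check_every * batch_size` pairs).
#'
#' @param trace A `training_trace` from [train()].
#' @return An `efficiency_result` with fields `deciphered`,
#'   `pairs_at_deciphering`, `epoch_at_deciphering`, `iteration` and
#'   `check_cadence_pairs`.
#' @export
data_efficiency <- function(trace) {
  stopifnot(inherits(trace, "training_trace"))
  checks <- trace$checks
  if (is.null(checks) || nrow(checks) == 0L) {
    stop("trace contains no deciphering checks", call. = FALSE)
  }
  hit <- which(checks$unequivocal)
  deciphered <- length(hit) > 0L
  first <- if (deciphered) checks[hit[1L], ] else NULL
  structure(list(
    deciphered = deciphered,
    pairs_at_deciphering = if (deciphered) first$cumulated_pairs else NA_real_,
    epoch_at_deciphering = if (deciphered) first$epoch else NA_integer_,
    iteration = if (deciphered) first$iteration else NA_integer_,
    check_cadence_pairs = trace$config$check_every * trace$config$batch_size,
    cap_pairs = trace$cumulated_pairs
  ), class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  if (x$deciphered) {
    cat(sprintf(
      "deciphered at %s cumulated pairs (epoch %d, cadence %s pairs)\n",
      format(x$pairs_at_deciphering, big.mark = ","), x$epoch_at_deciphering,
      format(x$check_cadence_pairs, big.mark = ",")))
  } else {
    cat(sprintf("not deciphered within %s pairs\n",
                format(x$cap_pairs, big.mark = ",")))
  }
  invisible(x)
}

#' Silhouette score of synonym clustering in embedding space
#'
#' Groups the 64 embedding rows by the amino-acid class their codon maps to
#' under `code` and computes the mean silhouette width (Euclidean distance),
#' excluding codons that are their class's only member.  Synonymous codons
#' that cluster tightly and away from other classes score near 1; an
#' unstructured embedding scores near 0.  If all pairwise distances vanish
#' (every codon embedded identically) the score is 0 by convention.
#'
#' @param embedding An [embedding_spec()], a 64 x d matrix, or an `MLP-EMBED`
#'   `decoder_model` (its learned embedding is extracted).
#' @param code Genetic code defining the synonym groups (default
#'   [standard_code()]).
#' @return Scalar in `[-1, 1]`.
#' @export
synonymy_clustering_score <- function(embedding, code = standard_code()) {
  m <- if (inherits(embedding, "decoder_model")) {
    stopifnot(embedding$spec$family == "MLP-EMBED")
    embedding$params$E
  } else if (inherits(embedding, "embedding_spec")) {
    embedding$matrix
  } else {
    as.matrix(embedding)
  }
  stopifnot(nrow(m) == 64L)
  grp <- aa_index(unname(code[codons()]))
  sizes <- tabulate(grp, nbins = 21L)
  if (all(sizes[grp] == 1L)) {
    stop("all synonym groups are singletons: silhouette undefined", call. = FALSE)
  }
  d <- stats::dist(m)
  if (max(d) == 0) return(0)
  sil <- cluster::silhouette(grp, d)
  keep <- sizes[grp] > 1L
  mean(sil[keep, "sil_width"])
}

#' Export decoded-table snapshots as CSV and PNG heatmaps
#'
#' For every probability snapshot retained in a trace, writes a 64 x 21 CSV
#' (codon rows, class columns) and a rendered heatmap; filenames carry the
#' iteration and the cumulated pairs, so the sequence of files replays how the
#' code's block pattern emerges during training.
#'
#' @param trace A `training_trace`.
#' @param out_dir Output directory (created if needed).
#' @return Data frame of written `csv` and `png` paths, invisibly.
#' @export
export_snapshots <- function(trace, out_dir) {
  stopifnot(inherits(trace, "training_trace"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create snapshot directory '%s'", out_dir), call. = FALSE)
  }
  files <- lapply(trace$snapshots, function(sn) {
    stem <- sprintf("snapshot_iter%07d_pairs%010.0f", sn$iteration,
                    sn$cumulated_pairs)
    csv <- file.path(out_dir, paste0(stem, ".csv"))
    png <- file.path(out_dir, paste0(stem, ".png"))
    utils::write.csv(data.frame(codon = codons(), sn$table$probs,
                                check.names = FALSE),
                     csv, row.names = FALSE)
    grDevices::png(png, width = 640, height = 1280)
    op <- graphics::par(mar = c(4, 4, 2, 1))
    graphics::image(x = seq_len(21L), y = seq_len(64L),
                    z = t(sn$table$probs[64:1, ]),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    axes = FALSE, xlab = "class", ylab = "codon",
                    main = sprintf("iteration %d (%s pairs)", sn$iteration,
                                   format(sn$cumulated_pairs, big.mark = ",")))
    graphics::axis(1, at = seq_len(21L), labels = amino_acids(), las = 1)
    graphics::axis(2, at = seq_len(64L), labels = rev(codons()), las = 2,
                   cex.axis = 0.5)
    graphics::par(op)
    grDevices::dev.off()
    data.frame(csv = csv, png = png, stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, files))
}

#' Write the final decoded table as a two-column TSV
#'
#' A `codon<TAB>amino_acid` table directly diffable against the standard code.
#'
#' @param table A `deciphered_table`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_decoded_tsv <- function(table, path) {
  stopifnot(inherits(table, "deciphered_table"))
  utils::write.table(
    data.frame(codon = codons(), amino_acid = unname(table$calls)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
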