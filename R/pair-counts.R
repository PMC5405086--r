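#' Count substitution pairs over a block
#'
#' For every alignment column and every unordered pair of the block's
#' sequences, the residue pair observed contributes one count — the
#' counting convention of the BLOSUM family of matrices, so frequencies
#' are depth-weighted.  Homo-pairs (identical residues) sit on the
#' diagonal of the 20x20 count matrix; the 190 hetero-pair types
#' (substitution hetero-pairs, SHPs) off it.  Counts are exact integers;
#' percentages are computed only at reporting time.
#'
#' The total count always equals `width * choose(depth, 2)`.
#'
#' @param x a [block].
#' @return An object of class `"pair_counts"`: a list with `counts`
#'   (symmetric 20x20 integer matrix; cell `[a, b]`, a != b, holds the
#'   number of times the unordered pair \{a, b\} was observed),
#'   `n_columns`, `n_sequences`, `homo_total`, `hetero_total`.
#' @examples
#' b <- block(c("AAV", "AVV"))
#' count_pairs(b)
#' @export
count_pairs <- function(x) {
  stopifnot(inherits(x, "block"))
  m <- block_matrix(x)
  idx <- match(m, AA)
  dim(idx) <- dim(m)

  # per-column residue tallies, then pairs from products:
  # off-diagonal unordered count = c_a * c_b; diagonal = choose(c_a, 2)
  S <- matrix(0, 20L, 20L)
  tot <- numeric(20L)
  for (j in seq_len(x$width)) {
    cj <- tabulate(idx[, j], nbins = 20L)
    S <- S + tcrossprod(cj)
    tot <- tot + cj
  }
  diag(S) <- (diag(S) - tot) / 2
  storage.mode(S) <- "integer"
  dimnames(S) <- list(AA, AA)

  structure(
    list(counts = S,
         n_columns = x$width,
         n_sequences = x$depth,
         homo_total = sum(diag(S)),
         hetero_total = sum(S[upper.tri(S)])),
    class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("Pair counts over ", x$n_columns, " columns x C(",
      x$n_sequences, ",2) sequence pairs\n", sep = "")
  cat("  total ", x$homo_total + x$hetero_total,
      " (homo ", x$homo_total, ", hetero ", x$hetero_total, ")\n",
      sep = "")
  het <- hetero_frequencies(x)
  obs <- sort(het[het > 0], decreasing = TRUE)
  cat("  observed hetero types: ", length(obs), "/190\n", sep = "")
  if (length(obs))
    cat("  top: ", paste(names(utils::head(obs, 5)),
                         utils::head(obs, 5), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Folded hetero-pair frequencies
#'
#' The 190 off-diagonal cells of a [count_pairs()] matrix folded into a
#' named integer vector (names are two-letter pair labels in
#' alphabetical order, e.g. `"AV"`).  Zero-count pairs are included, so
#' the vector always has length 190 and sums to the hetero total.
#'
#' @param pc a `pair_counts` object.
#' @return Named integer vector of length 190.
#' @export
hetero_frequencies <- function(pc) {
  stopifnot(inherits(pc, "pair_counts"))
  ut <- which(upper.tri(pc$counts), arr.ind = TRUE)
  v <- pc$counts[upper.tri(pc$counts)]
  names(v) <- paste0(AA[ut[, "row"]], AA[ut[, "col"]])
  v
}

#' Export a pair-count matrix as TSV
#'
#' Writes the 20x20 symmetric count matrix with residues in alphabetical
#' order as row and column labels (report Item B).
#'
#' @param pc a `pair_counts` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pair_counts_tsv <- function(pc, path) {
  stopifnot(inherits(pc, "pair_counts"))
  df <- data.frame(residue = AA, pc$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
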