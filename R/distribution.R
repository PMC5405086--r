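#' Hetero-pair frequency versus observed probability
#'
#' Each observed hetero-pair type gets a probability equal to its count
#' divided by the total hetero count (probabilities over observed types
#' sum to 1), and the types are binned into `n_bins` equal-width
#' probability intervals on `[0, max probability]`.  Intervals are
#' half-open `[lo, hi)` with the last bin closed, so the dominant pair
#' always falls in the highest occupied bin.  In typical blocks the
#' low-probability bins hold many pair types (high, non-selective
#' frequency) while the top bin narrows to one or two conservative
#' types.
#'
#' @param pc a [count_pairs()] result with at least one hetero-pair.
#' @param n_bins number of equal-width probability bins (default 10).
#' @return An object of class `"probability_table"`: list with
#'   `entries` (data.frame: `pair`, `count`, `probability`; zero-count
#'   pairs excluded, sorted by decreasing count then pair label) and
#'   `bins` (data.frame: `lower`, `upper`, `n_types`, `total_count`).
#' @export
probability_table <- function(pc, n_bins = 10L) {
  stopifnot(inherits(pc, "pair_counts"), n_bins >= 1L)
  if (pc$hetero_total == 0L)
    stop_blocksub("no_hetero",
      "no hetero-pairs observed; probability table undefined")
  het <- hetero_frequencies(pc)
  het <- het[het > 0L]
  prob <- het / pc$hetero_total
  ord <- order(-het, names(het))
  entries <- data.frame(pair = names(het)[ord],
                        count = as.integer(het[ord]),
                        probability = as.numeric(prob[ord]),
                        stringsAsFactors = FALSE)

  brk <- seq(0, max(prob), length.out = n_bins + 1L)
  # bin index: half-open [lo, hi), last bin closed at the max
  bin <- pmin(findInterval(entries$probability, brk,
                           rightmost.closed = TRUE), n_bins)
  bins <- data.frame(
    lower = brk[-length(brk)],
    upper = brk[-1L],
    n_types = vapply(seq_len(n_bins), function(k) sum(bin == k), 0L),
    total_count = vapply(seq_len(n_bins),
                         function(k) sum(entries$count[bin == k]), 0L))
  structure(list(entries = entries, bins = bins),
            class = "probability_table")
}

#' @export
print.probability_table <- function(x, ...) {
  cat("Hetero-pair probability table: ", nrow(x$entries),
      " observed types\n", sep = "")
  print(utils::head(x$entries, 5), row.names = FALSE)
  if (nrow(x$entries) > 5) cat("  ...\n")
  invisible(x)
}
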