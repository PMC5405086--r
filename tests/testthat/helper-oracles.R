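# Independent oracles and fixture builders, deliberately naive:
# quadratic enumeration, no shared code with the package internals.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# brute-force pair counting: explicit double loop over columns and
# unordered sequence pairs
brute_force_counts <- function(seqs) {
  chars <- strsplit(toupper(seqs), "")
  width <- length(chars[[1]])
  depth <- length(chars)
  m <- matrix(0L, 20, 20, dimnames = list(AA20, AA20))
  for (j in seq_len(width)) {
    for (i1 in seq_len(depth - 1)) {
      for (i2 in (i1 + 1):depth) {
        a <- chars[[i1]][j]; b <- chars[[i2]][j]
        if (a == b) {
          m[a, b] <- m[a, b] + 1L
        } else {
          m[a, b] <- m[a, b] + 1L
          m[b, a] <- m[b, a] + 1L
        }
      }
    }
  }
  m
}

# uniform random block, independent of the package generator
random_block <- function(width, depth) {
  blocksub::block(
    vapply(seq_len(depth),
           function(i) paste(sample(AA20, width, replace = TRUE),
                             collapse = ""),
           character(1)))
}

# block of given depth whose columns realize exactly the given
# unordered hetero pairs (depth 2: one column per pair)
block_from_pairs <- function(pairs_a, pairs_b) {
  blocksub::block(c(paste(pairs_a, collapse = ""),
                    paste(pairs_b, collapse = "")))
}

write_fasta_lines <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}
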