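#' Construct a BLOCK: a validated gap-free equal-length protein alignment
#'
#' A block is the unit of analysis: at least two aligned protein
#' sequences of identical length, with no gap characters and only the 20
#' standard amino-acid one-letter codes.  Sequences are normalized to
#' upper case; identifiers must be unique.
#'
#' @param sequences character vector of aligned sequences.
#' @param ids character vector of unique identifiers, same length as
#'   `sequences`.  Defaults to `names(sequences)` or `seq1`, `seq2`, ...
#' @return An object of class `"block"`: a list with `ids`, `sequences`,
#'   `width` (alignment columns) and `depth` (number of sequences).
#' @seealso [read_block_fasta()], [write_block_fasta()], [generate_block()]
#' @examples
#' b <- block(c(a = "ACDL", b = "ACEL"))
#' b$width
#' @export
block <- function(sequences, ids = NULL) {
  if (is.null(ids)) {
    ids <- names(sequences)
    if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
  }
  sequences <- toupper(as.character(sequences))
  ids <- as.character(ids)

  if (length(sequences) < 2L)
    stop_blocksub("empty_input",
      "a block needs at least 2 sequences")
  if (length(ids) != length(sequences))
    stop_blocksub("empty_input", "ids and sequences differ in length")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop_blocksub("duplicate_id",
      paste0("duplicate sequence identifier(s): ",
             paste(unique(dup), collapse = ", ")))

  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L)
    stop_blocksub("unequal_length",
      paste0("sequences differ in length (",
             paste(range(widths), collapse = "-"),
             "); input is not a gap-free block"))
  width <- widths[[1L]]
  if (width < 1L)
    stop_blocksub("empty_input", "sequences have zero length")

  chars <- strsplit(sequences, "", fixed = TRUE)
  for (i in seq_along(chars)) {
    bad <- which(chars[[i]] %in% GAP_CHARS)
    if (length(bad))
      stop_blocksub("gap_present",
        paste0("gap character in sequence '", ids[i], "' at column ",
               bad[1L], "; blocks are gap-free by construction"))
    bad <- which(!(chars[[i]] %in% AA))
    if (length(bad))
      stop_blocksub("illegal_residue",
        paste0("non-standard residue '", chars[[i]][bad[1L]],
               "' in sequence '", ids[i], "' at column ", bad[1L]))
  }

  structure(
    list(ids = ids, sequences = sequences,
         width = width, depth = length(sequences)),
    class = "block")
}

#' @export
print.block <- function(x, ...) {
  cat("BLOCK: ", x$depth, " sequences x ", x$width, " columns\n",
      sep = "")
  show <- utils::head(seq_len(x$depth), 6L)
  for (i in show) {
    s <- x$sequences[i]
    if (nchar(s) > 50) s <- paste0(substr(s, 1, 50), "...")
    cat(sprintf("  %-12s %s\n", x$ids[i], s))
  }
  if (x$depth > 6L) cat("  ... ", x$depth - 6L, " more\n", sep = "")
  invisible(x)
}

# depth x width character matrix view used by column-wise operations
block_matrix <- function(b) {
  m <- matrix(unlist(strsplit(b$sequences, "", fixed = TRUE)),
              nrow = b$depth, ncol = b$width, byrow = TRUE)
  rownames(m) <- b$ids
  m
}

#' Read a BLOCK-FASTA file
#'
#' Reads a standard multi-FASTA file and validates it as a block.
#' Identifiers are taken verbatim from the header up to the first
#' whitespace; lower-case residues are normalized to upper case.
#' Malformed input raises a classed error, never a silent fix:
#' `blocksub_unequal_length`, `blocksub_gap_present`,
#' `blocksub_illegal_residue` (with sequence id and column),
#' `blocksub_duplicate_id`, or `blocksub_empty_input`.
#'
#' @param path path to a multi-FASTA file.
#' @param drop_bad_columns if `TRUE`, columns containing a non-standard
#'   residue (X, B, Z, U, O, J, ...) are removed with a message instead
#'   of raising `blocksub_illegal_residue`.  Gap characters are always
#'   fatal.
#' @return A [block].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACD", ">b", "ACE"), f)
#' read_block_fasta(f)
#' @export
read_block_fasta <- function(path, drop_bad_columns = FALSE) {
  if (!file.exists(path))
    stop_blocksub("io", paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e)
      stop_blocksub("io", paste0("cannot parse FASTA: ",
                                 conditionMessage(e))))
  if (length(set) < 2L)
    stop_blocksub("empty_input",
      paste0("fewer than 2 sequences in ", path))

  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))

  if (drop_bad_columns) {
    widths <- nchar(seqs)
    if (length(unique(widths)) != 1L)
      stop_blocksub("unequal_length",
        "sequences differ in length; input is not a gap-free block")
    m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                nrow = length(seqs), byrow = TRUE)
    if (any(m %in% GAP_CHARS))
      stop_blocksub("gap_present",
        "gap character found; blocks are gap-free by construction")
    bad_col <- which(apply(m, 2L, function(col) any(!(col %in% AA))))
    if (length(bad_col)) {
      message("dropping ", length(bad_col),
              " column(s) with non-standard residues: ",
              paste(bad_col, collapse = ", "))
      if (length(bad_col) == ncol(m))
        stop_blocksub("empty_input",
          "all columns contain non-standard residues")
      m <- m[, -bad_col, drop = FALSE]
      seqs <- apply(m, 1L, paste, collapse = "")
    }
  }
  block(seqs, ids = ids)
}

#' Write a block as BLOCK-FASTA
#'
#' Standard multi-FASTA with sequence lines wrapped at 60 columns.
#' `read_block_fasta()` on the written file reproduces the block
#' field-for-field.
#'
#' @param x a [block].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_block_fasta <- function(x, path) {
  stopifnot(inherits(x, "block"))
  set <- Biostrings::AAStringSet(x$sequences)
  names(set) <- x$ids
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}
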