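#' Shannon entropy of an alignment column
#'
#' `H = -sum(p_i * log2(p_i))` over the residue proportions of the
#' column, in bits.  0 for an invariant column; log2(20) ~ 4.32 bits at
#' the uniform maximum.  A column with entropy at or below 1.0 bit —
#' effectively two equiprobable residues or fewer — is treated as highly
#' conserved.
#'
#' @param column character vector of residues (one alignment column).
#' @return entropy in bits.
#' @examples
#' shannon_entropy(c("L", "L", "L"))       # 0
#' shannon_entropy(c("A", "A", "V", "V"))  # 1
#' @export
shannon_entropy <- function(column) {
  stopifnot(length(column) > 0L)
  p <- table(column)
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Physicochemical category of an alignment column
#'
#' Assigns exactly one category per column by the first matching rule of
#' an ordered decision list (precedence makes the categories exclusive):
#' \enumerate{
#'   \item one residue type only -> `INV` (invariant line)
#'   \item all hydrophobic -> `HB`
#'   \item all acidic -> `Ac`
#'   \item all basic -> `Bs`
#'   \item all polar-charged (acidic + basic) with both present -> `PC`
#'   \item all Ser/Thr -> `ST`
#'   \item at least one hydrophobic and one hydrophilic -> `HB_HL`
#'   \item otherwise (hydrophilic-only mixtures beyond rules 3-6)
#'     -> `PU_PC`
#' }
#'
#' @param column character vector of residues.
#' @param scheme a [class_scheme()].
#' @return one of `"INV" "HB" "Ac" "Bs" "PC" "ST" "HB_HL" "PU_PC"`.
#' @export
column_category <- function(column, scheme = default_scheme()) {
  stopifnot(length(column) > 0L)
  u <- unique(column)
  if (length(u) == 1L) return("INV")
  if (all(u %in% scheme$hydrophobic)) return("HB")
  if (all(u %in% scheme$acidic)) return("Ac")
  if (all(u %in% scheme$basic)) return("Bs")
  pc <- c(scheme$acidic, scheme$basic)
  if (all(u %in% pc) && any(u %in% scheme$acidic) &&
      any(u %in% scheme$basic)) return("PC")
  if (all(u %in% scheme$ser_thr)) return("ST")
  if (any(u %in% scheme$hydrophobic) &&
      any(u %in% scheme$hydrophilic)) return("HB_HL")
  "PU_PC"
}

POSITION_CATEGORIES <- c("INV", "HB", "Ac", "Bs", "PC", "ST",
                         "HB_HL", "PU_PC")

#' Per-column positional analysis of a block
#'
#' For every column: Shannon entropy (bits), the invariant flag, the
#' conserved flag (entropy at or below `entropy_threshold`) and the
#' eight-way class category.  The aggregate gives one summary row per
#' block: the percent of columns per category (the categories partition
#' the columns, so they sum to 100 up to rounding), plus the percent of
#' invariant and of conserved columns.  Conservation overlaps the
#' categories and is reported separately.
#'
#' @param x a [block].
#' @param scheme a [class_scheme()].
#' @param entropy_threshold conservation threshold in bits (default 1.0).
#' @return An object of class `"positional_summary"`: list with
#'   `profile` (data.frame: `column` 1-based, `entropy_bits`,
#'   `invariant`, `conserved`, `category`), `category_percent` (named
#'   numeric over the 8 categories), `inv_percent`, `conv_percent`,
#'   `entropy_threshold`.
#' @export
positional_summary <- function(x, scheme = default_scheme(),
                               entropy_threshold = 1.0) {
  stopifnot(inherits(x, "block"))
  m <- block_matrix(x)
  ent <- apply(m, 2L, shannon_entropy)
  cat_ <- apply(m, 2L, column_category, scheme = scheme)
  inv <- cat_ == "INV"
  profile <- data.frame(
    column = seq_len(x$width),
    entropy_bits = ent,
    invariant = inv,
    conserved = ent <= entropy_threshold,
    category = cat_,
    stringsAsFactors = FALSE)
  pct <- 100 * vapply(POSITION_CATEGORIES,
                      function(k) sum(cat_ == k), 0) / x$width
  structure(
    list(profile = profile,
         category_percent = pct,
         inv_percent = 100 * mean(inv),
         conv_percent = 100 * mean(profile$conserved),
         entropy_threshold = entropy_threshold),
    class = "positional_summary")
}

#' @export
print.positional_summary <- function(x, ...) {
  cat(sprintf(
    "Positional summary over %d columns (conserved: H <= %.1f bits)\n",
    nrow(x$profile), x$entropy_threshold))
  cat(sprintf("  INV %.1f%%  CONV %.1f%%\n",
              x$inv_percent, x$conv_percent))
  cat("  ", paste(sprintf("%s %.1f", names(x$category_percent),
                          x$category_percent), collapse = "  "),
      "\n", sep = "")
  invisible(x)
}
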