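#' Fit the full substitution-pair analysis on a block
#'
#' The one-stop fitting function: counts the substitution pairs, derives
#' every block-level parameter (E, R, D, RD/MDR, CD), builds the
#' hetero-pair probability table and the per-column positional profile.
#' The result holds the itemized record the report writer emits:
#' Item A block metadata, Item B the 20x20 pair-count matrix, Item C the
#' parameter summary, Item D the residue-diversity table, Item E the
#' probability table, Item F the positional analysis.  All percentages
#' are re-derivable from the Item B integer counts.
#'
#' @param x a [block], or a path to a BLOCK-FASTA file.
#' @param scheme a [class_scheme()].
#' @param name block name used in reports (defaults to the file name or
#'   `"block"`).
#' @param entropy_threshold conservation threshold in bits for the
#'   positional analysis (default 1.0).
#' @param n_bins probability bins for Item E (default 10).
#' @return An object of class `"apbest"`: list with `name`, `block`,
#'   `scheme`, `pair_counts`, `summary` (a [block_summary()]),
#'   `probability` (a [probability_table()] or NULL for fully invariant
#'   blocks), `positional` (a [positional_summary()]).
#' @examples
#' fit <- apbest(generate_block(width = 60, depth = 8, seed = 7))
#' fit
#' coef(fit)
#' @export
apbest <- function(x, scheme = default_scheme(), name = NULL,
                   entropy_threshold = 1.0, n_bins = 10L) {
  if (is.character(x) && length(x) == 1L) {
    if (is.null(name))
      name <- sub("\\.[^.]*$", "", basename(x))
    x <- read_block_fasta(x)
  }
  stopifnot(inherits(x, "block"), inherits(scheme, "class_scheme"))
  if (is.null(name)) name <- "block"

  pc <- count_pairs(x)
  summ <- block_summary(pc, scheme)
  prob <- if (pc$hetero_total > 0L) probability_table(pc, n_bins)
          else NULL
  pos <- positional_summary(x, scheme, entropy_threshold)

  structure(
    list(name = name, block = x, scheme = scheme,
         pair_counts = pc, summary = summ,
         probability = prob, positional = pos),
    class = "apbest")
}

#' @export
print.apbest <- function(x, ...) {
  cat("Substitution-pair analysis of block '", x$name, "' (",
      x$block$depth, " x ", x$block$width, ")\n", sep = "")
  print(x$summary)
  cat(sprintf("INV %.1f%%  CONV %.1f%% (H <= %.1f bits)\n",
              x$positional$inv_percent, x$positional$conv_percent,
              x$positional$entropy_threshold))
  invisible(x)
}

#' @export
summary.apbest <- function(object, ...) {
  structure(object, class = c("summary.apbest", class(object)))
}

#' @export
print.summary.apbest <- function(x, ...) {
  cat("== Item A: block ==\n")
  cat(sprintf("  name %s  depth %d  width %d\n",
              x$name, x$block$depth, x$block$width))
  cat("== Item B: pair counts ==\n  ")
  print(x$pair_counts)
  cat("== Item C: parameters ==\n  ")
  print(x$summary)
  cat("== Item D: residue diversity (non-zero) ==\n")
  rd <- x$summary$rd[x$summary$rd > 0]
  if (length(rd))
    cat("  ", paste(sprintf("%s %.1f", names(rd), rd),
                    collapse = "  "), "\n", sep = "")
  else cat("  none\n")
  cat("== Item E: probability table ==\n  ")
  if (is.null(x$probability)) cat("no hetero-pairs\n")
  else print(x$probability)
  cat("== Item F: positional ==\n  ")
  print(x$positional)
  invisible(x)
}

#' Extract the block parameters as a named vector
#'
#' @param object an [apbest()] fit.
#' @param ... unused.
#' @return named numeric: `E`, `R`, `D_percent`, `RD_max`, `RD_min`,
#'   the five `CD_*` values, `INV_percent`, `CONV_percent`.
#' @export
coef.apbest <- function(object, ...) {
  s <- object$summary
  c(E = s$E, R = s$R,
    D_percent = if (s$no_hetero) 0 else s$dominant$percent,
    RD_max = if (s$no_hetero) 0 else unname(s$rd[s$mdr]),
    RD_min = if (s$no_hetero) 0 else unname(s$rd[s$rd_min]),
    CD_acidic = unname(s$cd["acidic"]),
    CD_basic = unname(s$cd["basic"]),
    CD_non_polar = unname(s$cd["non_polar"]),
    CD_hydrophobic = unname(s$cd["hydrophobic"]),
    CD_hydrophilic = unname(s$cd["hydrophilic"]),
    INV_percent = object$positional$inv_percent,
    CONV_percent = object$positional$conv_percent)
}

#' Plot the hetero-pair probability distribution of a fit
#'
#' Bar plot of the number of hetero-pair types per probability bin
#' (Item E), the in-package analogue of the frequency-versus-probability
#' distribution plots.
#'
#' @param x an [apbest()] fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.apbest <- function(x, ...) {
  if (is.null(x$probability)) {
    warning("no hetero-pairs; nothing to plot")
    return(invisible(NULL))
  }
  b <- x$probability$bins
  graphics::barplot(
    b$n_types,
    names.arg = sprintf("%.3f", (b$lower + b$upper) / 2),
    xlab = "observed probability (bin midpoint)",
    ylab = "number of hetero-pair types",
    main = paste0("Hetero-pair probability distribution: ", x$name),
    ...)
  invisible(x)
}
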