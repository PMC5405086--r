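#' One summary row per fitted block
#'
#' Serializes a fit's Item C into a single data.frame row mirroring the
#' package's summary-table column order (name, R, E, MDR with its RD,
#' minimally diverse residue with its RD, dominant pair with its share,
#' then the five CD columns).  Numbers are formatted to 1 decimal place
#' for reporting; the exact values live in the fit.
#'
#' @param fit an [apbest()] fit.
#' @param formatted if `TRUE` (default) numeric columns are 1-decimal
#'   strings (byte-stable output); if `FALSE` they stay numeric.
#' @return one-row data.frame.
#' @export
summary_row <- function(fit, formatted = TRUE) {
  stopifnot(inherits(fit, "apbest"))
  s <- fit$summary
  fmt <- function(v) if (formatted) sprintf("%.1f", v) else v
  data.frame(
    name = fit$name,
    R = fmt(s$R),
    E = fmt(s$E),
    MDR = if (s$no_hetero) "" else s$mdr,
    RD_max = fmt(if (s$no_hetero) 0 else unname(s$rd[s$mdr])),
    RD_min_residue = if (s$no_hetero) "" else s$rd_min,
    RD_min = fmt(if (s$no_hetero) 0 else unname(s$rd[s$rd_min])),
    D = if (s$no_hetero) "" else s$dominant$pair,
    D_percent = fmt(if (s$no_hetero) 0 else s$dominant$percent),
    CD_acidic = fmt(unname(s$cd["acidic"])),
    CD_basic = fmt(unname(s$cd["basic"])),
    CD_non_polar = fmt(unname(s$cd["non_polar"])),
    CD_hydrophobic = fmt(unname(s$cd["hydrophobic"])),
    CD_hydrophilic = fmt(unname(s$cd["hydrophilic"])),
    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

#' Write the itemized report of a fit
#'
#' Emits the Excel-openable TSV bundle, one file per item:
#' \describe{
#'   \item{itemA_block.tsv}{block metadata (name, depth, width)}
#'   \item{itemB_pair_counts.tsv}{the 20x20 symmetric count matrix}
#'   \item{itemC_summary.tsv}{one parameter row ([summary_row()])}
#'   \item{itemD_residue_diversity.tsv}{RD per residue, 1 decimal}
#'   \item{itemE_probability.tsv, itemE_bins.tsv}{hetero-pair
#'     probability table and bins (omitted when no hetero-pairs)}
#'   \item{itemF_positional.tsv, itemF_summary.tsv}{per-column profile
#'     and the aggregate category percentages}
#' }
#' Output is deterministic: identical fits give byte-identical files
#' (fixed ordering, fixed 1-decimal formatting of percentages).
#'
#' @param fit an [apbest()] fit.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(fit, dir) {
  stopifnot(inherits(fit, "apbest"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  write_tsv(data.frame(name = fit$name, depth = fit$block$depth,
                       width = fit$block$width), p("itemA_block.tsv"))
  write_pair_counts_tsv(fit$pair_counts, p("itemB_pair_counts.tsv"))
  write_tsv(summary_row(fit), p("itemC_summary.tsv"))
  write_tsv(data.frame(residue = AA,
                       RD = sprintf("%.1f", fit$summary$rd)),
            p("itemD_residue_diversity.tsv"))
  if (!is.null(fit$probability)) {
    e <- fit$probability$entries
    e$probability <- sprintf("%.6f", e$probability)
    write_tsv(e, p("itemE_probability.tsv"))
    b <- fit$probability$bins
    b$lower <- sprintf("%.6f", b$lower)
    b$upper <- sprintf("%.6f", b$upper)
    write_tsv(b, p("itemE_bins.tsv"))
  }
  prof <- fit$positional$profile
  prof$entropy_bits <- sprintf("%.4f", prof$entropy_bits)
  write_tsv(prof, p("itemF_positional.tsv"))
  pos <- fit$positional
  write_tsv(data.frame(
    name = fit$name,
    INV = sprintf("%.1f", pos$inv_percent),
    CONV = sprintf("%.1f", pos$conv_percent),
    as.list(stats::setNames(sprintf("%.1f", pos$category_percent),
                            names(pos$category_percent))),
    check.names = FALSE), p("itemF_summary.tsv"))
  invisible(dir)
}

#' Read back the summary row of a written report
#'
#' Parses `itemC_summary.tsv` from a [write_report()] directory; the
#' round trip `read_summary_tsv(write_report(fit))` reproduces
#' `summary_row(fit)` exactly.
#'
#' @param dir report directory.
#' @return one-row data.frame with the [summary_row()] columns.
#' @export
read_summary_tsv <- function(dir) {
  path <- file.path(dir, "itemC_summary.tsv")
  if (!file.exists(path))
    stop_blocksub("io", paste0("no itemC_summary.tsv in ", dir))
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
}

#' Correlate R with divergence rates across blocks
#'
#' Pearson product-moment correlation of the non-conservative to
#' conservative ratio R against literature-tabulated divergence rates
#' (percent change per 100 Myr).  Rates are user inputs: divergence-rate
#' estimation is out of scope.
#'
#' @param r_values numeric vector of R values (percent), one per block.
#' @param rates numeric vector of divergence rates, same length.
#' @return Pearson r.
#' @examples
#' fam <- reference_families()
#' correlate_with_divergence(fam$R, fam$divergence_rate)
#' @export
correlate_with_divergence <- function(r_values, rates) {
  if (length(r_values) != length(rates))
    stop_blocksub("insufficient_data",
      "r_values and rates differ in length")
  ok <- stats::complete.cases(r_values, rates)
  if (sum(ok) < 3L)
    stop_blocksub("insufficient_data",
      "need at least 3 blocks with rates for a correlation")
  if (stats::sd(r_values[ok]) == 0 || stats::sd(rates[ok]) == 0)
    stop_blocksub("zero_variance",
      "zero variance in R or in the rates; correlation undefined")
  stats::cor(r_values[ok], rates[ok])
}
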