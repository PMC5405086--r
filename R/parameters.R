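#' Hetero-pair type usage E
#'
#' E is the percentage of the 190 possible hetero-pair types actually
#' observed in the block: `100 * n_observed_types / 190`.  E = 0 means
#' no substitution at all (every column invariant in pairwise terms);
#' E = 100 means every hetero-pair type occurs at least once.  E is a
#' type-usage measure, so it ignores how often each type occurs.
#'
#' @param pc a [count_pairs()] result.
#' @return percent in `[0, 100]`.
#' @export
compute_E <- function(pc) {
  stopifnot(inherits(pc, "pair_counts"))
  het <- hetero_frequencies(pc)
  100 * sum(het > 0L) / 190
}

#' Non-conservative to conservative substitution ratio R
#'
#' Hetero-pairs within the hydrophobic or within the hydrophilic class
#' (HB-HB, HL-HL) are conservative substitutions; cross-class pairs
#' (HB-HL) are non-conservative.  R is the percentage ratio of their
#' observed frequencies:
#' `R = 100 * freq(HB-HL) / (freq(HB-HB) + freq(HL-HL))`.
#' R correlates positively with a family's divergence rate, which makes
#' it the block parameter of principal evolutionary interest.
#'
#' A block with no hetero-pairs at all returns 0 with attribute
#' `no_hetero_pairs = TRUE`.  Hetero-pairs present but none conservative
#' raises `blocksub_no_conservative` (ratio undefined).
#'
#' @param pc a [count_pairs()] result.
#' @param scheme a [class_scheme()].
#' @return non-negative percent.
#' @seealso [r_from_cd()] for the algebraic identity linking R to the
#'   hydrophobic/hydrophilic class diversities.
#' @export
compute_R <- function(pc, scheme = default_scheme()) {
  stopifnot(inherits(pc, "pair_counts"))
  if (pc$hetero_total == 0L)
    return(structure(0, no_hetero_pairs = TRUE))
  cat_m <- pair_category_matrix(scheme)
  ut <- upper.tri(pc$counts)
  cons <- sum(pc$counts[ut & cat_m %in% c("HB_HB", "HL_HL")])
  cross <- sum(pc$counts[ut & cat_m == "HB_HL"])
  if (cons == 0L)
    stop_blocksub("no_conservative",
      "no conservative substitutions observed; R is undefined")
  100 * cross / cons
}

#' Recover R from the hydrophobic and hydrophilic class diversities
#'
#' Because every hetero-pair occurrence involves the hydrophobic class,
#' the hydrophilic class, or both, the class diversities CD_HB and CD_HL
#' (each the percent of hetero occurrences with at least one member in
#' the class) overlap exactly on the cross-class share.  This forces the
#' identity
#' `R = 100 * (CD_HB + CD_HL - 100) / (200 - CD_HB - CD_HL)`,
#' which lets R be recovered from published CD values alone.
#'
#' @param cd_hb,cd_hl hydrophobic and hydrophilic class diversities, in
#'   percent.
#' @return R in percent.
#' @examples
#' r_from_cd(69.4, 66.1)  # ~55
#' @export
r_from_cd <- function(cd_hb, cd_hl) {
  100 * (cd_hb + cd_hl - 100) / (200 - cd_hb - cd_hl)
}

#' Dominant hetero-pair D
#'
#' The hetero-pair type with maximal observed frequency, and its share
#' of the total hetero-pair count in percent.  Ties are broken by
#' alphabetical order of the two-letter pair label.
#'
#' @param pc a [count_pairs()] result.
#' @return list with `pair` (e.g. `"LV"`) and `percent`.
#' @export
dominant_pair <- function(pc) {
  stopifnot(inherits(pc, "pair_counts"))
  if (pc$hetero_total == 0L)
    stop_blocksub("no_hetero",
      "no hetero-pairs observed; dominant pair undefined")
  het <- hetero_frequencies(pc)
  best <- sort(names(het)[het == max(het)])[1L]  # alphabetical tie-break
  list(pair = best,
       percent = 100 * het[[best]] / pc$hetero_total)
}

#' Residue diversity RD, maximally and minimally diverse residues
#'
#' RD(x) is the share of hetero-pair occurrences that involve residue x:
#' `100 * (hetero occurrences containing x) / (total hetero
#' occurrences)`.  Each occurrence has two member residues, so RD sums
#' to 200 over the 20 residues.  MDR (the maximally diverse residue) is
#' the argmax; RDmin the argmin; ties break alphabetically.  Residues
#' never seen in a hetero-pair get RD 0.
#'
#' @param pc a [count_pairs()] result.
#' @return list with `rd` (named numeric of length 20), `mdr`, `rd_min`
#'   (residue codes).
#' @export
residue_diversity <- function(pc) {
  stopifnot(inherits(pc, "pair_counts"))
  if (pc$hetero_total == 0L)
    stop_blocksub("no_hetero",
      "no hetero-pairs observed; residue diversity undefined")
  off <- pc$counts
  diag(off) <- 0L
  rd <- 100 * rowSums(off) / pc$hetero_total
  list(rd = rd,
       mdr = AA[which.max(rd)],
       rd_min = AA[which.min(rd)])
}

#' Class-specific diversity CD
#'
#' CD(c) is the percent of hetero-pair occurrences with at least one
#' member residue in class c, for the classes acidic, basic, non-polar,
#' hydrophobic and hydrophilic.  CD is occurrence-weighted (frequency
#' share, not type-count share); with that convention CD_HB + CD_HL
#' equals 100 plus the cross-class (non-conservative) share, which is
#' what makes [r_from_cd()] exact.
#'
#' @param pc a [count_pairs()] result.
#' @param scheme a [class_scheme()].
#' @return named numeric: `acidic`, `basic`, `non_polar`, `hydrophobic`,
#'   `hydrophilic`, each in `[0, 100]`.
#' @export
class_diversity <- function(pc, scheme = default_scheme()) {
  stopifnot(inherits(pc, "pair_counts"))
  if (pc$hetero_total == 0L)
    stop_blocksub("no_hetero",
      "no hetero-pairs observed; class diversity undefined")
  ut <- which(upper.tri(pc$counts), arr.ind = TRUE)
  a <- AA[ut[, "row"]]; b <- AA[ut[, "col"]]
  cnt <- pc$counts[upper.tri(pc$counts)]
  share <- function(members)
    100 * sum(cnt[a %in% members | b %in% members]) / pc$hetero_total
  c(acidic      = share(scheme$acidic),
    basic       = share(scheme$basic),
    non_polar   = share(scheme$non_polar),
    hydrophobic = share(scheme$hydrophobic),
    hydrophilic = share(scheme$hydrophilic))
}

#' Block-level parameter summary
#'
#' Computes every block-level evolutionary parameter from a pair-count
#' matrix in one call: E, R, the dominant pair D, RD/MDR and CD.  This
#' is the record behind one row of the package's summary table.
#'
#' @param pc a [count_pairs()] result.
#' @param scheme a [class_scheme()].
#' @return An object of class `"block_summary"`: list with `E`, `R`,
#'   `no_hetero` flag, `dominant` (or NULL), `rd`, `mdr`, `rd_min`,
#'   `cd`.
#' @export
block_summary <- function(pc, scheme = default_scheme()) {
  no_het <- pc$hetero_total == 0L
  r <- compute_R(pc, scheme)
  out <- list(
    E = compute_E(pc),
    R = as.numeric(r),
    no_hetero = no_het,
    dominant = if (no_het) NULL else dominant_pair(pc),
    rd = if (no_het) stats::setNames(numeric(20), AA)
         else residue_diversity(pc)$rd,
    mdr = if (no_het) NA_character_ else residue_diversity(pc)$mdr,
    rd_min = if (no_het) NA_character_ else residue_diversity(pc)$rd_min,
    cd = if (no_het)
           c(acidic = 0, basic = 0, non_polar = 0,
             hydrophobic = 0, hydrophilic = 0)
         else class_diversity(pc, scheme))
  structure(out, class = "block_summary")
}

#' @export
print.block_summary <- function(x, ...) {
  if (x$no_hetero) {
    cat("Block summary: no hetero-pairs (fully invariant block); ",
        "E = 0, R = 0\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("E = %.1f%%  R = %.1f%%  D = %s (%.1f%%)\n",
              x$E, x$R, x$dominant$pair, x$dominant$percent))
  cat(sprintf("MDR = %s (%.1f)  RDmin = %s (%.1f)\n",
              x$mdr, x$rd[x$mdr], x$rd_min, x$rd[x$rd_min]))
  cat("CD:", paste(sprintf("%s %.1f", names(x$cd), x$cd),
                   collapse = "  "), "\n")
  invisible(x)
}
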