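#' Amino-acid class scheme
#'
#' The partition of the 20 standard residues that drives pair
#' categorization, conservative/non-conservative labeling and positional
#' class typing.  The top split is hydrophobic (HB, 9 residues) versus
#' hydrophilic (HL, 11 residues) — the only split sizes compatible with
#' the 36 HB-HB, 55 HL-HL and 99 HB-HL hetero-pair type counts.  The
#' hydrophilic class is further partitioned into acidic, basic and
#' polar-uncharged sub-classes; Ser/Thr and non-polar are auxiliary sets
#' used in positional typing and class diversity.
#'
#' `default_scheme()` uses a common hydropathy grouping:
#' HB = \{A, V, L, I, P, F, M, W, C\},
#' HL = \{G, S, T, Y, N, Q, D, E, K, R, H\},
#' acidic = \{D, E\}, basic = \{K, R, H\},
#' polar-uncharged = \{G, S, T, Y, N, Q\}, non-polar = HB + G.
#' Class membership beyond the 9/11 sizes is a convention, so the scheme
#' is injectable everywhere: any alternative 9/11 partition satisfying
#' the invariants can be passed to [apbest()], [count_pairs()] etc.
#'
#' @param hydrophobic,hydrophilic,acidic,basic,polar_uncharged,non_polar
#'   character vectors of one-letter residue codes.  Invariants:
#'   HB and HL partition the 20 residues with sizes 9 and 11; acidic,
#'   basic and polar-uncharged partition HL; acidic and basic are the
#'   polar-charged set.
#' @return An object of class `"class_scheme"`.
#' @examples
#' s <- default_scheme()
#' length(s$hydrophobic)  # 9
#' @export
class_scheme <- function(hydrophobic, hydrophilic, acidic, basic,
                         polar_uncharged, non_polar) {
  norm <- function(x) sort(unique(toupper(as.character(x))))
  s <- list(hydrophobic = norm(hydrophobic),
            hydrophilic = norm(hydrophilic),
            acidic = norm(acidic),
            basic = norm(basic),
            polar_uncharged = norm(polar_uncharged),
            ser_thr = c("S", "T"),
            non_polar = norm(non_polar))

  all_res <- sort(c(s$hydrophobic, s$hydrophilic))
  if (!identical(all_res, AA) ||
      length(intersect(s$hydrophobic, s$hydrophilic)) > 0L)
    stop_blocksub("bad_scheme",
      "hydrophobic and hydrophilic must partition the 20 standard residues")
  if (length(s$hydrophobic) != 9L)
    stop_blocksub("bad_scheme",
      "hydrophobic class must have 9 residues (and hydrophilic 11)")
  hl_parts <- sort(c(s$acidic, s$basic, s$polar_uncharged))
  if (!identical(hl_parts, s$hydrophilic) ||
      anyDuplicated(c(s$acidic, s$basic, s$polar_uncharged)))
    stop_blocksub("bad_scheme",
      "acidic, basic and polar_uncharged must partition the hydrophilic class")
  if (!all(s$non_polar %in% AA))
    stop_blocksub("bad_scheme", "non_polar contains unknown residues")

  structure(s, class = "class_scheme")
}

#' @rdname class_scheme
#' @export
default_scheme <- function() {
  hb <- c("A", "V", "L", "I", "P", "F", "M", "W", "C")
  class_scheme(
    hydrophobic = hb,
    hydrophilic = c("G", "S", "T", "Y", "N", "Q", "D", "E", "K", "R", "H"),
    acidic = c("D", "E"),
    basic = c("K", "R", "H"),
    polar_uncharged = c("G", "S", "T", "Y", "N", "Q"),
    non_polar = c(hb, "G"))
}

#' @export
print.class_scheme <- function(x, ...) {
  cat("Amino-acid class scheme\n")
  for (nm in names(x))
    cat(sprintf("  %-16s %s\n", nm, paste(x[[nm]], collapse = "")))
  invisible(x)
}

#' Read a class scheme from a config file
#'
#' One `key = value` pair per line, keys being the class names of
#' [class_scheme()] and values residue strings, e.g.
#' `hydrophobic = AVLIPFMWC`.  Blank lines and `#` comments are
#' ignored; missing keys fall back to the default scheme.  The result is
#' validated against the scheme invariants.
#'
#' @param path config file path.
#' @return A `class_scheme`.
#' @export
read_class_scheme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  d <- default_scheme()
  vals <- list(hydrophobic = d$hydrophobic, hydrophilic = d$hydrophilic,
               acidic = d$acidic, basic = d$basic,
               polar_uncharged = d$polar_uncharged,
               non_polar = d$non_polar)
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop_blocksub("bad_scheme", paste0("cannot parse line: ", ln))
    key <- trimws(kv[1L])
    if (!key %in% names(vals))
      stop_blocksub("bad_scheme", paste0("unknown class name: ", key))
    vals[[key]] <- strsplit(gsub("[ ,]", "", toupper(kv[2L])), "")[[1L]]
  }
  do.call(class_scheme, vals)
}

#' Categorize a residue pair
#'
#' An unordered residue pair is `HOMO` when the residues are identical,
#' otherwise `HB_HB`, `HL_HL` or `HB_HL` by the class membership of its
#' members.  `HB_HB` and `HL_HL` hetero-pairs are conservative
#' substitutions; `HB_HL` pairs are non-conservative.  Symmetric in
#' `(a, b)`; vectorized.
#'
#' @param a,b one-letter residue codes (recycled to common length).
#' @param scheme a [class_scheme()].
#' @return character vector in `{"HOMO", "HB_HB", "HL_HL", "HB_HL"}`.
#' @examples
#' pair_category("L", "V", default_scheme())  # conservative hydrophobic
#' @export
pair_category <- function(a, b, scheme = default_scheme()) {
  a <- toupper(a); b <- toupper(b)
  stopifnot(all(a %in% AA), all(b %in% AA))
  a_hb <- a %in% scheme$hydrophobic
  b_hb <- b %in% scheme$hydrophobic
  out <- ifelse(a == b, "HOMO",
         ifelse(a_hb & b_hb, "HB_HB",
         ifelse(!a_hb & !b_hb, "HL_HL", "HB_HL")))
  out
}

#' Enumerate the 210 unordered residue pair types
#'
#' Lists all C(21, 2) = 210 unordered pairs of the 20 standard residues
#' (20 homo-pairs on the diagonal, 190 hetero-pairs off it) with their
#' category under `scheme`.  With the default 9/11 scheme the
#' hetero-pairs split 36 HB-HB, 55 HL-HL and 99 HB-HL.
#'
#' @param scheme a [class_scheme()].
#' @return data.frame with columns `a`, `b` (a <= b alphabetically),
#'   `pair` (two-letter label) and `category`.
#' @export
enumerate_pair_types <- function(scheme = default_scheme()) {
  idx <- which(upper.tri(diag(20), diag = TRUE), arr.ind = TRUE)
  a <- AA[idx[, "row"]]
  b <- AA[idx[, "col"]]
  data.frame(a = a, b = b, pair = paste0(a, b),
             category = pair_category(a, b, scheme),
             stringsAsFactors = FALSE)
}

# 20x20 category lookup used by the parameter computations
pair_category_matrix <- function(scheme) {
  m <- outer(AA, AA, function(a, b) pair_category(a, b, scheme))
  dimnames(m) <- list(AA, AA)
  m
}
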