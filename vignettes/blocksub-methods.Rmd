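---
title: "Methods: substitution-pair statistics for protein BLOCKs"
author: "blocksub"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substitution-pair statistics for protein BLOCKs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blocksub)
```

## The model

A BLOCK is a gap-free multiple alignment of orthologous protein
sequences: `depth` sequences, all of length `width`, over the 20
standard residues, with every column a fixed homologous position.
`blocksub` treats the block itself as the unit of analysis and never
builds or edits alignments; upstream steps (sequence retrieval,
alignment, block trimming, partial-sequence removal) are out of scope,
and malformed input is rejected with a named error rather than
repaired (`blocksub_gap_present`, `blocksub_unequal_length`,
`blocksub_illegal_residue`, `blocksub_duplicate_id`,
`blocksub_empty_input`).

Counting follows the convention of the BLOSUM family of matrices: for
each column, every unordered pair of the `depth` sequences contributes
one residue pair, so the total count is `width * choose(depth, 2)` and
frequencies are depth-weighted. No sequence weighting or percent-
identity clustering is applied — the statistics here describe the block
as given, not a redundancy-reduced version of it. Counts are kept as
exact integers; percentages are formed only at reporting time, so no
rounding drift accumulates.

Substitutions are labelled by a physicochemical class scheme. The top
split is hydrophobic (HB) versus hydrophilic (HL), sizes 9 and 11.
Those sizes are forced: the 190 hetero-pair types partition into 36
HB–HB, 55 HL–HL and 99 HB–HL types, and `C(9,2) = 36`, `C(11,2) = 55`,
`9 * 11 = 99` is the unique solution. Class *membership*, by contrast,
is a convention; the default follows common hydropathy groupings
(HB = A V L I P F M W C), places glutamine hydrophilic, histidine
basic, and glycine hydrophilic but also in the auxiliary non-polar set
(non-polar = HB + G). Because membership is conventional, the scheme
is a first-class injectable value: any alternative 9/11 partition
satisfying the invariants can be supplied programmatically or through
a small config file.

A hetero-pair within HB or within HL is a *conservative* substitution;
a cross-class (HB–HL) pair is *non-conservative*. This class-based
definition (rather than a substitution-score threshold) is what makes
the parameter algebra below exact.

## The parameters

All parameters are derived from the symmetric 20×20 count matrix and
reported in percent to one decimal place.

**E — hetero-pair type usage.** `E = 100 * (observed hetero types) /
190`. E is a *type-usage* measure: it counts which of the 190 types
occur at all, ignoring multiplicity, and so sets the usage limit of
the hetero-pair repertoire. 0 for a fully invariant block, 100 when
every type occurs.

**R — non-conservative/conservative ratio.**
`R = 100 * f(HB–HL) / (f(HB–HB) + f(HL–HL))` on observed frequencies.
R is the evolutionarily interesting parameter: across families it
tracks the literature divergence rate. A block with hetero-pairs but
no conservative ones has undefined R (error); a block with no
hetero-pairs at all reports R = 0 with an explicit flag.

**D — dominant pair.** The argmax of the 190 folded frequencies with
its percent share of the hetero total. Ties break by alphabetical
two-letter label, deterministically.

**RD and MDR.** `RD(x)` is residue *x*'s share of hetero occurrences.
Each occurrence has two members, so `sum(RD) = 200` identically — a
useful internal check. MDR is the argmax, the minimally diverse
residue the argmin, alphabetical tie-break.

**CD.** `CD(c)` is the percent of hetero occurrences with at least one
member in class *c*. RD and CD are *occurrence-weighted* (frequency
shares), not type-count shares. That choice is deliberate: with it,
CD_HB and CD_HL double-count exactly the cross-class occurrences, so

```
CD_HB + CD_HL = 100 + cross-class share
R = 100 * (CD_HB + CD_HL - 100) / (200 - CD_HB - CD_HL)
```

holds as an algebraic identity (`r_from_cd()`). Against the published
table of eight reference families the identity reproduces the
tabulated R within ±1 for seven rows:

```{r}
fam <- reference_families()
data.frame(family = fam$family, R = fam$R,
           R_identity = round(r_from_cd(fam$cd_hydrophobic,
                                        fam$cd_hydrophilic), 1))
```

The kappa-casein row (tabulated 92, identity ≈ 42) is internally
inconsistent as published; the package documents it and tests the
other seven. This seven-of-eight agreement is the strongest available
evidence for the occurrence-weighted reconstruction, and the package
ships the comparison as a doctest over the printed constants — it is a
statement about the published table's internal algebra, not a
reanalysis of the original sequence data.

A further tabulated ratio parameter, N, has no recoverable definition
(its published values match no reconstruction we tested), so the
package carries the column in `reference_families()` verbatim but does
not compute it.

## Positional analysis

Per column the package reports Shannon entropy
`H = -sum(p_i * log2(p_i))` in bits. The log base is a choice; bits
are used because with the conventional conservation threshold of
1.0, "conserved" then reads as "effectively at most two equiprobable
residues", the natural interpretation. The threshold is a tunable
argument (`entropy_threshold`, default 1.0 bit).

Each column also gets exactly one of eight categories by an ordered
decision list: INV (one residue type), HB (all hydrophobic), Ac (all
acidic), Bs (all basic), PC (acidic and basic mixed), ST (all
Ser/Thr), HB+HL (both top classes present), and PU+PC for the
remaining hydrophilic-only mixtures. Precedence — invariant first,
then pure-class rules, then mixed rules — is what makes the categories
exclusive, so their percentages partition the columns and sum to 100
up to 1-decimal rounding. Hydrophilic-only mixtures that are neither
purely charged nor purely Ser/Thr fold into PU+PC; a glycine/serine
column, for instance, types as PU+PC since G sits in the
polar-uncharged set. Conservation (H ≤ threshold) overlaps the
categories and is reported separately.

## The synthetic generator

`generate_block()` exists so every statistic is testable without
external data. It draws an ancestral sequence uniformly over the 20
residues and mutates each sequence independently from that ancestor —
a star phylogeny. Per sequence and unlocked column a substitution
happens with probability `p_sub`; it crosses the HB/HL boundary with
probability `p_cross` (uniform over the opposite class) and otherwise
stays within class (uniform over the other same-class residues). A
fraction `invariant_fraction` of columns is locked. Defaults: width
200, depth 20, `p_sub` 0.2, `p_cross` 0.3, `invariant_fraction` 0.1 —
a mid-divergence block at the scale used for the parameter-recovery
checks.

The generator emulates exactly the features the statistics measure:
a tunable conservative/non-conservative mix, locked invariant lines,
and seed-reproducibility. `p_cross = 0` forces R = 0 exactly, and the
recovered R increases with `p_cross` — the desk-scale analogue of R
tracking divergence rate. It does *not* emulate real data in other
respects: no tree structure (a star phylogeny has no shared internal
branches), no rate heterogeneity across sites beyond the locked
columns, no realistic amino-acid composition, and no
substitution-matrix bias within a class. Passing recovery tests
therefore demonstrates that the estimators measure what they claim on
data with known structure — not that real families satisfy the
generator's assumptions.

## Numerical and design choices

- Exact integer counts throughout; one shared folding of the 190
  off-diagonal cells; percentages formatted to one decimal only in
  reports.
- Deterministic tie-breaks (alphabetical pair label / residue) for D,
  MDR and the minimally diverse residue.
- Probability bins for the frequency-versus-probability table: 10
  equal-width bins on `[0, max probability]`, half-open `[lo, hi)`
  with the last bin closed, so the dominant pair always lands in the
  highest occupied bin. Curve fitting to the binned distribution is
  out of scope.
- Ambiguous residues (X, B, Z, U, O, J) are rejected by default —
  validation never silently repairs — with an explicit
  `drop_bad_columns` opt-in that removes offending columns and logs
  them. Gaps are always fatal.
- Degenerate blocks (no hetero-pairs) propagate as flagged zeros for
  E/R and as named errors for the parameters that are genuinely
  undefined (D, RD, CD, probability table).
- Divergence rates are user-supplied literature values; the package
  correlates against them (`correlate_with_divergence()`, Pearson)
  but never estimates rates.
- Report output is TSV (Excel-openable), byte-deterministic given the
  same fit: fixed column order, fixed formatting.

Test problem sizes were chosen to exercise the combinatorics well
inside a desk-scale budget: oracle equivalence on 100 random blocks up
to 10 sequences × 50 columns against a brute-force double loop;
invariant sweeps on 40 mixed random/synthetic blocks; parameter
recovery on 50 replicates of 200-column, 20-sequence blocks per
`p_cross` level.

## Limitations

- Published per-family values for real families are not reproducible
  here because the original sequence selections are unpublished; the
  package instead verifies the printed-table algebra (the R-from-CD
  identity, the R–rate correlation) and all internal invariants.
- Conservativeness is class-based only; score-based (substitution
  matrix) definitions would label borderline pairs differently.
- The 9/11 class membership is a convention fixed only up to the
  36/55/99 type counts; alternative memberships shift R, CD and the
  column typing, which is why the scheme is injectable.
- Depth-weighted counting means deep, redundant blocks weight common
  lineages heavily; no clustering correction is applied.
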