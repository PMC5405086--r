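test_that("default scheme has the forced 9/11 hydrophobic/hydrophilic split", {
  s <- default_scheme()
  expect_length(s$hydrophobic, 9L)
  expect_length(s$hydrophilic, 11L)
  expect_setequal(c(s$hydrophobic, s$hydrophilic), AA20)
  expect_true("Q" %in% s$hydrophilic)
  expect_setequal(s$acidic, c("D", "E"))
  expect_setequal(s$basic, c("K", "R", "H"))
  expect_setequal(s$ser_thr, c("S", "T"))
  # sub-classes partition the hydrophilic class
  expect_setequal(c(s$acidic, s$basic, s$polar_uncharged), s$hydrophilic)
  expect_setequal(s$non_polar, c(s$hydrophobic, "G"))
})

test_that("pair types enumerate to 20 homo + 190 hetero split 36/55/99", {
  pt <- enumerate_pair_types()
  expect_equal(nrow(pt), 210L)
  tab <- table(pt$category)
  expect_equal(as.integer(tab[c("HOMO", "HB_HB", "HL_HL", "HB_HL")]),
               c(20L, 36L, 55L, 99L))
})

test_that("pair categorization is symmetric and class-driven", {
  s <- default_scheme()
  expect_equal(pair_category("L", "V", s), "HB_HB")
  expect_equal(pair_category("E", "D", s), "HL_HL")
  expect_equal(pair_category("A", "A", s), "HOMO")
  expect_equal(pair_category("A", "D", s), "HB_HL")
  # symmetry over all ordered pairs
  m <- outer(AA20, AA20, pair_category, scheme = s)
  expect_true(all(m == t(m)))
})

test_that("scheme invariants are enforced by the constructor", {
  d <- default_scheme()
  # 8/12 split rejected
  expect_error(
    class_scheme(hydrophobic = setdiff(d$hydrophobic, "C"),
                 hydrophilic = c(d$hydrophilic, "C"),
                 acidic = d$acidic, basic = d$basic,
                 polar_uncharged = c(d$polar_uncharged, "C"),
                 non_polar = d$non_polar),
    class = "blocksub_bad_scheme")
  # overlapping top classes rejected
  expect_error(
    class_scheme(hydrophobic = d$hydrophobic,
                 hydrophilic = c(d$hydrophilic, "A"),
                 acidic = d$acidic, basic = d$basic,
                 polar_uncharged = d$polar_uncharged,
                 non_polar = d$non_polar),
    class = "blocksub_bad_scheme")
  # sub-classes must partition hydrophilic
  expect_error(
    class_scheme(hydrophobic = d$hydrophobic,
                 hydrophilic = d$hydrophilic,
                 acidic = c("D", "E", "K"), basic = d$basic,
                 polar_uncharged = d$polar_uncharged,
                 non_polar = d$non_polar),
    class = "blocksub_bad_scheme")
})

test_that("an alternative 9/11 partition is accepted and changes categories", {
  d <- default_scheme()
  # swap C (hydrophobic) with G (hydrophilic)
  alt <- class_scheme(
    hydrophobic = c(setdiff(d$hydrophobic, "C"), "G"),
    hydrophilic = c(setdiff(d$hydrophilic, "G"), "C"),
    acidic = d$acidic, basic = d$basic,
    polar_uncharged = c(setdiff(d$polar_uncharged, "G"), "C"),
    non_polar = d$non_polar)
  expect_equal(pair_category("C", "G", alt), "HB_HL")
  expect_equal(pair_category("C", "G", d), "HB_HL")
  expect_equal(pair_category("C", "A", alt), "HB_HL")
  tab <- table(enumerate_pair_types(alt)$category)
  expect_equal(as.integer(tab[c("HB_HB", "HL_HL", "HB_HL")]),
               c(36L, 55L, 99L))
})

test_that("a scheme config file round-trips through the validator", {
  f <- tempfile(fileext = ".cfg")
  writeLines(c("# comment",
               "hydrophobic = AVLIPFMWC",
               "hydrophilic = GSTYNQDEKRH",
               "acidic = DE",
               "basic = KRH",
               "polar_uncharged = GSTYNQ",
               "non_polar = AVLIPFMWCG"), f)
  expect_equal(read_class_scheme(f), default_scheme())
  writeLines("hydrophobic AVLIPFMWC", f)
  expect_error(read_class_scheme(f), class = "blocksub_bad_scheme")
})
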