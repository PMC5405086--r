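test_that("column entropy gives log2(k) bits for uniform k-residue columns", {
  expect_equal(shannon_entropy(rep("L", 5)), 0)
  expect_equal(shannon_entropy(c("A", "V")), 1)
  expect_equal(shannon_entropy(c("A", "A", "V", "V")), 1)
  expect_equal(shannon_entropy(c("A", "C", "D", "E")), 2)
  expect_equal(shannon_entropy(rep(AA20, 2)), log2(20))
})

test_that("entropy never decreases when a column is made more even", {
  set.seed(31)
  for (i in 1:20) {
    col <- sample(AA20[1:4], 12, replace = TRUE)
    tab <- table(col)
    if (length(tab) < 2 || max(tab) - min(tab) < 2) next
    hi <- names(tab)[which.max(tab)]
    lo <- names(tab)[which.min(tab)]
    col2 <- col
    col2[which(col == hi)[1]] <- lo
    expect_gte(shannon_entropy(col2), shannon_entropy(col))
  }
})

test_that("column categories follow the ordered decision list", {
  s <- default_scheme()
  expect_equal(column_category(c("L", "L", "L"), s), "INV")
  expect_equal(column_category(c("D", "D"), s), "INV")
  expect_equal(column_category(c("L", "V", "I"), s), "HB")
  expect_equal(column_category(c("D", "E"), s), "Ac")
  expect_equal(column_category(c("K", "R", "H"), s), "Bs")
  expect_equal(column_category(c("D", "K"), s), "PC")
  expect_equal(column_category(c("S", "T"), s), "ST")
  expect_equal(column_category(c("L", "D"), s), "HB_HL")
  expect_equal(column_category(c("S", "N"), s), "PU_PC")
  expect_equal(column_category(c("S", "N", "K"), s), "PU_PC")
  expect_equal(column_category(c("G", "S"), s), "PU_PC")
})

test_that("invariant, zero entropy and category INV coincide", {
  set.seed(37)
  b <- generate_block(width = 80, depth = 6, p_sub = 0.3,
                      invariant_fraction = 0.3, seed = 37)
  ps <- positional_summary(b)
  p <- ps$profile
  expect_equal(p$invariant, p$entropy_bits == 0)
  expect_equal(p$invariant, p$category == "INV")
  expect_true(all(p$conserved[p$invariant]))
})

test_that("category percentages partition the columns", {
  # all-invariant block
  ps <- positional_summary(block(c("ACD", "ACD", "ACD")))
  expect_equal(unname(ps$category_percent["INV"]), 100)
  expect_equal(ps$inv_percent, 100)
  expect_equal(ps$conv_percent, 100)
  expect_equal(sum(ps$category_percent), 100)

  set.seed(41)
  for (i in 1:8) {
    b <- random_block(sample(10:60, 1), sample(2:8, 1))
    ps <- positional_summary(b)
    expect_equal(sum(ps$category_percent), 100, tolerance = 1e-9)
    # rounded to 1 decimal the partition still sums to ~100
    expect_lt(abs(sum(round(ps$category_percent, 1)) - 100), 0.2 + 1e-9)
    # oracle: independent reclassification pass
    m <- vapply(strsplit(b$sequences, ""), identity, character(b$width))
    recls <- apply(t(m), 2, column_category, scheme = default_scheme())
    expect_equal(ps$profile$category, unname(recls))
  }
})

test_that("the conservation threshold is tunable", {
  b <- block(c("AV", "AV", "AI", "VL"))  # column 2: 4 distinct, H = 2 bits
  expect_equal(positional_summary(b, entropy_threshold = 1.0)$conv_percent, 50)
  expect_equal(positional_summary(b, entropy_threshold = 2.0)$conv_percent, 100)
})
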