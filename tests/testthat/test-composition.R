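mkprot <- function(seqs, category = NULL) {
  df <- data.frame(record_id = sprintf("r%d", seq_along(seqs)),
                   gene_symbol = sprintf("g%d", seq_along(seqs)),
                   sequence = seqs, length = nchar(seqs), flagged = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(category)) { df$category <- category; df$subcategory <- category }
  df
}

test_that("residue tallies and percentages behave on micro-examples", {
  one <- composition(mkprot("AAAA"))
  expect_equal(one$percent["A", "Plastid"], 100)
  expect_equal(unname(one$total_aa["Plastid"]), 4L)

  # order independence
  two <- composition(mkprot(c("AC", "CA")))
  expect_equal(two$percent["A", "Plastid"], 50)
  expect_equal(two$percent["C", "Plastid"], 50)

  # non-standard residues go to the `other` bucket with a warning
  expect_warning(odd <- composition(mkprot("MKXL")), "non-standard")
  expect_equal(unname(odd$counts["other", "Plastid"]), 1L)
  expect_equal(unname(odd$total_aa["Plastid"]), 3L)
})

test_that("unrounded percentages sum to 100 and category totals sum to the proteome total", {
  gen <- make_paper_like_fixture(5)
  comp <- composition(gen$proteins)
  nonempty <- comp$groups[comp$total_aa[comp$groups] > 0]
  for (g in nonempty) expect_equal(sum(comp$percent[, g]), 100)
  expect_equal(sum(comp$total_aa[setdiff(comp$groups, "Plastid")]),
               unname(comp$total_aa["Plastid"]))
  # the density denominator is the same residue total
  expect_equal(unname(comp$total_aa["Plastid"]), total_aa(gen$proteins))
})

test_that("composition of a concatenation equals the count-weighted merge", {
  set.seed(21)
  a <- mkprot(replicate(4, paste(sample(c("A","D","K","S"), 40, TRUE), collapse = "")))
  b <- mkprot(replicate(3, paste(sample(c("A","D","K","S"), 25, TRUE), collapse = "")))
  merged <- composition(rbind(a, b))
  expect_equal(merged$counts[, "Plastid"],
               composition(a)$counts[, "Plastid"] + composition(b)$counts[, "Plastid"])
})

test_that("a large generated proteome converges to its target frequencies", {
  freqs <- setNames(rep(0, 20), tripepscan:::AA_STANDARD)
  freqs[c("L", "I")] <- c(0.106, 0.090)
  freqs[setdiff(names(freqs), c("L", "I"))] <- (1 - 0.106 - 0.090) / 18
  cfg <- generator_config(n_proteins = c(Metabolism = 100L),
                          length_range = c(500L, 500L),
                          background_frequencies = freqs,
                          plants = list(), accidental_free = FALSE, seed = 99L)
  gen <- generate_proteome(cfg)
  comp <- composition(gen$proteins)   # n = 50,000 residues
  expect_equal(unname(comp$total_aa["Plastid"]), 50000L)
  expect_true(all(abs(comp$percent[, "Plastid"] - 100 * freqs[rownames(comp$percent)]) < 0.5))
})

test_that("comparisons against a reference report signed point differences", {
  comp <- composition(mkprot(c("AAAAAA", "CCCC")))   # A 60%, C 40%
  diff <- compare_composition(comp, c(A = 50, C = 50))
  expect_equal(diff$difference, c(10, -10))

  # identical tables -> all zero
  self_ref <- setNames(comp$percent[, "Plastid"], rownames(comp$percent))
  expect_true(all(compare_composition(comp, self_ref)$difference == 0))

  # combined Asx/Glx rows: a reference lacking N pools D+N on the computed side
  comp2 <- composition(mkprot("DNEQ"))
  pooled <- compare_composition(comp2, c(D = 40, E = 40))
  expect_equal(pooled$aa, c("DN", "EQ"))
  expect_equal(pooled$computed, c(50, 50))
  expect_equal(pooled$difference, c(10, 10))
})

test_that("the display layer rounds half-up and labels cysteine as cystine", {
  comp <- composition(mkprot(c("ACCCCCCC")))  # A 12.5%, C 87.5%
  disp <- format_composition(comp)
  expect_equal(disp["Alanine", "Plastid"], 12.5)
  expect_equal(disp["Cystine", "Plastid"], 87.5)
  expect_equal(round_half_up(0.125 * 100, 1), 12.5)
  expect_equal(round_half_up(1.005, 2), 1.01)
  expect_equal(round_half_up(2.675, 2), 2.68)
})
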