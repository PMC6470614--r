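test_that("planted occurrences are recovered exactly in accidental-free mode", {
  cfg <- generator_config(n_proteins = c(Metabolism = 1L),
                          length_range = c(30L, 30L),
                          plants = list(list(peptide = "AAP", count = 2L)),
                          accidental_free = TRUE, seed = 7L)
  gen <- generate_proteome(cfg)
  expect_equal(nrow(gen$proteins), 1L)
  expect_equal(gen$proteins$length, 30L)
  # background alphabet excludes the plant's residues
  bg <- setdiff(strsplit(gen$proteins$sequence, "")[[1]], c("A", "P"))
  expect_false(any(c("A", "P") %in% bg))

  hits <- scan_proteome(gen$peptides, gen$proteins)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$position, gen$ground_truth$plants$position)
})

test_that("generation is deterministic under a fixed seed, byte for byte", {
  cfg <- generator_config(n_proteins = 2L, length_range = c(40L, 80L),
                          plants = list(list(peptide = "IPP", count = 1L)),
                          seed = 123L)
  g1 <- generate_proteome(cfg)
  g2 <- generate_proteome(cfg)
  expect_identical(g1, g2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_fixture_bundle(g1, d1); p2 <- write_fixture_bundle(g2, d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_proteome(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("infeasible plant loads fail with a capacity message", {
  cfg <- generator_config(n_proteins = c(Transport = 1L),
                          length_range = c(12L, 12L),
                          plants = list(list(peptide = "AAP", count = 5L)),
                          seed = 1L)
  expect_error(generate_proteome(cfg), "capacity")
})

test_that("uniform background composition converges at fifty thousand residues", {
  cfg <- generator_config(n_proteins = c(Unknown = 100L),
                          length_range = c(500L, 500L),
                          plants = list(), accidental_free = FALSE, seed = 77L)
  comp <- composition(generate_proteome(cfg)$proteins)
  expect_true(all(abs(comp$percent[, "Plastid"] - 5) < 1))
})

test_that("the miniature study-shaped fixture has the advertised structure", {
  gen <- make_paper_like_fixture(42L)
  # classifies without any unknown-symbol fallback warning
  expect_no_warning(classify_proteins(gen$proteins[, setdiff(names(gen$proteins),
                                                             c("category", "subcategory"))]))
  expect_equal(length(unique(gen$proteins$category)), 7L)
  expect_equal(nrow(gen$peptides), 10L)
  expect_equal(sum(gen$peptides$terminal_class == "XXX"), 4L)
  expect_setequal(gen$peptides$sequence[gen$peptides$terminal_class == "XXX"],
                  c("LVQ", "LVE", "IWH", "GPM"))
  expect_true(abs(total_aa(gen$proteins) - 2000) < 500)

  # scan totals equal ledger totals, by construction
  hits <- scan_proteome(gen$peptides, gen$proteins)
  expect_equal(nrow(hits), nrow(gen$ground_truth$plants))
  tab <- tabulate_hits(hits, gen$proteins, "category")
  expect_equal(unname(colSums(tab$counts)),
               unname(gen$ground_truth$totals_by_category))
})

test_that("generator configs validate their inputs", {
  expect_error(generator_config(c(Weird = 1L)), "unknown category")
  expect_error(generator_config(1L, length_range = c(5L, 20L)))
  expect_error(generator_config(1L, plants = list(list(peptide = "AAPA", count = 1L))),
               "tripeptide")
  bad_freq <- setNames(rep(0.1, 3), c("A", "C", "D"))
  expect_error(generator_config(1L, background_frequencies = bad_freq), "sum to 1")
})
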