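mkprot2 <- function(seqs, symbols = sprintf("g%d", seq_along(seqs)),
                    category = "Metabolism", subcategory = "Carbohydrates") {
  data.frame(record_id = sprintf("r%d", seq_along(seqs)),
             gene_symbol = symbols, sequence = seqs, length = nchar(seqs),
             flagged = FALSE, category = category, subcategory = subcategory,
             stringsAsFactors = FALSE)
}

mkpep <- function(seqs) {
  data.frame(sequence = seqs, ic50_uM = 5, source = NA_character_,
             terminal_class = terminal_class(seqs), stringsAsFactors = FALSE)
}

test_that("occurrence counting includes overlaps and rejects invalid queries", {
  expect_equal(count_occurrences("AAA", "AAAA"), 2L)
  expect_equal(count_occurrences("IPP", "MIPPG"), 1L)
  expect_equal(count_occurrences("LVQ", "MKT"), 0L)
  expect_equal(count_occurrences("AAA", "AA"), 0L)
  expect_error(count_occurrences("AAAA", "AAAA"), "tripeptide")
  # windows containing a non-standard residue never match
  expect_equal(count_occurrences("AAA", "AAXAA"), 0L)
})

test_that("proteome scans honour counting mode and deterministic ordering", {
  prot <- mkprot2("AAPAAP")
  pep <- mkpep("AAP")
  pos <- scan_proteome(pep, prot, mode = "positions")
  expect_equal(nrow(pos), 2L)
  expect_equal(pos$position, c(0L, 3L))
  expect_equal(attr(pos, "mode"), "positions")

  uniq <- scan_proteome(pep, prot, mode = "unique_pairs")
  expect_equal(nrow(uniq), 1L)
  expect_equal(uniq$position, 0L)

  # ordering: by protein (input order), then position, then peptide
  prot2 <- mkprot2(c("CADCA", "ACADD"))
  peps2 <- mkpep(c("ACA", "CAD", "ADD"))
  hits <- scan_proteome(peps2, prot2)
  expect_equal(hits$record_id, c("r1", "r2", "r2", "r2"))
  expect_equal(hits$position, c(0L, 0L, 1L, 2L))
  expect_equal(hits$peptide, c("CAD", "ACA", "CAD", "ADD"))
})

test_that("scans agree with the independent regex oracle on random proteomes", {
  set.seed(31)
  for (rep in 1:30) {
    prot <- random_protein_set(sample(1:4, 1), 30:400)
    peps <- random_tripeptides(sample(3:12, 1))
    for (mode in c("positions", "unique_pairs")) {
      got <- scan_proteome(peps, prot, mode = mode)
      want <- oracle_scan(peps, prot, mode = mode)
      got_sorted <- got[order(got$record_id, got$position, got$peptide),
                        c("peptide", "record_id", "position")]
      rownames(got_sorted) <- rownames(want) <- NULL
      expect_identical(got_sorted, want)
    }
  }
})

test_that("count tables partition hits by class and group with published-style totals", {
  prot <- mkprot2(c("AAPCAAY", "AAPAAP"), category = c("Metabolism", "Transport"),
                  subcategory = c("Carbohydrates", "Transport"))
  hits <- scan_proteome(mkpep(c("AAP", "AAY")), prot)
  tab <- tabulate_hits(hits, prot, "category")
  expect_equal(unname(tab$peptide_total["Metabolism"]), 2)
  expect_equal(unname(tab$peptide_total["Transport"]), 2)
  expect_equal(tab$grand_total, 4)
  expect_equal(unname(tab$total_aa["Metabolism"]), 7)
  # column totals = sum of the 12 class cells
  expect_equal(colSums(tab$counts), tab$peptide_total)
  # density = 100 * count / total AA, half-up at 2 decimals
  expect_equal(unname(tab$density["Metabolism"]),
               peptide_density(2, 7))

  # empty hit set -> all-zero table
  none <- scan_proteome(mkpep("WWW"), prot)
  tab0 <- tabulate_hits(none, prot, "category")
  expect_true(all(tab0$counts == 0))
  expect_true(all(tab0$density == 0))

  # photosystem subcategory grouping warns when no photosystem proteins exist
  expect_warning(tabulate_hits(hits, prot, "photosystem_subcategory"),
                 "no Photosystems")
})

test_that("tabulation is additive over disjoint protein sets", {
  set.seed(41)
  schema_syms <- default_schema()$gene
  mk <- function(ids, syms) {
    df <- random_protein_set(length(ids), 50:200)
    df$record_id <- ids
    df$gene_symbol <- syms
    classify_proteins(df, default_schema())
  }
  a <- mk(c("a1", "a2"), c("psaA", "rbcL"))
  b <- mk(c("b1", "b2"), c("atpA", "rpl1"))
  peps <- random_tripeptides(8)
  ha <- scan_proteome(peps, a); hb <- scan_proteome(peps, b)
  hu <- scan_proteome(peps, rbind(a, b))
  ta <- tabulate_hits(ha, a, "category")
  tb <- tabulate_hits(hb, b, "category")
  tu <- tabulate_hits(hu, rbind(a, b), "category")
  expect_equal(tu$counts, ta$counts + tb$counts)
  expect_equal(tu$total_aa, ta$total_aa + tb$total_aa)
})

test_that("density reproduces published arithmetic and guards its domain", {
  expect_equal(peptide_density(751, 50333), 1.49)
  expect_equal(peptide_density(742, 50229), 1.48)
  expect_equal(peptide_density(53, 2654), 2.00)
  expect_equal(peptide_density(0, 1000), 0.00)
  expect_error(peptide_density(1, 0), "positive")
})

test_that("count tables serialise to TSV with totals and parameter header", {
  gen <- make_paper_like_fixture(3)
  hits <- scan_proteome(gen$peptides, gen$proteins)
  tab <- tabulate_hits(hits, gen$proteins, "category")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, path)
  lines <- readLines(path)
  expect_match(lines[1], "grouping=category")
  body <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                     check.names = FALSE)
  expect_equal(nrow(body), 15L)   # 12 classes + Total + Total_AA + density
  expect_equal(as.integer(body[body$Peptide == "Total", "Metabolism"]),
               unname(tab$peptide_total["Metabolism"]))
})
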