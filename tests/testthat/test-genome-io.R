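test_that("GenBank CDS extraction honours deposited translations and translates the rest", {
  gb <- write_mini_genbank()
  # genA's deposited translation disagrees with the conceptual one on
  # purpose, so the deposited-wins rule is exercised (with a warning);
  # locB and the join CDS are conceptual-only.
  expect_warning(prot <- read_genbank_proteins(gb), "disagrees")
  expect_equal(nrow(prot), 3L)
  expect_equal(prot$gene_symbol, c("genA", "locB", "hypothetical protein C"))
  expect_equal(prot$sequence[1], "MKL")      # deposited, trailing stop stripped
  expect_equal(prot$sequence[2], "MK")       # complement strand, table 11
  expect_equal(prot$sequence[3], "MCG")      # spliced join, trailing stop gone
  expect_equal(prot$length, nchar(prot$sequence))
})

test_that("a plain forward CDS translates by hand-checkable table-11 rules", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TINY 9 bp    DNA     linear   SYN",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..9",
    '                     /gene="x"',
    "ORIGIN",
    "        1 atggcttaa",
    "//"), path)
  prot <- read_genbank_proteins(path)
  expect_equal(prot$sequence, "MA")
})

test_that("genome summaries count residues, GC and feature types", {
  gb <- write_mini_genbank()
  s <- summarize_genome(gb)
  expect_equal(s$n_pcg, 3L)
  expect_equal(s$n_rrna, 2L)
  expect_equal(s$n_trna, 1L)
  expect_equal(s$n_intron, 1L)               # the one join() CDS

  mk <- function(seq) {
    p <- withr::local_tempfile(fileext = ".gb", .local_envir = parent.frame())
    writeLines(c("LOCUS       T 4 bp", "ORIGIN",
                 sprintf("        1 %s", tolower(seq)), "//"), p)
    p
  }
  expect_equal(summarize_genome(mk("ATGC"))$gc_percent, 50.0)
  expect_equal(summarize_genome(mk("ATGC"))$total_nt, 4L)
  expect_equal(summarize_genome(mk("AAAA"))$gc_percent, 0.0)
})

test_that("protein FASTA round-trips with annotations, fallbacks and normalisation", {
  gen <- make_paper_like_fixture(7)
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "p.fasta"); ann <- file.path(dir, "p.tsv")
  write_protein_fasta(gen$proteins, fa, ann)
  back <- read_protein_fasta(fa, ann)
  expect_identical(back$sequence, gen$proteins$sequence)
  expect_identical(back$gene_symbol, gen$proteins$gene_symbol)
  expect_equal(total_aa(back), sum(nchar(gen$proteins$sequence)))

  # lowercase residues are uppercased; unannotated ids fall back with warning
  fa2 <- file.path(dir, "two.fasta")
  writeLines(c(">p1 desc", "mkl", ">p2", "ACD"), fa2)
  ann2 <- file.path(dir, "two.tsv")
  writeLines(c("record_id\tgene_symbol", "p1\tpsaA"), ann2)
  expect_warning(two <- read_protein_fasta(fa2, ann2), "p2")
  expect_equal(two$sequence, c("MKL", "ACD"))
  expect_equal(two$gene_symbol, c("psaA", "p2"))

  fa3 <- file.path(dir, "dup.fasta")
  writeLines(c(">p1", "MKL", ">p1", "ACD"), fa3)
  expect_error(read_protein_fasta(fa3), "duplicated")
})

test_that("dedupe_genes collapses identical gene copies and CDS without coordinates error", {
  dir <- withr::local_tempdir()
  gb <- file.path(dir, "dup.gb")
  writeLines(c(
    "LOCUS       DUP 40 bp    DNA     linear   SYN",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..9",
    '                     /gene="rrsA"',
    '                     /translation="MA"',
    "     CDS             21..29",
    '                     /gene="rrsA"',
    '                     /translation="MA"',
    "ORIGIN",
    "        1 atggcttaaa cgtacgtacg atggcttaaa cgtacgtacg",
    "//"), gb)
  expect_equal(nrow(read_genbank_proteins(gb)), 2L)                   # default: keep copies
  expect_equal(nrow(read_genbank_proteins(gb, dedupe_genes = TRUE)), 1L)

  gb2 <- file.path(dir, "bad.gb")
  writeLines(c(
    "LOCUS       BAD 9 bp    DNA     linear   SYN",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..somewhere",
    '                     /gene="x"',
    "ORIGIN",
    "        1 atggcttaa",
    "//"), gb2)
  expect_error(read_genbank_proteins(gb2), "unparsable")
})
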